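# Minimum-variance ("smoothest") paths across an energy matrix.
#
# The pose grid is a layered DAG: each step advances the rotation index by
# one row while the separation index may change by a bounded amount.  The
# smoothest path minimizes the sample variance of per-step energy changes.
# Because the endpoints fix the mean step change (the energy differences
# telescope), minimizing the variance is equivalent to minimizing the sum
# of squared deviations from that mean -- a per-edge additive cost, which
# restores the recursive structure Dijkstra's algorithm needs.

#' Movement rule on the pose grid
#'
#' Each step advances the rotation index by one row; the separation index
#' may change by any amount in `sep_deltas` (clipped at the grid edges).
#' The default rule allows -2..+3 columns per step and runs from
#' (rotation row 1, separation column 1) to (last rotation row,
#' separation column 1): both end states sit at the first separation
#' column.
#'
#' @param sep_deltas integer vector of allowed per-step column changes.
#' @param start_sep,goal_sep 1-based separation columns of the start
#'   (first row) and goal (last row) nodes.
#' @return object of class `move_rule`.
#' @export
move_rule <- function(sep_deltas = -2:3, start_sep = 1L, goal_sep = 1L) {
  sep_deltas <- sort(unique(as.integer(sep_deltas)))
  if (length(sep_deltas) == 0L)
    stop("sep_deltas must be non-empty", call. = FALSE)
  base::structure(list(sep_deltas = sep_deltas,
                       start_sep = as.integer(start_sep),
                       goal_sep = as.integer(goal_sep)),
                  class = "move_rule")
}

#' Reachable nodes one rotation step ahead
#'
#' @param node integer pair `(rot_index, sep_index)`.
#' @param rule a [move_rule()].
#' @param grid_shape integer pair `(rotations, separations)`.
#' @return two-column matrix of `(rot_index, sep_index)` nodes; zero rows
#'   at the terminal rotation row.
#' @export
neighbors <- function(node, rule, grid_shape) {
  r <- node[1L]; s <- node[2L]
  R <- grid_shape[1L]; S <- grid_shape[2L]
  if (r < 1L || r > R || s < 1L || s > S)
    stop("node outside the grid", call. = FALSE)
  if (r == R)
    return(matrix(integer(0), 0L, 2L,
                  dimnames = list(NULL, c("rot_index", "sep_index"))))
  s2 <- s + rule$sep_deltas
  s2 <- s2[s2 >= 1L & s2 <= S]
  cbind(rot_index = rep(r + 1L, length(s2)), sep_index = s2)
}

#' Mean per-step energy change between fixed endpoints
#'
#' By telescoping, the mean of the per-step energy differences along any
#' path with `n_steps` steps from `e_start` to `e_goal` is
#' `(e_goal - e_start) / n_steps`, independent of the route.
#'
#' @param e_start,e_goal endpoint energies (kcal/mol).
#' @param n_steps number of steps (>= 1).
#' @return kcal/mol per step.
#' @export
mean_step_energy <- function(e_start, e_goal, n_steps) {
  if (n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
  (e_goal - e_start) / n_steps
}

#' Edge weight of the minimum-variance reformulation
#'
#' The squared deviation of a step's energy change from the
#' path-independent mean step, `(e_to - e_from - mean_step)^2`.  Summed
#' along a path this is `(n-1)` times the sample variance of the step
#' changes, so the shortest path under this weight is the smoothest path.
#' Non-finite energies (masked grid nodes) give an infinite weight.
#'
#' @param e_from,e_to node energies (kcal/mol).
#' @param mean_step the [mean_step_energy()] of the endpoints.
#' @return nonnegative weight.
#' @export
edge_weight <- function(e_from, e_to, mean_step) {
  w <- (e_to - e_from - mean_step)^2
  w[!is.finite(w)] <- Inf
  w
}

#' Sample variance of per-step energy changes
#'
#' The smoothness measure of a path: the sample variance (denominator
#' n - 1) of the consecutive energy differences.
#'
#' @param energies ordered per-node energies (length >= 2... a path of at
#'   least one step).
#' @return variance in (kcal/mol)^2.
#' @export
path_variance <- function(energies) {
  if (length(energies) < 2L)
    stop("need at least 2 energies", call. = FALSE)
  d <- diff(energies)
  if (length(d) == 1L) return(0)
  stats::var(d)
}

#' Total climb of a path
#'
#' Sum of the positive energy increments along a path -- the cumulative
#' barrier a route has to surmount, used to compare high-barrier,
#' low-barrier and smoothest routes.
#'
#' @param energies ordered per-node energies.
#' @return kcal/mol (>= 0).
#' @export
total_climb <- function(energies) {
  if (length(energies) < 2L)
    stop("need at least 2 energies", call. = FALSE)
  sum(pmax(diff(energies), 0))
}

.path_metrics <- function(energies) {
  d <- diff(energies)
  n <- length(d)
  mean_step <- (energies[length(energies)] - energies[1L]) / n
  list(variance = path_variance(energies),
       mean_step = mean_step,
       sum_sq_steps = sum(d^2),
       total_climb = total_climb(energies),
       max_barrier = max(energies) - energies[1L])
}

# Candidate-order for deterministic tie-breaking: smaller |delta| first,
# then smaller predecessor column.
.delta_order <- function(deltas, pred_cols) {
  order(abs(deltas), pred_cols)
}

# Layer-by-layer dynamic program over the rotation rows.  `node_e` are the
# node energies (Inf = masked), `w(e1, e2)` the edge weight.
.solve_dp <- function(node_e, rule, wfun) {
  R <- nrow(node_e); S <- ncol(node_e)
  dist <- matrix(Inf, R, S)
  pred <- matrix(NA_integer_, R, S)
  if (is.finite(node_e[1L, rule$start_sep]))
    dist[1L, rule$start_sep] <- 0
  for (r in seq_len(R - 1L)) {
    for (s2 in seq_len(S)) {
      if (!is.finite(node_e[r + 1L, s2])) next
      pc <- s2 - rule$sep_deltas
      ok <- pc >= 1L & pc <= S
      pc <- pc[ok]; dl <- rule$sep_deltas[ok]
      ord <- .delta_order(dl, pc)
      for (k in ord) {
        p <- pc[k]
        if (!is.finite(dist[r, p])) next
        cand <- dist[r, p] + wfun(node_e[r, p], node_e[r + 1L, s2])
        if (cand < dist[r + 1L, s2]) {   # strict: first-in-order wins ties
          dist[r + 1L, s2] <- cand
          pred[r + 1L, s2] <- p
        }
      }
    }
  }
  list(dist = dist, pred = pred)
}

# Label-setting (Dijkstra) solver on the same layered graph, with the same
# lexicographic tie-break on relaxation.
.solve_dijkstra <- function(node_e, rule, wfun) {
  R <- nrow(node_e); S <- ncol(node_e)
  dist <- matrix(Inf, R, S)
  pred <- matrix(NA_integer_, R, S)
  tie_d <- matrix(Inf, R, S)   # |delta| of the stored predecessor edge
  tie_p <- matrix(Inf, R, S)   # predecessor column of the stored edge
  done <- matrix(FALSE, R, S)
  if (is.finite(node_e[1L, rule$start_sep]))
    dist[1L, rule$start_sep] <- 0
  repeat {
    open <- which(!done & is.finite(dist))
    if (length(open) == 0L) break
    u <- open[which.min(dist[open])]
    done[u] <- TRUE
    r <- (u - 1L) %% R + 1L
    s <- (u - 1L) %/% R + 1L
    if (r == R) next
    for (d in rule$sep_deltas) {
      s2 <- s + d
      if (s2 < 1L || s2 > S || !is.finite(node_e[r + 1L, s2])) next
      cand <- dist[r, s] + wfun(node_e[r, s], node_e[r + 1L, s2])
      better <- cand < dist[r + 1L, s2] ||
        (cand == dist[r + 1L, s2] &&
           (abs(d) < tie_d[r + 1L, s2] ||
              (abs(d) == tie_d[r + 1L, s2] && s < tie_p[r + 1L, s2])))
      if (better && !done[r + 1L, s2]) {
        dist[r + 1L, s2] <- cand
        pred[r + 1L, s2] <- s
        tie_d[r + 1L, s2] <- abs(d)
        tie_p[r + 1L, s2] <- s
      }
    }
  }
  list(dist = dist, pred = pred)
}

.trace_path <- function(pred, goal_row, goal_col) {
  cols <- integer(goal_row)
  cols[goal_row] <- goal_col
  for (r in seq(goal_row, 2L)) {
    cols[r - 1L] <- pred[r, cols[r]]
    if (is.na(cols[r - 1L])) stop("broken predecessor chain", call. = FALSE)
  }
  cols
}

#' Find the energetically smoothest path across an energy matrix
#'
#' Solves for the feasible grid path (one rotation row per step, bounded
#' separation change, fixed endpoints) minimizing the variance of
#' per-step energy changes.  The variance objective is reformulated as an
#' additive per-edge cost `(delta E - mean step)^2` -- path-independent
#' because the endpoint energies fix the mean -- and solved exactly on
#' the layered pose graph, either by label-setting (Dijkstra) or by
#' layer-by-layer dynamic programming (the two are equivalent on this
#' DAG and are cross-checked in the test suite).  Ties are broken
#' deterministically: smaller per-step |separation change|, then smaller
#' predecessor column.  Masked (non-finite) grid nodes are infeasible.
#'
#' @param matrix an `energy_matrix` (any shape; rows are rotation steps).
#' @param rule a [move_rule()].
#' @param method `"dijkstra"` (default) or `"dp"`.
#' @param objective `"variance"` (edge weight `(dE - mean)^2`, default)
#'   or `"squared"` (edge weight `dE^2`); the two select the same optimal
#'   paths because they differ by a path-independent constant.
#' @return object of class `smooth_path`: list with `steps` (data.frame:
#'   step, rot_index, sep_index, rotation_deg, separation_A, energy, dE),
#'   `weight` (sum of edge weights), `metrics` (variance, mean_step,
#'   sum_sq_steps, total_climb, max_barrier) and the solver settings.
#' @export
smoothest_path <- function(matrix, rule = move_rule(),
                           method = c("dijkstra", "dp"),
                           objective = c("variance", "squared")) {
  stopifnot(inherits(matrix, "energy_matrix"), inherits(rule, "move_rule"))
  method <- match.arg(method)
  objective <- match.arg(objective)
  R <- nrow(matrix); S <- ncol(matrix)
  if (R < 2L) stop("matrix needs at least 2 rotation rows", call. = FALSE)
  if (rule$start_sep < 1L || rule$start_sep > S ||
      rule$goal_sep < 1L || rule$goal_sep > S)
    stop("start/goal column outside the grid", call. = FALSE)
  node_e <- unclass(matrix)
  node_e[!is.finite(node_e)] <- Inf
  e_start <- node_e[1L, rule$start_sep]
  e_goal <- node_e[R, rule$goal_sep]
  if (!is.finite(e_start) || !is.finite(e_goal))
    stop("start or goal node is masked; no feasible path", call. = FALSE)
  ms <- if (objective == "variance")
    mean_step_energy(e_start, e_goal, R - 1L) else 0
  wfun <- function(e1, e2) edge_weight(e1, e2, ms)
  sol <- switch(method,
                dijkstra = .solve_dijkstra(node_e, rule, wfun),
                dp = .solve_dp(node_e, rule, wfun))
  if (!is.finite(sol$dist[R, rule$goal_sep]))
    stop("no feasible path from start to goal under the movement rule",
         call. = FALSE)
  cols <- .trace_path(sol$pred, R, rule$goal_sep)
  energies <- node_e[cbind(seq_len(R), cols)]
  steps <- data.frame(step = seq_len(R),
                      rot_index = seq_len(R), sep_index = cols,
                      rotation_deg = attr(matrix, "rot_axis"),
                      separation_A = attr(matrix, "sep_axis")[cols],
                      energy = energies,
                      dE = c(NA, diff(energies)))
  base::structure(list(steps = steps, energies = energies,
                       weight = sol$dist[R, rule$goal_sep],
                       metrics = .path_metrics(energies),
                       method = method, objective = objective,
                       rule = rule),
                  class = "smooth_path")
}

#' Exhaustive smoothest-path oracle
#'
#' Enumerates every feasible path on a small grid (at most 10 rotation
#' rows) and returns the global minimum-weight path together with the
#' number of feasible paths.  Serves as the independent check of the
#' efficient solvers; the number of paths grows exponentially with the
#' row count, which is why the reformulated shortest-path solver exists.
#'
#' @inheritParams smoothest_path
#' @return list with `path` (a `smooth_path`), `weight` and
#'   `feasible_path_count`.
#' @export
brute_force_smoothest <- function(matrix, rule = move_rule(),
                                  objective = c("variance", "squared")) {
  stopifnot(inherits(matrix, "energy_matrix"))
  objective <- match.arg(objective)
  R <- nrow(matrix); S <- ncol(matrix)
  if (R > 10L)
    stop("grid too large to enumerate (", R, " rows > 10)", call. = FALSE)
  node_e <- unclass(matrix)
  node_e[!is.finite(node_e)] <- Inf
  e_start <- node_e[1L, rule$start_sep]
  e_goal <- node_e[R, rule$goal_sep]
  if (!is.finite(e_start) || !is.finite(e_goal))
    stop("start or goal node is masked; no feasible path", call. = FALSE)
  ms <- if (objective == "variance")
    mean_step_energy(e_start, e_goal, R - 1L) else 0

  best_w <- Inf
  best_cols <- NULL
  count <- 0L
  cols <- integer(R)
  cols[1L] <- rule$start_sep
  recurse <- function(r, w) {
    if (r == R) {
      if (cols[R] == rule$goal_sep) {
        count <<- count + 1L
        if (w < best_w) { best_w <<- w; best_cols <<- cols }
      }
      return(invisible())
    }
    dl <- rule$sep_deltas
    nxt <- cols[r] + dl
    ok <- nxt >= 1L & nxt <= S
    nxt <- nxt[ok]; dl <- dl[ok]
    for (k in .delta_order(dl, nxt)) {
      s2 <- nxt[k]
      if (!is.finite(node_e[r + 1L, s2])) next
      cols[r + 1L] <<- s2
      recurse(r + 1L,
              w + edge_weight(node_e[r, cols[r]], node_e[r + 1L, s2], ms))
    }
  }
  if (is.finite(node_e[1L, rule$start_sep])) recurse(1L, 0)
  if (is.null(best_cols))
    stop("no feasible path from start to goal under the movement rule",
         call. = FALSE)
  energies <- node_e[cbind(seq_len(R), best_cols)]
  steps <- data.frame(step = seq_len(R),
                      rot_index = seq_len(R), sep_index = best_cols,
                      rotation_deg = attr(matrix, "rot_axis"),
                      separation_A = attr(matrix, "sep_axis")[best_cols],
                      energy = energies,
                      dE = c(NA, diff(energies)))
  path <- base::structure(list(steps = steps, energies = energies,
                               weight = best_w,
                               metrics = .path_metrics(energies),
                               method = "brute_force",
                               objective = objective, rule = rule),
                          class = "smooth_path")
  list(path = path, weight = best_w, feasible_path_count = count)
}

#' @export
print.smooth_path <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("smooth_path: %d nodes (%d steps), solver = %s\n",
              nrow(x$steps), nrow(x$steps) - 1L, x$method))
  cat(sprintf("  step variance      %.6g (kcal/mol)^2\n", m$variance))
  cat(sprintf("  mean step          %.6g kcal/mol\n", m$mean_step))
  cat(sprintf("  total climb        %.6g kcal/mol\n", m$total_climb))
  cat(sprintf("  max barrier        %.6g kcal/mol\n", m$max_barrier))
  cat(sprintf("  max separation idx %d (%g Angstrom) at step %d\n",
              max(x$steps$sep_index),
              x$steps$separation_A[which.max(x$steps$sep_index)],
              which.max(x$steps$sep_index)))
  invisible(x)
}

#' @export
summary.smooth_path <- function(object, ...) {
  print(object)
  cat("\nstep table:\n")
  print(object$steps, row.names = FALSE)
  invisible(object)
}

#' Energy profile of a smoothest path
#'
#' @param x a `smooth_path`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.smooth_path <- function(x, ...) {
  graphics::plot(x$steps$step, x$steps$energy, type = "b", pch = 16,
                 xlab = "step (rotation row)", ylab = "energy (kcal/mol)",
                 main = "energy along the smoothest path", ...)
  invisible(x)
}

#' Structured report of a path on its matrix
#'
#' Re-derives the per-step table from the matrix (validating that the
#' path's nodes and energies belong to it) and bundles it with the path
#' metrics.
#'
#' @param path a `smooth_path`.
#' @param matrix the `energy_matrix` the path was computed on.
#' @return list with `steps` (data.frame) and `metrics` (list), class
#'   `path_report`.
#' @export
path_report <- function(path, matrix) {
  stopifnot(inherits(path, "smooth_path"), inherits(matrix, "energy_matrix"))
  st <- path$steps
  if (nrow(st) != nrow(matrix) ||
      any(st$sep_index < 1L | st$sep_index > ncol(matrix)))
    stop("path does not fit the matrix shape", call. = FALSE)
  e <- unclass(matrix)[cbind(st$rot_index, st$sep_index)]
  if (!isTRUE(all.equal(e, st$energy, tolerance = 1e-12)))
    stop("path energies do not match the matrix", call. = FALSE)
  base::structure(list(steps = st, metrics = path$metrics),
                  class = "path_report")
}

#' Serialize a path report
#'
#' Writes the report as JSON (`<stem>.json`) and as a tab-separated step
#' table (`<stem>.tsv`).
#'
#' @param report a [path_report()].
#' @param stem output path stem (without extension).
#' @return named character vector of the two files written, invisibly.
#' @export
write_path_report <- function(report, stem) {
  stopifnot(inherits(report, "path_report"))
  json <- paste0(stem, ".json")
  tsv <- paste0(stem, ".tsv")
  jsonlite::write_json(list(steps = report$steps, metrics = report$metrics),
                       json, auto_unbox = TRUE, digits = NA)
  utils::write.table(report$steps, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json, tsv = tsv))
}
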