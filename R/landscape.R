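# Total-energy matrices over the pose grid: assembly, I/O, synthesis.

#' Construct an energy matrix over a pose grid
#'
#' Rows are rotation positions, columns separations.  Values are energies
#' in kcal/mol, either absolute or relative to the inhibited state.
#' Non-finite entries mark infeasible grid nodes (the path solver treats
#' them as untraversable; they are never interpolated).
#'
#' @param values numeric matrix (rotations x separations).
#' @param rot_axis degrees per row (strictly increasing).
#' @param sep_axis Angstrom per column (strictly increasing).
#' @param reference `"absolute"` or `"relative-to-inhibited"`.
#' @return object of class `energy_matrix`.
#' @export
energy_matrix <- function(values,
                          rot_axis = seq(0, by = 5,
                                         length.out = nrow(values)),
                          sep_axis = seq(9, by = 1,
                                         length.out = ncol(values)),
                          reference = "absolute") {
  values <- as.matrix(values)
  if (length(rot_axis) != nrow(values) || length(sep_axis) != ncol(values))
    stop("axis lengths must match the matrix shape", call. = FALSE)
  if (any(diff(rot_axis) <= 0) || any(diff(sep_axis) <= 0))
    stop("axes must be strictly increasing", call. = FALSE)
  reference <- match.arg(reference, c("absolute", "relative-to-inhibited"))
  dimnames(values) <- list(format(rot_axis, trim = TRUE),
                           format(sep_axis, trim = TRUE))
  base::structure(values, class = c("energy_matrix", "matrix"),
                  rot_axis = as.numeric(rot_axis),
                  sep_axis = as.numeric(sep_axis),
                  reference = reference)
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat(sprintf("energy_matrix: %d rotations x %d separations (%s, kcal/mol)\n",
              nrow(x), ncol(x), attr(x, "reference")))
  cat(sprintf("  rotation 0-%g deg, separation %g-%g Angstrom\n",
              max(attr(x, "rot_axis")), min(attr(x, "sep_axis")),
              max(attr(x, "sep_axis"))))
  cat(sprintf("  energy range [%.3f, %.3f]\n",
              min(x[is.finite(x)]), max(x[is.finite(x)])))
  invisible(x)
}

#' Heatmap of an energy landscape, optionally with a path overlay
#'
#' @param x an `energy_matrix`.
#' @param path optional `smooth_path` to overlay.
#' @param ... passed to [graphics::image()].
#' @export
plot.energy_matrix <- function(x, path = NULL, ...) {
  rot <- attr(x, "rot_axis"); sep <- attr(x, "sep_axis")
  graphics::image(rot, sep, unclass(x),
                  xlab = "rotation (deg)", ylab = "separation (Angstrom)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = "total energy landscape", ...)
  if (!is.null(path)) {
    stopifnot(inherits(path, "smooth_path"))
    graphics::lines(path$steps$rotation_deg, path$steps$separation_A,
                    lwd = 2, col = "black")
    graphics::points(path$steps$rotation_deg, path$steps$separation_A,
                     pch = 16, cex = 0.6)
  }
  invisible(x)
}

#' Scorer parameters for the screened non-bonded stand-in
#'
#' Parameters for [simple_nonbonded_score()], a desk-scale stand-in
#' scorer whose absolute values are not physical energies; it exists so
#' the full grid-to-path pipeline can run without a molecular-mechanics
#' engine.  Externally minimized energies can be imported with
#' [read_energy_matrix()] instead.
#'
#' @param dielectric uniform screening dielectric (default 80, bulk
#'   water).
#' @param lj_epsilon Lennard-Jones well depth, kcal/mol.
#' @param lj_sigma Lennard-Jones contact distance, Angstrom.
#' @param cutoff pair-interaction cutoff, Angstrom.
#' @param coulomb_constant 332.06 kcal Angstrom / (mol e^2).
#' @return object of class `scorer_params`.
#' @export
scorer_params <- function(dielectric = 80, lj_epsilon = 0.1,
                          lj_sigma = 3.5, cutoff = 12,
                          coulomb_constant = 332.06) {
  p <- list(dielectric = dielectric, lj_epsilon = lj_epsilon,
            lj_sigma = lj_sigma, cutoff = cutoff,
            coulomb_constant = coulomb_constant)
  if (any(!vapply(p, function(v) is.finite(v) && v > 0, logical(1L))[
    c("dielectric", "lj_sigma", "cutoff", "coulomb_constant")]) ||
    !is.finite(lj_epsilon) || lj_epsilon < 0)
    stop("scorer parameters must be positive and finite (lj_epsilon may be 0)",
         call. = FALSE)
  base::structure(p, class = "scorer_params")
}

#' Screened-Coulomb + Lennard-Jones inter-domain score
#'
#' Sums, over all atom pairs between two domains within the cutoff, the
#' screened Coulomb term k q_i q_j / (eps r) and the 12-6 Lennard-Jones
#' term 4 eps_LJ ((sigma/r)^12 - (sigma/r)^6).  A stand-in for a full
#' molecular-mechanics or continuum-electrostatics total energy: relative
#' trends over a pose grid are meaningful, absolute values are not.
#'
#' @param structure a `domain_structure` (charges in the atom table).
#' @param domain_a,domain_b domain names.
#' @param params a [scorer_params()].
#' @return energy in kcal/mol.
#' @export
simple_nonbonded_score <- function(structure, domain_a, domain_b,
                                   params = scorer_params()) {
  stopifnot(inherits(structure, "domain_structure"),
            inherits(params, "scorer_params"))
  ia <- domain_atoms(structure, domain_a)
  ib <- domain_atoms(structure, domain_b)
  xa <- coords(structure, ia); xb <- coords(structure, ib)
  qa <- structure$atoms$charge[ia]; qb <- structure$atoms$charge[ib]
  # pairwise distance matrix |a| x |b|
  r2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  r <- sqrt(pmax(r2, 0))
  if (any(r < 1e-3)) {
    k <- which(r < 1e-3, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "atom overlap: atoms %d (%s) and %d (%s) are %.2g Angstrom apart",
      structure$atoms$serial[ia[k[1L]]], domain_a,
      structure$atoms$serial[ib[k[2L]]], domain_b, r[k[1L], k[2L]]),
      call. = FALSE)
  }
  keep <- r <= params$cutoff
  if (!any(keep)) return(0)
  rr <- r[keep]
  qq <- outer(qa, qb)[keep]
  sr6 <- (params$lj_sigma / rr)^6
  sum(params$coulomb_constant * qq / (params$dielectric * rr) +
        4 * params$lj_epsilon * (sr6^2 - sr6))
}

#' Evaluate a scorer over every pose of a manifest
#'
#' @param manifest a `pose_manifest`.
#' @param scorer function taking a pose `domain_structure` and returning
#'   an energy in kcal/mol; e.g.
#'   `function(p) simple_nonbonded_score(p, "anchor", "mobile")`.
#' @return an [energy_matrix()] with axes taken from the manifest.
#' @export
build_energy_matrix <- function(manifest, scorer) {
  stopifnot(inherits(manifest, "pose_manifest"), is.function(scorer))
  spec <- attr(manifest, "spec")
  vals <- matrix(NA_real_, length(spec$rotations), length(spec$separations))
  for (i in seq_len(nrow(manifest))) {
    pose <- manifest_pose(manifest, manifest$rot_index[i],
                          manifest$sep_index[i])
    vals[manifest$rot_index[i], manifest$sep_index[i]] <- scorer(pose)
  }
  energy_matrix(vals, rot_axis = spec$rotations, sep_axis = spec$separations)
}

#' Express a matrix relative to the inhibited-state energy
#'
#' Subtracts a reference energy (by default the value at grid node (1, 1),
#' the inhibited pose) from every entry, matching the convention of
#' plotting "relative total energy" heatmaps.  Shift-invariant quantities
#' (paths, step variances) are unchanged.
#'
#' @param matrix an `energy_matrix`.
#' @param reference_value reference energy (kcal/mol); default the (1, 1)
#'   entry.
#' @return an `energy_matrix` flagged `relative-to-inhibited`.
#' @export
relative_energies <- function(matrix, reference_value = matrix[1L, 1L]) {
  stopifnot(inherits(matrix, "energy_matrix"))
  if (!is.finite(reference_value))
    stop("reference energy must be finite", call. = FALSE)
  energy_matrix(unclass(matrix) - reference_value,
                rot_axis = attr(matrix, "rot_axis"),
                sep_axis = attr(matrix, "sep_axis"),
                reference = "relative-to-inhibited")
}

#' Write an energy matrix as comma-separated text
#'
#' Format: optional `#`-prefixed header comments, then a header row
#' `rot_deg\\sep_A,<sep values>` and one row per rotation with the
#' rotation angle in the first column.  Values keep full double
#' precision, so `read_energy_matrix(write_energy_matrix(m))` is exact.
#'
#' @param matrix an `energy_matrix`.
#' @param path output file.
#' @param comments optional character vector written as `# ` header lines.
#' @return `path`, invisibly.
#' @export
write_energy_matrix <- function(matrix, path, comments = NULL) {
  stopifnot(inherits(matrix, "energy_matrix"))
  fmt <- function(v) vapply(v, function(x) sprintf("%.17g", x),
                            character(1L))
  lines <- c(
    if (length(comments)) paste0("# ", comments),
    paste(c("rot_deg\\sep_A", fmt(attr(matrix, "sep_axis"))),
          collapse = ","),
    vapply(seq_len(nrow(matrix)), function(i)
      paste(c(fmt(attr(matrix, "rot_axis")[i]), fmt(unclass(matrix)[i, ])),
            collapse = ","), character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an energy matrix from comma-separated text
#'
#' @param path file produced by [write_energy_matrix()] (or any CSV with
#'   a separation header row and leading rotation column; shapes are not
#'   hard-coded).
#' @return an [energy_matrix()].
#' @export
read_energy_matrix <- function(path) {
  lines <- readLines(path)
  comments <- grepl("^\\s*#", lines)
  meta <- sub("^\\s*#\\s?", "", lines[comments])
  lines <- lines[!comments & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("matrix file '", path, "' has no data rows", call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncols <- length(cells[[1L]])
  ragged <- which(lengths(cells) != ncols)
  if (length(ragged))
    stop("ragged row ", ragged[1L], ": expected ", ncols, " fields, got ",
         lengths(cells)[ragged[1L]], call. = FALSE)
  parse_num <- function(row, cols, rowlab) {
    v <- suppressWarnings(as.numeric(row[cols]))
    bad <- which(is.na(v) & !(toupper(trimws(row[cols])) %in%
                                c("NA", "NAN", "INF", "-INF")))
    if (length(bad))
      stop("non-numeric cell at row ", rowlab, ", column ",
           cols[bad[1L]], ": '", row[cols[bad[1L]]], "'", call. = FALSE)
    v
  }
  sep_axis <- parse_num(cells[[1L]], 2:ncols, "header")
  body <- cells[-1L]
  rot_axis <- vapply(seq_along(body), function(i)
    parse_num(body[[i]], 1L, i + 1L), numeric(1L))
  vals <- t(vapply(seq_along(body), function(i)
    parse_num(body[[i]], 2:ncols, i + 1L), numeric(ncols - 1L)))
  m <- energy_matrix(vals, rot_axis = rot_axis, sep_axis = sep_axis)
  if (length(meta)) attr(m, "comments") <- meta
  m
}

#' Synthesize a basin-plus-barrier energy landscape
#'
#' Generates a landscape with the statistical features of a kinase
#' activation map: a smooth basin decreasing along the rotation axis (the
#' activated end below the inhibited end), a rotational energy-barrier
#' ridge over `barrier_rows` whose amplitude decays with separation and
#' falls below 1% of `barrier_height` beyond column `barrier_decay_col`,
#' and i.i.d. Gaussian noise.
#'
#' The ridge has a Gaussian row profile centered on `barrier_rows` (sd =
#' half the row span) and an exponential column decay reaching 1% of the
#' height at `barrier_decay_col`, clamped to exactly zero beyond it --
#' past the decay column, separation genuinely no longer costs barrier
#' energy, which is what lets a path bypass the barrier by separating
#' first.  With `noise_sd = 0` (the default) the result is deterministic
#' and independent of `seed`.
#'
#' @param rows,cols grid shape (default 30 x 17).
#' @param basin_slope basin decrease per rotation row, kcal/mol
#'   (default 1).
#' @param barrier_height ridge height at the first column, kcal/mol
#'   (default 20).
#' @param barrier_rows row index range of the ridge (default 13:16, i.e.
#'   60--75 degrees on the default axis).
#' @param barrier_decay_col column at which the ridge has decayed to 1%
#'   of its height (default 12, i.e. 20 Angstrom on the default axis).
#' @param noise_sd i.i.d. Gaussian roughness, kcal/mol (default 0: the
#'   idealized landscape).
#' @param seed integer fixing all randomness (optional).
#' @param offset constant added to every entry (kcal/mol; shifts the
#'   inhibited-state energy without changing any path).
#' @return an [energy_matrix()].
#' @export
synthetic_landscape <- function(rows = 30L, cols = 17L, basin_slope = 1,
                                barrier_height = 20,
                                barrier_rows = 13:16,
                                barrier_decay_col = 12L,
                                noise_sd = 0, seed = NULL,
                                offset = 0) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 2L, cols >= 1L, noise_sd >= 0)
  barrier_rows <- as.integer(barrier_rows)
  if (any(barrier_rows < 1L | barrier_rows > rows))
    stop("barrier_rows outside the grid", call. = FALSE)
  if (barrier_decay_col < 1L || barrier_decay_col > cols)
    stop("barrier_decay_col outside the grid", call. = FALSE)
  mu <- mean(barrier_rows)
  sdr <- max((max(barrier_rows) - min(barrier_rows)) / 2, 1)
  ridge_row <- exp(-(seq_len(rows) - mu)^2 / (2 * sdr^2))
  decay <- if (barrier_decay_col > 1L)
    exp(-log(100) * (seq_len(cols) - 1L) / (barrier_decay_col - 1L))
  else c(1, rep(0, cols - 1L))
  decay[seq_len(cols) > barrier_decay_col] <- 0
  basin <- -basin_slope * (seq_len(rows) - 1L)
  vals <- outer(basin, rep(1, cols)) +
    barrier_height * outer(ridge_row, decay) + offset
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    vals <- vals + matrix(stats::rnorm(rows * cols, 0, noise_sd),
                          rows, cols)
  }
  energy_matrix(vals,
                rot_axis = seq(0, by = 5, length.out = rows),
                sep_axis = seq(9, by = 1, length.out = cols))
}

#' Preset synthetic landscapes
#'
#' Three qualitative regimes of kinase-activation landscapes:
#' `"wt"` (barrier bypassable by early separation), `"stair"` (a raised
#' inhibited state with a narrower barrier that can be skirted gradually,
#' gain-of-function-like) and `"locked"` (a barrier persisting out to
#' large separations with a stabilized inhibited state,
#' loss-of-function-like).
#'
#' @param preset one of `"wt"`, `"stair"`, `"locked"`.
#' @param seed integer fixing the noise.
#' @param noise_sd noise level, kcal/mol.
#' @return an [energy_matrix()] with the preset parameters recorded in
#'   the `"comments"` attribute (written as header comments by
#'   [write_energy_matrix()]).
#' @export
preset_landscape <- function(preset = c("wt", "stair", "locked"),
                             seed = NULL, noise_sd = 0) {
  preset <- match.arg(preset)
  par <- switch(preset,
    wt     = list(barrier_height = 20, barrier_decay_col = 12L, offset = 0),
    stair  = list(barrier_height = 20, barrier_decay_col = 8L,  offset = 5),
    locked = list(barrier_height = 30, barrier_decay_col = 16L, offset = -5))
  m <- synthetic_landscape(barrier_height = par$barrier_height,
                           barrier_decay_col = par$barrier_decay_col,
                           offset = par$offset, noise_sd = noise_sd,
                           seed = seed)
  attr(m, "comments") <- c(
    paste0("preset: ", preset),
    sprintf("barrier_height_kcal_mol: %g", par$barrier_height),
    sprintf("barrier_decay_col: %d", par$barrier_decay_col),
    sprintf("offset_kcal_mol: %g", par$offset),
    sprintf("noise_sd_kcal_mol: %g", noise_sd),
    if (!is.null(seed)) sprintf("seed: %d", as.integer(seed)))
  m
}
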