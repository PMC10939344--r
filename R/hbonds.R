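# Hydrogen-bond occupancy over a trajectory.

#' Hydrogen-bond geometric criteria
#'
#' A donor--acceptor contact counts as a hydrogen bond in a frame when the
#' donor--acceptor distance is at most `max_distance` and the deviation of
#' the donor--H...acceptor arrangement from linearity (180 degrees minus
#' the angle at the hydrogen) is at most `max_angle`.
#'
#' @param max_distance donor--acceptor cutoff in Angstrom (> 0).
#' @param max_angle allowed deviation from linearity in degrees,
#'   in (0, 90).
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.5, max_angle = 20) {
  if (!is.finite(max_distance) || max_distance <= 0)
    stop("max_distance must be positive", call. = FALSE)
  if (!is.finite(max_angle) || max_angle <= 0 || max_angle >= 90)
    stop("max_angle must be in (0, 90) degrees", call. = FALSE)
  structure(list(max_distance = max_distance, max_angle = max_angle),
            class = "hbond_criteria")
}

# Hydrogens covalently attached to each donor (bonding distance < 1.2 A in
# the first frame).
.attached_hydrogens <- function(structure, frame1, donors) {
  h_idx <- which(toupper(structure$atoms$element) == "H")
  lapply(donors, function(d) {
    if (length(h_idx) == 0L) return(integer(0))
    dd <- sqrt(rowSums(sweep(frame1[h_idx, , drop = FALSE], 2L,
                             frame1[d, ])^2))
    h_idx[dd < 1.2]
  })
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For every donor--acceptor pair, the occupancy is the percentage of
#' frames in which the pair satisfies the geometric criteria.  Results are
#' reported per residue pair (summing over the atom pairs the two residues
#' contribute) and per residue (summing over all pairs the residue takes
#' part in, on either side).  The per-residue convention deliberately
#' allows occupancies above 100%: a residue that donates to two partners
#' throughout the trajectory has 200% occupancy.
#'
#' @param traj a `domain_trajectory`.
#' @param donors atom indices (or a domain name) of donor heavy atoms;
#'   atoms without a hydrogen within 1.2 Angstrom (covalent bonding
#'   distance) are dropped, and the selection must retain at least one
#'   donor.
#' @param acceptors atom indices (or a domain name) of acceptor heavy
#'   atoms.
#' @param criteria an [hbond_criteria()].
#' @return object of class `hbond_occupancy`: list with data.frames
#'   `pairs` (donor_residue, acceptor_residue, pair_occupancy_percent) and
#'   `residues` (residue, residue_occupancy_percent).
#' @export
hbond_occupancy <- function(traj, donors, acceptors,
                            criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "domain_trajectory"),
            inherits(criteria, "hbond_criteria"))
  s <- traj$structure
  don <- .resolve_selection(s, donors)
  acc <- .resolve_selection(s, acceptors)
  don <- don[toupper(s$atoms$element[don]) != "H"]
  acc <- acc[toupper(s$atoms$element[acc]) != "H"]
  if (length(don) == 0L || length(acc) == 0L)
    stop("donor/acceptor selection contains no heavy atoms", call. = FALSE)

  hyd <- .attached_hydrogens(s, traj$frames[[1L]], don)
  has_h <- lengths(hyd) > 0L
  if (!any(has_h))
    stop("selection contains no donor atom with an attached hydrogen ",
         "(< 1.2 Angstrom)", call. = FALSE)
  don <- don[has_h]
  hyd <- hyd[has_h]

  resno <- s$atoms$resid
  # candidate atom pairs, excluding identical atoms and same-residue pairs
  pairs <- expand.grid(d = don, a = acc, KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$d != pairs$a & resno[pairs$d] != resno[pairs$a], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("no donor/acceptor pairs outside a single residue", call. = FALSE)

  nT <- traj$n_frames
  hits <- numeric(nrow(pairs))
  for (f in traj$frames) {
    for (k in seq_len(nrow(pairs))) {
      d <- pairs$d[k]; a <- pairs$a[k]
      r_da <- sqrt(sum((f[d, ] - f[a, ])^2))
      if (r_da > criteria$max_distance) next
      # best (most linear) attached hydrogen decides the angle
      dev <- vapply(hyd[[match(d, don)]], function(h) {
        v1 <- f[d, ] - f[h, ]
        v2 <- f[a, ] - f[h, ]
        cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
        180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      }, numeric(1L))
      if (min(dev) <= criteria$max_angle) hits[k] <- hits[k] + 1
    }
  }
  pair_occ <- 100 * hits / nT

  pair_tab <- stats::aggregate(
    list(pair_occupancy_percent = pair_occ),
    by = list(donor_residue = resno[pairs$d],
              acceptor_residue = resno[pairs$a]),
    FUN = sum)
  pair_tab <- pair_tab[order(pair_tab$donor_residue,
                             pair_tab$acceptor_residue), , drop = FALSE]
  rownames(pair_tab) <- NULL

  res_ids <- sort(unique(c(pair_tab$donor_residue,
                           pair_tab$acceptor_residue)))
  res_occ <- vapply(res_ids, function(r)
    sum(pair_tab$pair_occupancy_percent[pair_tab$donor_residue == r |
                                          pair_tab$acceptor_residue == r]),
    numeric(1L))
  res_tab <- data.frame(residue = res_ids,
                        residue_occupancy_percent = res_occ)
  structure(list(pairs = pair_tab, residues = res_tab,
                 criteria = criteria, n_frames = nT),
            class = "hbond_occupancy")
}

#' @export
print.hbond_occupancy <- function(x, ...) {
  cat(sprintf("hbond_occupancy over %d frames (cutoffs: %.2f Angstrom, %g deg)\n",
              x$n_frames, x$criteria$max_distance, x$criteria$max_angle))
  shown <- x$pairs[x$pairs$pair_occupancy_percent > 0, , drop = FALSE]
  if (nrow(shown)) print(shown, row.names = FALSE)
  else cat("  no hydrogen bonds detected\n")
  invisible(x)
}

#' Write an occupancy report as a tab-separated table
#'
#' Columns: donor_residue, acceptor_residue, pair_occupancy_percent,
#' residue_occupancy_percent (of the donor residue).
#'
#' @param occ an `hbond_occupancy`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(occ, path) {
  stopifnot(inherits(occ, "hbond_occupancy"))
  tab <- occ$pairs
  tab$residue_occupancy_percent <- occ$residues$residue_occupancy_percent[
    match(tab$donor_residue, occ$residues$residue)]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
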