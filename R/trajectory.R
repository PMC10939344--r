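# Multi-model trajectories and the structural statistics computed on them.

#' Construct a trajectory
#'
#' A trajectory is an ordered set of coordinate frames congruent with one
#' structure: every frame has the same atom count and ordering.
#'
#' @param structure the `domain_structure` whose atoms the frames describe.
#' @param frames list of N x 3 coordinate matrices (one per frame).
#' @return object of class `domain_trajectory` with elements `structure`,
#'   `frames` and `n_frames`.
#' @export
trajectory <- function(structure, frames) {
  stopifnot(inherits(structure, "domain_structure"))
  if (length(frames) == 0L)
    stop("trajectory must contain at least one frame", call. = FALSE)
  n <- nrow(structure$atoms)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != n || ncol(f) != 3L)
      stop("every frame must be ", n, " x 3 (atom count drift?)",
           call. = FALSE)
    unname(f)
  })
  base::structure(list(structure = structure, frames = frames,
                       n_frames = length(frames)),
                  class = "domain_trajectory")
}

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL-delimited models become frames; all models must share the
#' atom ordering of the first.
#'
#' @inheritParams read_structure
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, domains, charges = NULL) {
  ref <- read_structure(path, domains, charges)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n <- nrow(ref$atoms)
  if (ncol(xyz) != 3L * n)
    stop("atom count drift across models in '", path, "'", call. = FALSE)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  trajectory(ref, frames)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a `domain_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  a <- traj$structure$atoms
  xyz <- do.call(rbind, lapply(traj$frames, function(f) as.numeric(t(f))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resid, chain = a$chain,
                   resid = rep("GLY", nrow(a)),
                   eleno = a$serial, elety = a$name, elesy = a$element)
  invisible(path)
}

#' @export
print.domain_trajectory <- function(x, ...) {
  cat("domain_trajectory:", x$n_frames, "frames x",
      nrow(x$structure$atoms), "atoms\n")
  invisible(x)
}

# Weighted Kabsch superposition: returns `x` rigidly transformed onto `ref`.
.superpose <- function(x, ref, w) {
  cx <- drop(crossprod(x, w)) / sum(w)
  cr <- drop(crossprod(ref, w)) / sum(w)
  xc <- sweep(x, 2L, cx)
  rc <- sweep(ref, 2L, cr)
  h <- crossprod(xc * w, rc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(xc %*% t(rot), 2L, cr, "+")
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Computes the (optionally mass- or otherwise weighted) RMSD
#' \deqn{RMSD = \sqrt{\frac{\sum_i w_i |r_i - r_i^{ref}|^2}{\sum_i w_i}},}
#' the weighted mean squared displacement under the root; uniform weights
#' reduce to the plain root-mean-square distance.  With `superpose = TRUE`
#' the mobile set is
#' first fitted onto the reference by the weighted least-squares rigid
#' (Kabsch) transformation, so pure rigid-body displacements give 0.
#'
#' @param x,ref N x 3 coordinate matrices (or `domain_structure`s).
#' @param superpose logical; apply the least-squares rigid fit first.
#' @param weights optional nonnegative per-atom weights, not all zero
#'   (default uniform).
#' @return RMSD in Angstrom (scalar, >= 0).
#' @export
rmsd <- function(x, ref, superpose = FALSE, weights = NULL) {
  if (inherits(x, "domain_structure")) x <- coords(x)
  if (inherits(ref, "domain_structure")) ref <- coords(ref)
  x <- as.matrix(x); ref <- as.matrix(ref)
  if (!all(dim(x) == dim(ref)))
    stop("coordinate sets differ in shape (", nrow(x), " vs ", nrow(ref),
         " atoms)", call. = FALSE)
  n <- nrow(x)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    stop("weights must be nonnegative, length ", n, ", not all zero",
         call. = FALSE)
  if (superpose) x <- .superpose(x, ref, w)
  sqrt(sum(w * rowSums((x - ref)^2)) / sum(w))
}

#' Root-mean-square fluctuation about the time-average structure
#'
#' Per-atom RMSF over a trajectory,
#' \deqn{RMSF_i = \sqrt{\frac{1}{T}\sum_{t=1}^{T} |r_i(t) - \bar r_i|^2},}
#' where \eqn{\bar r_i} is the time-average position of atom \eqn{i}
#' (no superposition is applied; align the trajectory beforehand if the
#' frames are not already in a common frame of reference).
#'
#' @param traj a `domain_trajectory` with at least 2 frames.
#' @param selection optional atom indices or a domain name (default: all
#'   atoms).
#' @return numeric vector of per-atom RMSF values (Angstrom).
#' @export
rmsf <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "domain_trajectory"))
  if (traj$n_frames < 2L)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  idx <- .resolve_selection(traj$structure, selection)
  stack <- vapply(traj$frames, function(f) f[idx, , drop = FALSE],
                  matrix(0, length(idx), 3L))
  if (length(idx) == 1L) dim(stack) <- c(1L, 3L, traj$n_frames)
  mean_pos <- apply(stack, c(1L, 2L), mean)
  dev2 <- vapply(seq_len(traj$n_frames), function(t)
    rowSums((stack[, , t, drop = FALSE][, , 1L] - mean_pos)^2),
    numeric(length(idx)))
  if (length(idx) == 1L) dim(dev2) <- c(1L, traj$n_frames)
  sqrt(rowMeans(dev2))
}

.resolve_selection <- function(structure, selection) {
  if (is.null(selection)) return(seq_len(nrow(structure$atoms)))
  if (is.character(selection) && length(selection) == 1L &&
      selection %in% names(structure$domains))
    return(domain_atoms(structure, selection))
  idx <- as.integer(selection)
  if (length(idx) == 0L || any(idx < 1L | idx > nrow(structure$atoms)))
    stop("empty or out-of-range atom selection", call. = FALSE)
  idx
}
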