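# Synthetic two-domain fixtures: toy structures and trajectories that
# exercise the full pipeline at desk scale.

#' Toy two-domain structure
#'
#' Two compact pseudo-atom clusters, an `anchor` domain centered at the
#' origin and a `mobile` domain centered `radius` Angstrom away along +x,
#' with alternating partial charges so the non-bonded scorer produces a
#' non-trivial landscape.  Each atom is its own residue: anchor residues
#' `1..n_anchor`, mobile residues `101..(100 + n_mobile)`.
#'
#' @param n_anchor,n_mobile atoms per domain.
#' @param radius anchor-to-mobile center distance (Angstrom).
#' @param spread cluster radius scale (Angstrom).
#' @param seed integer seed fixing the atom placements.
#' @return a [domain_structure()] with domains `anchor` and `mobile`.
#' @export
toy_two_domain_structure <- function(n_anchor = 24L, n_mobile = 18L,
                                     radius = 16, spread = 4, seed = 42L) {
  set.seed(as.integer(seed))
  n <- n_anchor + n_mobile
  cluster <- function(k, center) {
    pts <- matrix(stats::rnorm(3L * k, sd = spread / 2), k, 3L)
    pts <- pts - matrix(colMeans(pts), k, 3L, byrow = TRUE)  # exact center
    sweep(pts, 2L, center, "+")
  }
  xyz <- rbind(cluster(n_anchor, c(0, 0, 0)),
               cluster(n_mobile, c(radius, 0, 0)))
  elements <- rep_len(c("C", "N", "O"), n)
  atoms <- data.frame(
    serial = seq_len(n),
    name = rep_len(c("C1", "N1", "O1"), n),
    element = elements,
    resid = c(seq_len(n_anchor), 100L + seq_len(n_mobile)),
    chain = rep(c("A", "B"), c(n_anchor, n_mobile)),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    charge = rep_len(c(0.2, -0.2), n),
    stringsAsFactors = FALSE
  )
  domain_structure(atoms, list(anchor = c(1L, n_anchor),
                               mobile = c(101L, 100L + n_mobile)))
}

#' Activated-state mass center for a toy system
#'
#' Places the mobile domain's activated-state center at radius
#' `|OA| + separation` from the anchor center, rotated `angle` degrees
#' from the inhibited direction within a fixed plane -- the geometry in
#' which the `separation`-shifted inhibited center and the activated
#' center sit at equal radii.
#'
#' @param structure a `domain_structure`.
#' @param anchor,mobile domain names.
#' @param separation radial offset of the activated center (default 9).
#' @param angle in-plane angle from the inhibited direction, degrees.
#' @param plane_hint vector not parallel to O->A used to pick the plane
#'   (default +z).
#' @return numeric length-3 vector.
#' @export
toy_activated_center <- function(structure, anchor = "anchor",
                                 mobile = "mobile", separation = 9,
                                 angle = 145, plane_hint = c(0, 0, 1)) {
  O <- center_of_mass(structure, anchor)
  A <- center_of_mass(structure, mobile)
  u <- .unit(A - O)
  h <- as.numeric(plane_hint)
  v <- h - sum(h * u) * u
  if (sqrt(sum(v^2)) < 1e-8)
    stop("plane_hint is parallel to O->A", call. = FALSE)
  v <- .unit(v)
  # v here is the plane normal candidate; in-plane second axis:
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  r <- sqrt(sum((A - O)^2)) + separation
  th <- angle * pi / 180
  O + r * (cos(th) * u + sin(th) * w)
}

#' Toy hydrogen-bonding trajectory
#'
#' A minimal donor/acceptor system: residue 1 is an NH2-like donor (N
#' plus two hydrogens pointing along +x and +y), residue 2 an acceptor
#' oxygen on the +x hydrogen's line at 3.0 Angstrom from the donor, and
#' residue 3 an acceptor oxygen likewise on the +y line.  With
#' `broken_frames = 0` both bonds persist in every frame (donor residue
#' occupancy 200% under the summing convention); `broken_frames` > 0
#' pushes residue 3 out of range in that many trailing frames.
#'
#' @param n_frames number of frames.
#' @param broken_frames frames (at the end) in which the residue-3 bond
#'   is broken.
#' @return a [trajectory()].
#' @export
toy_hbond_trajectory <- function(n_frames = 5L, broken_frames = 0L) {
  stopifnot(n_frames >= 2L, broken_frames >= 0L,
            broken_frames <= n_frames)
  atoms <- data.frame(
    serial = 1:5,
    name = c("N", "H1", "H2", "O", "O"),
    element = c("N", "H", "H", "O", "O"),
    resid = c(1L, 1L, 1L, 2L, 3L),
    chain = "A",
    x = c(0, 1, 0, 3, 0),
    y = c(0, 0, 1, 0, 3),
    z = c(0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  s <- domain_structure(atoms, list(all = c(1L, 3L)))
  base_xyz <- coords(s)
  frames <- lapply(seq_len(n_frames), function(i) {
    f <- base_xyz
    if (i > n_frames - broken_frames) f[5L, 2L] <- 6  # beyond 3.5 cutoff
    f
  })
  trajectory(s, frames)
}
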