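# Rigid-body separation x rotation pose grids of a mobile domain about an
# anchor domain, in the plane spanned by three mass centers.

.unit <- function(v) v / sqrt(sum(v^2))

#' Build the rotation frame from three mass centers
#'
#' The anchor center `O`, the mobile-domain center in the inhibited state
#' `A`, and the mobile-domain center in the activated state `C` define the
#' motion plane.  The frame consists of the in-plane unit vector
#' `u` along O->A, the in-plane unit vector `v` orthogonal to `u` and
#' oriented so that C has a positive v-component, and the plane normal
#' `n = u x v`.  `theta_total` is the in-plane angle from O->A to O->C in
#' degrees, positive by construction and in (0, 180).
#'
#' @param O,A,C numeric length-3 vectors (Angstrom).
#' @return object of class `rotation_frame` with elements `O`, `u`, `v`,
#'   `n`, `radius` (= |A - O|) and `theta_total` (degrees).
#' @export
build_rotation_frame <- function(O, A, C) {
  O <- as.numeric(O); A <- as.numeric(A); C <- as.numeric(C)
  stopifnot(length(O) == 3L, length(A) == 3L, length(C) == 3L)
  oa <- A - O
  oc <- C - O
  cr <- c(oa[2] * oc[3] - oa[3] * oc[2],
          oa[3] * oc[1] - oa[1] * oc[3],
          oa[1] * oc[2] - oa[2] * oc[1])
  area <- sqrt(sum(cr^2)) / 2
  if (!is.finite(area) || area <= 1e-6)
    stop("mass centers are coincident or collinear; cannot define a ",
         "rotation plane", call. = FALSE)
  u <- .unit(oa)
  v <- .unit(oc - sum(oc * u) * u)  # in-plane, positive toward C
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  theta <- atan2(sum(oc * v), sum(oc * u)) * 180 / pi
  structure(list(O = O, u = u, v = v, n = n,
                 radius = sqrt(sum(oa^2)), theta_total = theta),
            class = "rotation_frame")
}

#' @export
print.rotation_frame <- function(x, ...) {
  cat(sprintf("rotation_frame: |OA| = %.3f Angstrom, theta_total = %.2f deg\n",
              x$radius, x$theta_total))
  invisible(x)
}

#' Pose-grid specification
#'
#' Defaults reproduce the canonical activation grid: separations 9--25
#' Angstrom in 1 Angstrom steps (17 columns) and rotations 0--145 degrees
#' in 5 degree steps (30 rows).
#'
#' @param sep_min,sep_max,sep_step radial separations in Angstrom.
#' @param rot_step,rot_total rotation increments/total in degrees.
#' @return object of class `grid_spec` with the `separations` and
#'   `rotations` axes.
#' @export
grid_spec <- function(sep_min = 9, sep_max = 25, sep_step = 1,
                      rot_step = 5, rot_total = 145) {
  stopifnot(sep_step > 0, rot_step > 0, sep_max >= sep_min, rot_total > 0)
  ns <- (sep_max - sep_min) / sep_step
  nr <- rot_total / rot_step
  if (abs(ns - round(ns)) > 1e-9 || abs(nr - round(nr)) > 1e-9)
    stop("grid extents must be integer multiples of the step sizes",
         call. = FALSE)
  structure(list(sep_min = sep_min, sep_max = sep_max, sep_step = sep_step,
                 rot_step = rot_step, rot_total = rot_total,
                 separations = seq(sep_min, sep_max, by = sep_step),
                 rotations = seq(0, rot_total, by = rot_step)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rotations (0-%g deg by %g) x %d separations (%g-%g Angstrom by %g)\n",
              length(x$rotations), x$rot_total, x$rot_step,
              length(x$separations), x$sep_min, x$sep_max, x$sep_step))
  invisible(x)
}

# Rodrigues rotation matrix for angle `deg` about unit axis `n`.
.rotation_matrix <- function(n, deg) {
  th <- deg * pi / 180
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigidly place the mobile domain at a grid pose
#'
#' The mobile domain is first translated radially outward by `separation`
#' along O->A, then rotated as a rigid body by `rotation` degrees about
#' the axis through O along the plane normal.  Position and orientation
#' co-rotate, so the same face of the mobile domain keeps pointing at the
#' anchor.  All other domains are untouched.  The mobile mass center ends
#' at `O + (|OA| + separation) * (cos(rot) u + sin(rot) v)`.
#'
#' @param structure a `domain_structure`.
#' @param mobile name of the mobile domain.
#' @param frame a [build_rotation_frame()] result.
#' @param separation radial displacement in Angstrom (>= 0).
#' @param rotation rotation in degrees.
#' @return a new `domain_structure` with the mobile domain repositioned.
#' @export
pose_transform <- function(structure, mobile, frame, separation, rotation) {
  stopifnot(inherits(structure, "domain_structure"),
            inherits(frame, "rotation_frame"))
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  idx <- domain_atoms(structure, mobile)
  xyz <- coords(structure)
  x <- xyz[idx, , drop = FALSE]
  x <- x + matrix(separation * frame$u, nrow(x), 3L, byrow = TRUE)
  R <- .rotation_matrix(frame$n, rotation)
  x <- sweep(sweep(x, 2L, frame$O) %*% t(R), 2L, frame$O, "+")
  xyz[idx, ] <- x
  set_coords(structure, xyz)
}

#' Generate the full pose grid
#'
#' Produces one rigid pose of the mobile domain per (rotation, separation)
#' grid node; the default specification yields 30 x 17 = 510 poses.  Node
#' (1, 1) is the `sep_min`-separated inhibited pose at 0 degrees rotation.
#'
#' @param structure a `domain_structure`.
#' @param anchor,mobile domain names; the frame origin O is the anchor's
#'   mass center and A the mobile domain's mass center.
#' @param activated_center length-3 vector: the mobile domain's mass
#'   center in the activated state (defines the rotation direction).
#' @param spec a [grid_spec()].
#' @param out_dir optional directory; when given, every pose is written as
#'   a PDB file `pose_r<rot>_s<sep>.pdb` plus a `manifest.csv`
#'   (rot_index, sep_index, rotation_deg, separation_A, filename).
#' @param keep_poses logical; retain the pose structures in memory
#'   (default TRUE when `out_dir` is NULL).
#' @return object of class `pose_manifest`: a data.frame with columns
#'   rot_index, sep_index, rotation_deg, separation_A, filename, with the
#'   frame, spec, template structure and (optionally) pose list attached
#'   as attributes.
#' @export
generate_pose_grid <- function(structure, anchor, mobile, activated_center,
                               spec = grid_spec(), out_dir = NULL,
                               keep_poses = is.null(out_dir)) {
  stopifnot(inherits(structure, "domain_structure"),
            inherits(spec, "grid_spec"))
  O <- center_of_mass(structure, anchor)
  A <- center_of_mass(structure, mobile)
  frame <- build_rotation_frame(O, A, as.numeric(activated_center))
  if (abs(frame$theta_total - spec$rot_total) > 5)
    warning(sprintf(
      "measured angle between inhibited and activated centers (%.1f deg) differs from the grid's rot_total (%g deg)",
      frame$theta_total, spec$rot_total), call. = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(out_dir))
      stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  }
  rot <- spec$rotations
  sep <- spec$separations
  grid <- expand.grid(rot_index = seq_along(rot), sep_index = seq_along(sep),
                      KEEP.OUT.ATTRS = FALSE)
  grid$rotation_deg <- rot[grid$rot_index]
  grid$separation_A <- sep[grid$sep_index]
  grid$filename <- sprintf("pose_r%02d_s%02d.pdb", grid$rot_index,
                           grid$sep_index)
  poses <- if (keep_poses) vector("list", nrow(grid)) else NULL
  for (i in seq_len(nrow(grid))) {
    p <- pose_transform(structure, mobile, frame,
                        grid$separation_A[i], grid$rotation_deg[i])
    if (keep_poses) poses[[i]] <- p
    if (!is.null(out_dir))
      write_structure(p, file.path(out_dir, grid$filename[i]))
  }
  if (!is.null(out_dir))
    utils::write.csv(grid, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  base::structure(grid, class = c("pose_manifest", "data.frame"),
            frame = frame, spec = spec, template = structure,
            mobile = mobile, anchor = anchor, out_dir = out_dir,
            poses = poses)
}

#' Retrieve one pose from a manifest
#'
#' @param manifest a `pose_manifest`.
#' @param rot_index,sep_index 1-based grid indices.
#' @return the pose as a `domain_structure` (from memory when retained,
#'   otherwise re-read from the manifest's output directory).
#' @export
manifest_pose <- function(manifest, rot_index, sep_index) {
  stopifnot(inherits(manifest, "pose_manifest"))
  i <- which(manifest$rot_index == rot_index &
               manifest$sep_index == sep_index)
  if (length(i) != 1L)
    stop("no manifest entry (", rot_index, ", ", sep_index, ")",
         call. = FALSE)
  poses <- attr(manifest, "poses")
  if (!is.null(poses)) return(poses[[i]])
  out_dir <- attr(manifest, "out_dir")
  path <- file.path(out_dir, manifest$filename[i])
  if (is.null(out_dir) || !file.exists(path))
    stop("pose file missing for entry (", rot_index, ", ", sep_index,
         "): ", manifest$filename[i], call. = FALSE)
  tpl <- attr(manifest, "template")
  read_structure(path, tpl$domains, charges = tpl$atoms$charge)
}

#' Maximum internal-distance deviation of the mobile domain
#'
#' Verifies that a pose is a rigid copy of the original mobile domain by
#' comparing internal pairwise distances over a deterministic subset of at
#' most `max_pairs` atom pairs.
#'
#' @param original,pose `domain_structure`s with identical atom ordering.
#' @param mobile mobile domain name.
#' @param max_pairs pair budget (default 500).
#' @return maximum absolute deviation of an internal distance (Angstrom).
#' @export
verify_rigidity <- function(original, pose, mobile, max_pairs = 500L) {
  if (nrow(original$atoms) != nrow(pose$atoms) ||
      !all(original$atoms$serial == pose$atoms$serial))
    stop("structures differ in atom ordering", call. = FALSE)
  idx <- domain_atoms(original, mobile)
  n <- length(idx)
  if (n < 2L) return(0)
  if (n * (n - 1) / 2 > max_pairs) {
    # evenly spaced deterministic subset keeping the pair budget
    k <- max(2L, floor((1 + sqrt(1 + 8 * max_pairs)) / 2))
    idx <- idx[unique(round(seq(1L, n, length.out = k)))]
  }
  d0 <- stats::dist(coords(original, idx))
  d1 <- stats::dist(coords(pose, idx))
  max(abs(d1 - d0))
}
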