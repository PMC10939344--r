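# Structure I/O, centers of mass, RMSD/RMSF, hydrogen-bond occupancy.

test_that("PDB round-trip preserves atoms and resolves domain selections", {
  s <- tiny_structure()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f, list(M = c(1, 1)))
  expect_equal(nrow(s2$atoms), 3L)
  expect_equal(coords(s2), coords(s), tolerance = 1e-8)
  expect_length(domain_atoms(s2, "M"), 2L)  # residue 1 has two atoms

  # a kinase-like partition over a long residue range: four non-empty
  # domains (FERM/SH2/PK/TK residue windows)
  n <- length(34:1153)
  big <- domain_structure(
    data.frame(serial = seq_len(n), name = "CA", element = "C",
               resid = 34:1153, chain = "A",
               x = seq_len(n), y = 0, z = 0, stringsAsFactors = FALSE),
    list(FERM = c(34, 420), SH2 = c(439, 544),
         PK = c(583, 855), TK = c(875, 1153)))
  fb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(big, fb)
  jak <- read_structure(fb, list(FERM = c(34, 420), SH2 = c(439, 544),
                                 PK = c(583, 855), TK = c(875, 1153)))
  expect_equal(vapply(names(jak$domains),
                      function(d) length(domain_atoms(jak, d)),
                      integer(1L), USE.NAMES = FALSE),
               c(387L, 106L, 273L, 279L))
})

test_that("malformed or unsupported PDB content is rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1      badxyz   0.000   0.000  1.00  0.00           N",
    "END"), f)
  expect_error(read_structure(f, list(M = c(1, 1))),
               "parse|coordinate|malformed", ignore.case = TRUE)

  # insertion codes are ambiguous for range-based partitions
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1A      0.000   0.000   0.000  1.00  0.00           N",
    "END"), f2)
  expect_error(read_structure(f2, list(M = c(1, 1))), "insertion")

  # a domain selecting nothing is a spec error
  s <- tiny_structure()
  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f3)
  expect_error(read_structure(f3, list(M = c(50, 60))), "zero atoms")
})

test_that("domain partitions must be non-overlapping", {
  atoms <- tiny_structure()$atoms
  expect_error(domain_structure(atoms, list(A = c(1, 2), B = c(2, 2))),
               "overlap")
})

test_that("center_of_mass is the mass-weighted mean", {
  one <- domain_structure(
    data.frame(serial = 1L, name = "X", element = "C", resid = 1L,
               chain = "A", x = 1, y = 2, z = 3, mass = 1,
               stringsAsFactors = FALSE),
    list(M = c(1, 1)))
  expect_equal(unname(center_of_mass(one, "M")), c(1, 2, 3))

  two <- function(m1, m2) domain_structure(
    data.frame(serial = 1:2, name = "X", element = "C", resid = c(1L, 1L),
               chain = "A", x = c(0, 4), y = 0, z = 0, mass = c(m1, m2),
               stringsAsFactors = FALSE),
    list(M = c(1, 1)))
  expect_equal(unname(center_of_mass(two(1, 1), "M")), c(2, 0, 0))
  expect_equal(unname(center_of_mass(two(1, 3), "M")), c(3, 0, 0))
})

test_that("center_of_mass is equivariant under rigid transforms", {
  s <- toy_two_domain_structure(seed = 11)
  for (seed in 1:5) {
    rt <- rand_rigid(seed)
    s2 <- set_coords(s, apply_rigid(coords(s), rt))
    expect_equal(unname(center_of_mass(s2, "mobile")),
                 unname(drop(rt$R %*% center_of_mass(s, "mobile") + rt$t)),
                 tolerance = 1e-9)
  }
})

test_that("rmsd matches direct computation and superposition removes rigid motion", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(x, x), 0)
  shifted <- sweep(x, 2, c(3, 4, 0), "+")
  expect_equal(rmsd(shifted, x), 5)
  expect_equal(rmsd(shifted, x, superpose = TRUE), 0, tolerance = 1e-9)

  # superposed rmsd never exceeds the raw rmsd; cross-check against the
  # independent bio3d fitting route
  for (seed in 1:10) {
    set.seed(seed)
    a <- matrix(rnorm(36), 12, 3)
    b <- matrix(rnorm(36), 12, 3)
    raw <- rmsd(a, b)
    fit <- rmsd(a, b, superpose = TRUE)
    expect_lte(fit, raw + 1e-12)
    # bio3d::rmsd rounds to 3 decimals
    ref_fit <- bio3d::rmsd(as.numeric(t(b)), as.numeric(t(a)),
                           fit = TRUE)
    expect_equal(fit, ref_fit, tolerance = 1e-3)
  }
})

test_that("rmsd validates shapes and weights", {
  x <- matrix(0, 4, 3)
  expect_error(rmsd(x, matrix(0, 5, 3)), "shape")
  expect_error(rmsd(x, x, weights = rep(0, 4)), "weights")
  expect_error(rmsd(x, x, weights = c(-1, 1, 1, 1)), "weights")
  # weighted rmsd concentrates on the weighted atoms
  y <- x; y[1, 1] <- 2
  expect_equal(rmsd(y, x, weights = c(1, 0, 0, 0)), 2)
  expect_equal(rmsd(y, x, weights = c(0, 1, 1, 1)), 0)
})

test_that("rmsf measures fluctuation about the time average", {
  s <- tiny_structure()
  still <- trajectory(s, rep(list(coords(s)), 4))
  expect_equal(rmsf(still), rep(0, 3))

  # one atom alternating between (0,0,0) and (2,0,0): mean (1,0,0),
  # deviation 1 every frame
  f1 <- coords(s); f2 <- coords(s)
  f1[1, ] <- c(0, 0, 0); f2[1, ] <- c(2, 0, 0)
  alt <- trajectory(s, list(f1, f2, f1, f2))
  expect_equal(rmsf(alt)[1], 1)
  expect_equal(rmsf(alt)[2:3], rep(0, 2))  # static atoms stay at 0

  # time reversal leaves rmsf unchanged
  set.seed(5)
  frames <- lapply(1:6, function(i) coords(s) + matrix(rnorm(9), 3, 3))
  tr <- trajectory(s, frames)
  rv <- trajectory(s, rev(frames))
  expect_equal(rmsf(tr), rmsf(rv))

  expect_error(rmsf(trajectory(s, list(coords(s)))), "2 frames")
})

test_that("multi-model PDB trajectories round-trip", {
  traj <- toy_hbond_trajectory(n_frames = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  back <- read_trajectory(f, list(all = c(1, 3)))
  expect_equal(back$n_frames, 3L)
  for (i in 1:3)
    expect_equal(back$frames[[i]], traj$frames[[i]], tolerance = 1e-8)
})

test_that("hbond occupancy applies the distance and angle criteria", {
  mk <- function(dx, dev_deg = 0) {
    # donor N at origin, H along +x, acceptor O at distance dx rotated
    # dev_deg away from the D-H line
    th <- dev_deg * pi / 180
    atoms <- data.frame(
      serial = 1:3, name = c("N", "H", "O"), element = c("N", "H", "O"),
      resid = c(1L, 1L, 2L), chain = "A",
      x = c(0, 1, dx * cos(th)), y = c(0, 0, dx * sin(th)), z = 0,
      stringsAsFactors = FALSE)
    s <- domain_structure(atoms, list(all = c(1, 2)))
    trajectory(s, rep(list(coords(s)), 4))
  }
  # 3.4 A, deviation ~10 deg in every frame -> 100%
  occ <- hbond_occupancy(mk(3.4, 9.5), donors = 1L, acceptors = 3L)
  expect_equal(occ$pairs$pair_occupancy_percent, 100)
  # 3.6 A -> never bonded
  occ2 <- hbond_occupancy(mk(3.6, 0), donors = 1L, acceptors = 3L)
  expect_equal(occ2$pairs$pair_occupancy_percent, 0)
})

test_that("per-residue occupancy sums partners and may exceed 100%", {
  traj <- toy_hbond_trajectory(n_frames = 5, broken_frames = 0)
  occ <- hbond_occupancy(traj, donors = 1L, acceptors = c(4L, 5L))
  expect_equal(sort(occ$pairs$pair_occupancy_percent), c(100, 100))
  expect_equal(
    occ$residues$residue_occupancy_percent[occ$residues$residue == 1], 200)

  # partial occupancy: breaking 2 of 5 frames on one partner
  part <- hbond_occupancy(toy_hbond_trajectory(5, broken_frames = 2),
                          donors = 1L, acceptors = c(4L, 5L))
  expect_setequal(part$pairs$pair_occupancy_percent, c(100, 60))
  expect_equal(
    part$residues$residue_occupancy_percent[part$residues$residue == 1],
    160)
})

test_that("hbond occupancy is monotone in the cutoffs", {
  traj <- toy_hbond_trajectory(n_frames = 4)
  occ_at <- function(d, a) {
    o <- hbond_occupancy(traj, 1L, c(4L, 5L), hbond_criteria(d, a))
    sum(o$pairs$pair_occupancy_percent)
  }
  dists <- c(2.5, 3.0, 3.5, 4.0)
  angs <- c(5, 20, 45)
  for (a in angs) expect_true(!is.unsorted(vapply(dists, occ_at, 0, a = a)))
  for (d in dists) expect_true(!is.unsorted(vapply(angs, occ_at, 0, d = d)))
})

test_that("hbond occupancy validates its inputs", {
  traj <- toy_hbond_trajectory()
  expect_error(hbond_occupancy(traj, donors = 2L, acceptors = 4L),
               "no heavy atoms")  # a hydrogen cannot be the donor heavy atom
  expect_error(hbond_occupancy(traj, donors = 4L, acceptors = 5L),
               "hydrogen")        # oxygen 4 carries no H here
  expect_error(hbond_criteria(max_angle = 95), "max_angle")
  expect_error(hbond_criteria(max_distance = -1), "max_distance")
})

test_that("occupancy report writes the documented tab-separated columns", {
  occ <- hbond_occupancy(toy_hbond_trajectory(), 1L, c(4L, 5L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_occupancy(occ, f)
  tab <- utils::read.delim(f)
  expect_named(tab, c("donor_residue", "acceptor_residue",
                      "pair_occupancy_percent",
                      "residue_occupancy_percent"))
  expect_equal(nrow(tab), 2L)
})

test_that("unknown elements fall back to carbon mass with a warning", {
  expect_warning(m <- element_mass(c("C", "XX")), "unknown")
  expect_equal(m, c(12.011, 12.011))
  expect_equal(element_mass(c("N", "O")), c(14.007, 15.999))
})
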