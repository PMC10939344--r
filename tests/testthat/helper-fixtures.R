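# Fixtures are built in code at test time; nothing is stored on disk.

# A deterministic three-atom structure with one single-residue domain.
tiny_structure <- function() {
  atoms <- data.frame(
    serial = 1:3, name = c("N", "CA", "O"), element = c("N", "C", "O"),
    resid = c(1L, 1L, 2L), chain = "A",
    x = c(0, 2, 0), y = c(0, 0, 3), z = c(0, 0, 0),
    stringsAsFactors = FALSE)
  domain_structure(atoms, list(M = c(1L, 1L), X = c(2L, 2L)))
}

# Random energy matrix on the default axes.
rand_matrix <- function(rows, cols, seed, sd = 3) {
  set.seed(seed)
  energy_matrix(matrix(rnorm(rows * cols, sd = sd), rows, cols),
                rot_axis = seq(0, by = 5, length.out = rows),
                sep_axis = seq(9, by = 1, length.out = cols))
}

# Random rigid transform (proper rotation + translation).
rand_rigid <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 10))
}

apply_rigid <- function(xyz, rt) {
  sweep(xyz %*% t(rt$R), 2, rt$t, "+")
}

# Small two-domain system for scorer tests: one atom per domain.
point_pair_structure <- function(r = 1, q1 = 1, q2 = -1) {
  atoms <- data.frame(
    serial = 1:2, name = c("Q1", "Q2"), element = c("C", "C"),
    resid = c(1L, 2L), chain = "A",
    x = c(0, r), y = 0, z = 0, charge = c(q1, q2),
    stringsAsFactors = FALSE)
  domain_structure(atoms, list(a = c(1L, 1L), b = c(2L, 2L)))
}
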