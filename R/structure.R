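# Structures: atom tables partitioned into named domains.

# Atomic masses (amu) for the elements that occur in protein PDB files.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  CA = 40.078, MN = 54.938, `NA` = 22.990, K = 39.098, CL = 35.45
)

#' Look up atomic masses by element symbol
#'
#' Unknown elements fall back to the mass of carbon (12.011 amu) with a
#' warning, so that a structure with exotic heteroatoms still loads.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .element_masses[key]
  unknown <- is.na(m)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(key[unknown]), collapse = ", "),
            "; assigning 12.011 amu", call. = FALSE)
    m[unknown] <- 12.011
  }
  unname(m)
}

.normalize_domains <- function(domains) {
  if (is.null(domains) || length(domains) == 0L)
    stop("at least one domain must be defined", call. = FALSE)
  if (is.null(names(domains)) || any(!nzchar(names(domains))))
    stop("domains must be a named list of residue ranges", call. = FALSE)
  lapply(domains, function(rng) {
    if (is.numeric(rng) && length(rng) == 2L) rng <- matrix(rng, nrow = 1L)
    rng <- as.matrix(rng)
    if (ncol(rng) != 2L || any(rng[, 1L] > rng[, 2L]))
      stop("each domain range must be c(start, end) with start <= end",
           call. = FALSE)
    storage.mode(rng) <- "integer"
    colnames(rng) <- c("start", "end")
    rng
  })
}

#' Construct a domain-partitioned structure
#'
#' The central container of the package: an atom table (one row per atom,
#' in file order) plus a mapping from domain names to residue ranges
#' (1-based inclusive author numbering).  Domain ranges may not overlap
#' between domains, and every domain must select at least one atom.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resid` (integer residue number), `chain`, `x`, `y`, `z`, and
#'   optionally `mass` (amu; derived from `element` when absent) and
#'   `charge` (elementary charges; default 0).
#' @param domains named list; each entry a `c(start, end)` residue range or
#'   a two-column matrix of ranges.
#' @return object of class `domain_structure`.
#' @export
domain_structure <- function(atoms, domains) {
  required <- c("serial", "name", "element", "resid", "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("atom coordinates must all be finite", call. = FALSE)
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be positive and finite", call. = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- 0
  atoms$resid <- as.integer(atoms$resid)
  domains <- .normalize_domains(domains)

  covered <- lapply(domains, function(rng)
    unlist(lapply(seq_len(nrow(rng)), function(i) rng[i, 1L]:rng[i, 2L])))
  all_res <- unlist(covered)
  if (anyDuplicated(all_res))
    stop("domain residue ranges overlap", call. = FALSE)

  obj <- structure(list(atoms = atoms, domains = domains),
                   class = "domain_structure")
  for (d in names(domains)) {
    if (length(domain_atoms(obj, d)) == 0L)
      stop("domain '", d, "' selects zero atoms", call. = FALSE)
  }
  obj
}

#' Atom indices belonging to a domain
#'
#' @param structure a `domain_structure`.
#' @param domain domain name.
#' @return integer vector of row indices into `structure$atoms`.
#' @export
domain_atoms <- function(structure, domain) {
  stopifnot(inherits(structure, "domain_structure"))
  rng <- structure$domains[[domain]]
  if (is.null(rng))
    stop("unknown domain '", domain, "'", call. = FALSE)
  resid <- structure$atoms$resid
  keep <- rep(FALSE, length(resid))
  for (i in seq_len(nrow(rng)))
    keep <- keep | (resid >= rng[i, 1L] & resid <= rng[i, 2L])
  which(keep)
}

#' Atom coordinates as an N x 3 matrix
#'
#' @param structure a `domain_structure`.
#' @param index optional atom indices (default: all atoms).
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(structure, index = NULL) {
  m <- as.matrix(structure$atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  if (!is.null(index)) m <- m[index, , drop = FALSE]
  m
}

#' Replace atom coordinates
#'
#' @param structure a `domain_structure`.
#' @param xyz N x 3 matrix congruent with the atom table.
#' @return the modified structure.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(inherits(structure, "domain_structure"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(structure$atoms) || ncol(xyz) != 3L)
    stop("coordinate matrix must be ", nrow(structure$atoms), " x 3",
         call. = FALSE)
  structure$atoms$x <- xyz[, 1L]
  structure$atoms$y <- xyz[, 2L]
  structure$atoms$z <- xyz[, 3L]
  structure
}

#' @export
print.domain_structure <- function(x, ...) {
  cat("domain_structure:", nrow(x$atoms), "atoms,",
      length(x$domains), "domains\n")
  for (d in names(x$domains)) {
    rng <- x$domains[[d]]
    cat(sprintf("  %-8s residues %s  (%d atoms)\n", d,
                paste(apply(rng, 1L, function(r) paste(r, collapse = "-")),
                      collapse = ","),
                length(domain_atoms(x, d))))
  }
  invisible(x)
}

#' Read a PDB structure with a domain partition
#'
#' Wraps the bio3d PDB parser and attaches the domain partition, element
#' symbols and masses.  Residue numbers are taken as 1-based author
#' numbering; records carrying insertion codes are rejected because the
#' partition ranges would be ambiguous.
#'
#' @param path PDB file.
#' @param domains named list of residue ranges, e.g.
#'   `list(FERM = c(34, 420), SH2 = c(439, 544), PK = c(583, 855),
#'   TK = c(875, 1153))`.
#' @param charges optional numeric vector of per-atom partial charges
#'   (elementary charges), recycled to the atom count; default 0.
#' @return a [domain_structure()].
#' @export
read_structure <- function(path, domains, charges = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no ATOM records in '", path, "'", call. = FALSE)
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported; renumber residues first",
         call. = FALSE)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("malformed coordinate field in '", path, "'", call. = FALSE)
  element <- at$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  # fall back to the first letter of the atom name (toy files often omit
  # the element column)
  element[blank] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[blank])),
                           1L, 1L)
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = toupper(element),
    resid = as.integer(at$resno), chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  atoms$mass <- element_mass(atoms$element)
  atoms$charge <- if (is.null(charges)) 0 else rep_len(charges, nrow(atoms))
  domain_structure(atoms, domains)
}

#' Write a structure to a PDB file
#'
#' @param structure a `domain_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(structure))),
                   resno = a$resid, chain = a$chain,
                   resid = rep("GLY", nrow(a)),
                   eleno = a$serial, elety = a$name,
                   elesy = a$element)
  invisible(path)
}

#' Mass-weighted center of a domain
#'
#' @param structure a `domain_structure`.
#' @param domain domain name.
#' @param xyz optional replacement coordinates (N x 3, e.g. one trajectory
#'   frame); defaults to the structure's own coordinates.
#' @return numeric length-3 vector (x, y, z) in Angstrom.
#' @export
center_of_mass <- function(structure, domain, xyz = NULL) {
  idx <- domain_atoms(structure, domain)
  if (length(idx) == 0L)
    stop("domain '", domain, "' selects zero atoms", call. = FALSE)
  m <- structure$atoms$mass[idx]
  p <- if (is.null(xyz)) coords(structure, idx) else xyz[idx, , drop = FALSE]
  drop(crossprod(p, m)) / sum(m)
}
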