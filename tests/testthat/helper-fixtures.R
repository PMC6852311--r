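# shared fixtures, built once per test run (scaffold construction solves
# several small optimisation problems, so the heavyweight objects are
# cached in this environment)
.fx <- new.env()

fx_config <- function() {
  if (is.null(.fx$cfg)) .fx$cfg <- default_config()
  .fx$cfg
}

fx_acceptor <- function() {
  if (is.null(.fx$acc)) .fx$acc <- make_acceptor(fx_config(), seed = 2L)
  .fx$acc
}

fx_scaffold <- function() {
  if (is.null(.fx$scaf)) .fx$scaf <- make_scaffold(seed = 1L)
  .fx$scaf
}

fx_library <- function() {
  if (is.null(.fx$lib)) .fx$lib <- make_donor_library(fx_config(), seed = 1L)
  .fx$lib
}

fx_grid <- function() {
  if (is.null(.fx$grid)) .fx$grid <- make_labeled_grid(fx_config(), seed = 1L)
  .fx$grid
}

fx_ensemble <- function() {
  if (is.null(.fx$man)) {
    .fx$ens_dir <- file.path(tempdir(), "dfgout_fx_ensemble")
    .fx$man <- suppressWarnings(build_ensemble(
      reference_profile()$sequence, fx_acceptor(), fx_library(),
      fx_config(), out_dir = .fx$ens_dir))
  }
  .fx$man
}

fx_ensemble_dir <- function() {
  fx_ensemble()
  .fx$ens_dir
}

# independent dihedral oracle: acos of the plane-normal angle with the
# sign taken from the scalar triple product (distinct formulation from
# the package's atan2 kernel)
oracle_dihedral <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2]*b[3] - a[3]*b[2],
                            a[3]*b[1] - a[1]*b[3],
                            a[1]*b[2] - a[2]*b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(max(-1, min(1, cosphi))) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) phi <- -phi
  dfgout::wrap_angle(phi)
}

random_rigid <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = stats::runif(3, -10, 10))
}

transform_domain <- function(domain, tr) {
  xyz <- apply_transform(as.matrix(domain$atoms[, c("x", "y", "z")]), tr)
  domain$atoms$x <- xyz[, 1]; domain$atoms$y <- xyz[, 2]
  domain$atoms$z <- xyz[, 3]
  domain
}

# minimal hand-written PDB text fixture
pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          occ = 1, b = 0, altloc = " ", icode = " ") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", name), altloc, resname, chain, resno,
          icode, xyz[1], xyz[2], xyz[3], occ, b, substr(name, 1, 1))
}

write_mini_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

# three-residue chain fixture (ALA-GLY-ASP) with full backbone
mini_residue_lines <- function(resno, resname, origin, chain = "A",
                               serial0 = 0) {
  nm <- c("N", "CA", "C", "O")
  offs <- list(c(0, 0, 0), c(1.46, 0, 0), c(2.0, 1.4, 0), c(1.5, 2.4, 0))
  vapply(seq_along(nm), function(i) {
    pdb_atom_line(serial0 + i, nm[i], resname, chain, resno,
                  origin + offs[[i]])
  }, character(1))
}
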