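#' Geometric kernel: dihedrals, pseudotorsions, distances and superposition
#'
#' All angles are reported in degrees in the range (-180, 180] with the
#' IUPAC sign convention (cis = 0, trans = +/-180); distances are in
#' Angstrom. Domain-level operations address residues by their reference
#' (1ATP) IDs and raise informative errors naming the missing atom when a
#' required coordinate is absent.
#'
#' @name geometry
NULL

# numeric guards shared across the package
.EPS_DEGENERATE <- 1e-10

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < .EPS_DEGENERATE) stop("zero-length vector cannot be normalised")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap an angle in degrees into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Dihedral angle over four points
#'
#' Torsion about the p2->p3 axis, degrees in (-180, 180]. Errors when the
#' first or last three points are collinear (the angle is then undefined).
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (.vnorm(b2) < .EPS_DEGENERATE) {
    stop("undefined dihedral: central axis p2->p3 has zero length")
  }
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (.vnorm(n1) < .EPS_DEGENERATE || .vnorm(n2) < .EPS_DEGENERATE) {
    stop("undefined dihedral: collinear points")
  }
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- -sum(m1 * n2)  # IUPAC sign (matches the plane-normal triple product)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Planar angle at p2 between p1 and p3, in degrees
#' @noRd
.planar_angle <- function(p1, p2, p3) {
  u <- .unit(p1 - p2)
  v <- .unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Returns the point X with |X - p3| = bond, angle(p2, p3, X) = angle and
#' dihedral_angle(p1, p2, p3, X) = torsion. Used by the scaffold generator
#' and for analytic side-chain placement.
#'
#' @param p1,p2,p3 numeric 3-vectors defining the frame.
#' @param bond bond length, Angstrom.
#' @param angle planar angle at p3, degrees.
#' @param torsion dihedral (p1, p2, p3, X), degrees.
#' @return numeric 3-vector.
#' @export
place_atom <- function(p1, p2, p3, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(p3 - p2)
  n <- .unit(.cross(p2 - p1, bc))
  m <- .cross(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  p3 + d[1] * bc + d[2] * m + d[3] * n
}

# --- domain-level feature geometry ------------------------------------------

.require_coord <- function(domain, ref_id, elety, what = elety) {
  xyz <- domain_atom_coord(domain, ref_id, elety)
  if (is.null(xyz)) {
    stop(sprintf("missing %s at reference %d", what, ref_id), call. = FALSE)
  }
  xyz
}

#' C-alpha pseudotorsion over four consecutive reference IDs
#'
#' Dihedral over the C-alpha atoms of residues `start_id` .. `start_id + 3`
#' in reference numbering. This is the xi-type observable used by the
#' A-loop and P-loop classifiers.
#'
#' @param domain a `numbered_domain`.
#' @param start_id first reference ID of the four-residue window.
#' @return angle in degrees.
#' @export
ca_pseudotorsion <- function(domain, start_id) {
  ids <- start_id + 0:3
  cas <- lapply(ids, function(i) .require_coord(domain, i, "CA"))
  dihedral_angle(cas[[1]], cas[[2]], cas[[3]], cas[[4]])
}

#' Backbone psi dihedral at a reference ID
#'
#' Standard psi: N(i), CA(i), C(i), N(i+1).
#'
#' @inheritParams ca_pseudotorsion
#' @param id reference ID of the residue.
#' @return angle in degrees.
#' @export
backbone_psi <- function(domain, id) {
  dihedral_angle(.require_coord(domain, id, "N"),
                 .require_coord(domain, id, "CA"),
                 .require_coord(domain, id, "C"),
                 .require_coord(domain, id + 1L, "N"))
}

#' C-alpha to C-alpha distance between two reference IDs
#'
#' @inheritParams backbone_psi
#' @param id_a,id_b reference IDs.
#' @return distance in Angstrom.
#' @export
ca_distance <- function(domain, id_a, id_b) {
  a <- .require_coord(domain, id_a, "CA")
  b <- .require_coord(domain, id_b, "CA")
  .vnorm(a - b)
}

#' Minimal distance between two named atom sets on two residues
#'
#' Minimum over the cross product of the atoms found; used e.g. for the
#' Lys72 NZ to Glu91 OE1/OE2 salt-bridge criterion. Errors when no named
#' atom is present on one side.
#'
#' @inheritParams backbone_psi
#' @param id_a,id_b reference IDs.
#' @param atoms_a,atoms_b character vectors of atom names.
#' @return distance in Angstrom.
#' @export
min_atom_distance <- function(domain, id_a, atoms_a, id_b, atoms_b) {
  ca <- Filter(Negate(is.null),
               lapply(atoms_a, function(n) domain_atom_coord(domain, id_a, n)))
  cb <- Filter(Negate(is.null),
               lapply(atoms_b, function(n) domain_atom_coord(domain, id_b, n)))
  if (length(ca) == 0) {
    stop(sprintf("missing atoms {%s} at reference %d",
                 paste(atoms_a, collapse = ","), id_a), call. = FALSE)
  }
  if (length(cb) == 0) {
    stop(sprintf("missing atoms {%s} at reference %d",
                 paste(atoms_b, collapse = ","), id_b), call. = FALSE)
  }
  min(vapply(ca, function(a) {
    min(vapply(cb, function(b) .vnorm(a - b), numeric(1)))
  }, numeric(1)))
}

# chi dihedral atom quadruples per residue type, chi1..chi4
.CHI_ATOMS <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

#' Side-chain chi dihedral of a residue
#'
#' Standard chi atom quadruples per residue type (chi1 = N-CA-CB-XG, ...).
#' Errors for residues without the requested chi (e.g. Gly, Ala) or when a
#' defining atom is missing.
#'
#' @inheritParams backbone_psi
#' @param id reference ID of the residue.
#' @param chi_index which chi (1-4).
#' @return angle in degrees.
#' @export
sidechain_chi <- function(domain, id, chi_index = 1L) {
  resname <- domain_residue_name(domain, id)
  if (is.null(resname)) stop(sprintf("no residue at reference %d", id), call. = FALSE)
  quads <- .CHI_ATOMS[[resname]]
  if (is.null(quads) || chi_index > length(quads)) {
    stop(sprintf("no sidechain chi%d for %s at reference %d",
                 chi_index, resname, id), call. = FALSE)
  }
  q <- quads[[chi_index]]
  pts <- lapply(q, function(n) .require_coord(domain, id, n))
  dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}

# --- superposition -----------------------------------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation mapping `mobile` onto
#' `reference` (paired rows). The rotation determinant is constrained to
#' +1, so reflected inputs fit with a positive residual rather than an
#' improper rotation.
#'
#' @param mobile,reference n x 3 matrices of paired coordinates, n >= 3.
#' @return a `superposition_result`: list with `rotation` (3x3),
#'   `translation` (length 3; transformed = coords %*% t(R) + t), `rmsd`
#'   and `n_atoms`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be equal-size n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) stop("superposition requires at least 3 paired atoms")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm)
  b <- sweep(reference, 2, cr)
  if (max(svd(a)$d) < .EPS_DEGENERATE || svd(a)$d[2] < .EPS_DEGENERATE) {
    stop("degenerate (collinear or coincident) coordinate set")
  }
  h <- t(a) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  structure(list(rotation = rot, translation = trans,
                 rmsd = rmsd, n_atoms = n),
            class = "superposition_result")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix or length-3 vector.
#' @param transform a `superposition_result` (or list with `rotation`,
#'   `translation`).
#' @return transformed coordinates, same shape as input.
#' @export
apply_transform <- function(coords, transform) {
  if (is.null(dim(coords))) {
    as.vector(transform$rotation %*% coords) + transform$translation
  } else {
    sweep(coords %*% t(transform$rotation), 2, transform$translation, `+`)
  }
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("Superposition: %d atoms, rmsd %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Backbone RMSD between two numbered domains over a reference-ID set
#'
#' Uses N, CA, C, O of every requested reference ID present with a complete
#' backbone in both domains; IDs missing on either side are dropped (and
#' reported via the `dropped_ids` attribute). With `fit = TRUE` the domains
#' are first superposed on the same selection.
#'
#' @param domain_a,domain_b `numbered_domain` objects.
#' @param id_set integer vector of reference IDs; default: all shared IDs.
#' @param fit superpose before measuring (default TRUE).
#' @return RMSD in Angstrom, with attribute `dropped_ids`.
#' @export
backbone_rmsd <- function(domain_a, domain_b, id_set = NULL, fit = TRUE) {
  if (is.null(id_set)) {
    id_set <- intersect(domain_reference_ids(domain_a),
                        domain_reference_ids(domain_b))
  }
  bb <- c("N", "CA", "C", "O")
  keep <- logical(length(id_set))
  xa <- list(); xb <- list()
  for (k in seq_along(id_set)) {
    ca <- lapply(bb, function(n) domain_atom_coord(domain_a, id_set[k], n))
    cb <- lapply(bb, function(n) domain_atom_coord(domain_b, id_set[k], n))
    if (!any(vapply(ca, is.null, logical(1))) &&
        !any(vapply(cb, is.null, logical(1)))) {
      keep[k] <- TRUE
      xa[[length(xa) + 1]] <- do.call(rbind, ca)
      xb[[length(xb) + 1]] <- do.call(rbind, cb)
    }
  }
  if (!any(keep)) stop("no common reference IDs with complete backbone")
  a <- do.call(rbind, xa)
  b <- do.call(rbind, xb)
  if (fit) {
    sp <- superpose(a, b)
    val <- sp$rmsd
  } else {
    val <- sqrt(mean(rowSums((a - b)^2)))
  }
  attr(val, "dropped_ids") <- id_set[!keep]
  val
}
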