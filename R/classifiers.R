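#' Conformational classifiers
#'
#' Assigns the four element classes of a kinase catalytic domain:
#' DFG \{in, out\}, A-loop \{closed type 2, open DFG-out, closed
#' A-under-P\}, P-loop \{collapsed, stretched\} and alphaC-helix
#' \{in, inter, out\}. All classifiers are pure functions of a
#' [compute_features()] vector plus a configuration of intervals; every
#' assignment carries its evidence and every non-assignment a
#' machine-readable reason.
#'
#' @name classifiers
NULL

# absolute guard for boundary comparisons, so values posed exactly on an
# inclusive threshold (e.g. d = 4.0) classify deterministically despite
# floating-point rounding
.BOUNDARY_EPS <- 1e-9

.in_interval <- function(x, iv) {
  x >= iv[1] - .BOUNDARY_EPS & x <= iv[2] + .BOUNDARY_EPS
}

.FEATURE_NAMES <- c("xi_dfg_m1_d", "xi_dfg_f_g", "d_hrd_m4__dfg_p3",
                    "psi_gmotif_m1", "psi_gmotif_p1", "xi_gmotif_p1_p2",
                    "d_phi__hrd_p4", "d_lys_glu", "chi_glu",
                    "dfg_pseudodihedral")

.try_feature <- function(expr) {
  tryCatch(list(value = expr, note = NA_character_),
           error = function(e) list(value = NA_real_,
                                    note = conditionMessage(e)))
}

# centroid of the delta atoms of the DFG-Asp side chain (OD1/OD2 for Asp;
# generic delta names for noncanonical residues)
.delta_centroid <- function(domain, ref_id) {
  at <- domain$atoms
  i <- which(at$ref_id == ref_id &
               at$name %in% c("OD1", "OD2", "CD", "CD1", "CD2", "ND1",
                              "ND2", "SD", "OG", "OG1"))
  i <- i[substr(at$name[i], 2, 2) == "D"]
  if (length(i) == 0) return(NULL)
  c(mean(at$x[i]), mean(at$y[i]), mean(at$z[i]))
}

#' Compute all classifier observables of a numbered domain
#'
#' Pure function of the coordinates. Features whose defining atoms are
#' absent are flagged unavailable (with the reason), never silently NaN.
#'
#' @param domain a `numbered_domain`.
#' @param config a validated configuration (default [default_config()]).
#' @return a `kinase_features` object: named `values`, logical
#'   `available`, and `notes`.
#' @export
compute_features <- function(domain, config = default_config()) {
  w <- config$aloop$windows
  f <- list(
    xi_dfg_m1_d = .try_feature(ca_pseudotorsion(domain, w$xi_dfg_m1_d)),
    xi_dfg_f_g = .try_feature(ca_pseudotorsion(domain, w$xi_dfg_f_g)),
    d_hrd_m4__dfg_p3 = .try_feature(ca_distance(domain, 160L, 189L)),
    psi_gmotif_m1 = .try_feature(backbone_psi(domain, 49L)),
    psi_gmotif_p1 = .try_feature(backbone_psi(domain, 56L)),
    xi_gmotif_p1_p2 = .try_feature(ca_pseudotorsion(domain, 55L)),
    d_phi__hrd_p4 = .try_feature(ca_distance(domain, 54L, 170L)),
    d_lys_glu = .try_feature(min_atom_distance(domain, 72L, "NZ",
                                               91L, c("OE1", "OE2"))),
    chi_glu = .try_feature(sidechain_chi(domain, 91L,
                                         config$alphac$chi_index)),
    dfg_pseudodihedral = .try_feature({
      ca_m1 <- .require_coord(domain, 183L, "CA")
      ca <- .require_coord(domain, 184L, "CA")
      cg <- .require_coord(domain, 184L, "CG", "CG (DFG pseudodihedral)")
      dc <- .delta_centroid(domain, 184L)
      if (is.null(dc)) stop("missing delta atoms at reference 184")
      dihedral_angle(ca_m1, ca, cg, dc)
    }))
  values <- vapply(f, function(x) x$value, numeric(1))
  notes <- vapply(f, function(x) x$note, character(1))
  structure(list(values = values, available = !is.na(values), notes = notes),
            class = "kinase_features")
}

#' Build a feature vector directly from values
#'
#' Mainly for classifier-level tests and threshold scans: any feature not
#' supplied is marked unavailable.
#'
#' @param ... named feature values (see [compute_features()] for names).
#' @return a `kinase_features` object.
#' @export
feature_vector <- function(...) {
  given <- list(...)
  bad <- setdiff(names(given), .FEATURE_NAMES)
  if (length(bad) > 0) {
    stop(sprintf("unknown feature(s): %s", paste(bad, collapse = ", ")))
  }
  values <- stats::setNames(rep(NA_real_, length(.FEATURE_NAMES)),
                            .FEATURE_NAMES)
  values[names(given)] <- unlist(given)
  structure(list(values = values, available = !is.na(values),
                 notes = stats::setNames(rep(NA_character_,
                                             length(.FEATURE_NAMES)),
                                         .FEATURE_NAMES)),
            class = "kinase_features")
}

#' @export
print.kinase_features <- function(x, ...) {
  cat("kinase_features:\n")
  for (n in names(x$values)) {
    cat(sprintf("  %-18s %s\n", n,
                if (x$available[n]) sprintf("%10.3f", x$values[n])
                else sprintf("unavailable (%s)", x$notes[n])))
  }
  invisible(x)
}

.unassigned <- function(reason) {
  list(class = "unassigned", reason = reason, evidence = NULL)
}

#' Classify the DFG state
#'
#' "out" iff the DFG pseudodihedral lies in the configured out-interval,
#' "in" iff in the in-interval, otherwise unassigned.
#'
#' @param fv a `kinase_features` vector.
#' @param config validated configuration.
#' @return list: `class`, `reason` (for unassigned), `evidence`.
#' @export
classify_dfg <- function(fv, config = default_config()) {
  if (!fv$available[["dfg_pseudodihedral"]]) {
    return(.unassigned(paste0("dfg_pseudodihedral unavailable: ",
                              fv$notes[["dfg_pseudodihedral"]])))
  }
  x <- fv$values[["dfg_pseudodihedral"]]
  cls <- if (.in_interval(x, config$dfg$out_interval)) "out"
  else if (.in_interval(x, config$dfg$in_interval)) "in"
  else "unassigned"
  list(class = cls,
       reason = if (cls == "unassigned") "pseudodihedral between intervals" else NA,
       evidence = list(dfg_pseudodihedral = x))
}

#' Classify the alphaC-helix state
#'
#' d <= 4 A: in; d >= 8.5 A: out; in between, the Glu chi dihedral decides
#' (inter if chi <= 100 deg, in otherwise). Thresholds from config.
#'
#' @inheritParams classify_dfg
#' @export
classify_alphac <- function(fv, config = default_config()) {
  a <- config$alphac
  if (!fv$available[["d_lys_glu"]]) {
    return(.unassigned(paste0("d_lys_glu unavailable: ",
                              fv$notes[["d_lys_glu"]])))
  }
  d <- fv$values[["d_lys_glu"]]
  if (d <= a$d_in_max + .BOUNDARY_EPS) {
    return(list(class = "in", reason = NA, evidence = list(d_lys_glu = d)))
  }
  if (d >= a$d_out_min - .BOUNDARY_EPS) {
    return(list(class = "out", reason = NA, evidence = list(d_lys_glu = d)))
  }
  if (!fv$available[["chi_glu"]]) {
    return(.unassigned("chi needed: d in intermediate band but chi_glu unavailable"))
  }
  chi <- fv$values[["chi_glu"]]
  cls <- if (chi <= a$chi_inter_max + .BOUNDARY_EPS) "inter" else "in"
  list(class = cls, reason = NA,
       evidence = list(d_lys_glu = d, chi_glu = chi))
}

#' Classify the P-loop state
#'
#' Counts, for each class, how many of the four conditions
#' (psi_G-motif-1, psi_G-motif+1, xi_G-motif\{+1,+2\}, Phi54-HRD+4
#' distance) fall inside that class's intervals. A class is assigned iff
#' its count reaches `min_conditions` (default 3 of 4) and strictly
#' exceeds the other class's count; qualifying ties are ambiguous.
#'
#' @inheritParams classify_dfg
#' @export
classify_ploop <- function(fv, config = default_config()) {
  feat <- c("psi_gmotif_m1", "psi_gmotif_p1", "xi_gmotif_p1_p2",
            "d_phi__hrd_p4")
  avail <- fv$available[feat]
  if (sum(avail) < 3) {
    return(.unassigned(sprintf("only %d of 4 P-loop features available",
                               sum(avail))))
  }
  classes <- names(config$ploop$classes)
  counts <- vapply(classes, function(cl) {
    sum(vapply(feat[avail], function(f) {
      .in_interval(fv$values[[f]], config$ploop$classes[[cl]][[f]])
    }, logical(1)))
  }, integer(1))
  fired <- lapply(classes, function(cl) {
    feat[avail][vapply(feat[avail], function(f)
      .in_interval(fv$values[[f]], config$ploop$classes[[cl]][[f]]),
      logical(1))]
  })
  names(fired) <- classes
  mc <- config$ploop$min_conditions
  qualifying <- counts >= mc
  ev <- list(values = fv$values[feat], counts = counts, fired = fired)
  if (!any(qualifying)) {
    return(list(class = "unassigned",
                reason = sprintf("no class reaches %d of 4 conditions", mc),
                evidence = ev))
  }
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    return(list(class = "unassigned", reason = "ambiguous: equal qualifying counts",
                evidence = ev))
  }
  if (!qualifying[best]) {
    return(list(class = "unassigned",
                reason = sprintf("no class reaches %d of 4 conditions", mc),
                evidence = ev))
  }
  list(class = classes[best], reason = NA, evidence = ev)
}

#' Classify the A-loop state
#'
#' Each class is a conjunction of two pseudotorsion intervals
#' (xi_DFG\{-1,D\}, xi_DFG\{F,G\}) and one C-alpha distance interval
#' (HRD-4 to DFG+3). Config validation guarantees the class boxes are
#' mutually exclusive, so at most one class matches.
#'
#' @inheritParams classify_dfg
#' @export
classify_aloop <- function(fv, config = default_config()) {
  feat <- c("xi_dfg_m1_d", "xi_dfg_f_g", "d_hrd_m4__dfg_p3")
  if (!all(fv$available[feat])) {
    miss <- feat[!fv$available[feat]]
    return(.unassigned(sprintf("feature(s) unavailable: %s",
                               paste(miss, collapse = ", "))))
  }
  for (cl in names(config$aloop$classes)) {
    box <- config$aloop$classes[[cl]]
    if (all(vapply(feat, function(f)
      .in_interval(fv$values[[f]], box[[f]]), logical(1)))) {
      return(list(class = cl, reason = NA, evidence = as.list(fv$values[feat])))
    }
  }
  list(class = "unassigned", reason = "no A-loop class box matches",
       evidence = as.list(fv$values[feat]))
}

#' Composite conformational classification of a domain
#'
#' Runs all four element classifiers; A-loop, P-loop and alphaC are
#' classified regardless of the DFG state, and the DFG label is always
#' reported alongside.
#'
#' @param domain a `numbered_domain`.
#' @param config validated configuration.
#' @return a `conformation_label`: `dfg`, `aloop`, `ploop`, `alphac`
#'   (strings), `features`, `evidence` (per element).
#' @export
classify_structure <- function(domain, config = default_config()) {
  fv <- compute_features(domain, config)
  classify_features(fv, config)
}

#' Classify a precomputed feature vector
#'
#' @param fv a `kinase_features` vector.
#' @param config validated configuration.
#' @return a `conformation_label`.
#' @export
classify_features <- function(fv, config = default_config()) {
  el <- list(dfg = classify_dfg(fv, config),
             aloop = classify_aloop(fv, config),
             ploop = classify_ploop(fv, config),
             alphac = classify_alphac(fv, config))
  structure(list(dfg = el$dfg$class, aloop = el$aloop$class,
                 ploop = el$ploop$class, alphac = el$alphac$class,
                 features = fv, evidence = el),
            class = "conformation_label")
}

#' @export
print.conformation_label <- function(x, ...) {
  cat(sprintf("conformation: dfg=%s aloop=%s ploop=%s alphac=%s\n",
              x$dfg, x$aloop, x$ploop, x$alphac))
  invisible(x)
}
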