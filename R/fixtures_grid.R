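#' Labelled scaffold grids and synthetic donor libraries
#'
#' Built on [make_scaffold()]: poses are taken at the midpoints of the
#' configured class intervals, so the generating label and the classifier
#' output agree by construction, plus boundary and unassigned-band
#' members that pin the inclusive thresholds.
#'
#' @name fixtures_grid
NULL

.mid <- function(iv) (iv[1] + iv[2]) / 2

.alphac_pose <- function(cls) {
  switch(cls,
         "in" = list(d_lys_glu = 3.0, chi_glu = 120),
         "inter" = list(d_lys_glu = 6.25, chi_glu = 50),
         "out" = list(d_lys_glu = 9.5, chi_glu = 120))
}

.ploop_pose <- function(cls, config) {
  box <- config$ploop$classes[[cls]]
  list(psi_gmotif_m1 = .mid(box$psi_gmotif_m1),
       psi_gmotif_p1 = .mid(box$psi_gmotif_p1),
       xi_gmotif_p1_p2 = .mid(box$xi_gmotif_p1_p2),
       d_phi__hrd_p4 = .mid(box$d_phi__hrd_p4))
}

.aloop_pose <- function(cls, config) {
  box <- config$aloop$classes[[cls]]
  list(xi_dfg_m1_d = .mid(box$xi_dfg_m1_d),
       xi_dfg_f_g = .mid(box$xi_dfg_f_g),
       d_hrd_m4__dfg_p3 = .mid(box$d_hrd_m4__dfg_p3))
}

#' Labelled scaffold grid covering all 2 x 3 x 3 class combinations
#'
#' Eighteen DFG-out scaffolds posed at class-interval midpoints, plus
#' boundary members (alphaC distances exactly at 4.0 and 8.5 Angstrom,
#' chi exactly at 100 degrees) and one unassigned-band member per
#' element. The attached labels are the generating classes, computed
#' from the intervals, not from the classifiers.
#'
#' @param config validated configuration.
#' @param seed integer base seed.
#' @return list of entries `list(domain, label, pose, kind)`; `kind` is
#'   "grid", "boundary" or "unassigned_band".
#' @export
make_labeled_grid <- function(config = default_config(), seed = 1L) {
  entries <- list()
  k <- 0L
  dfg_out_mid <- .mid(config$dfg$out_interval)
  for (pl in .PLOOP_CLASSES) {
    for (ac in .ALPHAC_CLASSES) {
      for (al in .ALOOP_CLASSES) {
        k <- k + 1L
        pose <- c(.aloop_pose(al, config), .ploop_pose(pl, config),
                  .alphac_pose(ac), list(dfg_pseudodihedral = dfg_out_mid))
        dom <- make_scaffold(pose, seed = seed * 1000L + k,
                             name = sprintf("grid_%02d", k), config = config)
        entries[[length(entries) + 1]] <- list(
          domain = dom,
          label = list(dfg = "out", aloop = al, ploop = pl, alphac = ac),
          pose = pose, kind = "grid")
      }
    }
  }
  a <- config$alphac
  boundary <- list(
    list(pose = list(d_lys_glu = a$d_in_max, chi_glu = 120),
         label = list(alphac = "in"), note = "d at in-boundary (inclusive)"),
    list(pose = list(d_lys_glu = a$d_out_min, chi_glu = 120),
         label = list(alphac = "out"), note = "d at out-boundary (inclusive)"),
    list(pose = list(d_lys_glu = 6.0, chi_glu = a$chi_inter_max),
         label = list(alphac = "inter"), note = "chi at boundary (inclusive)"))
  for (b in boundary) {
    k <- k + 1L
    dom <- make_scaffold(b$pose, seed = seed * 1000L + k,
                         name = sprintf("boundary_%02d", k), config = config)
    lab <- list(dfg = "in", aloop = "open_dfg_out", ploop = "stretched",
                alphac = b$label$alphac)
    entries[[length(entries) + 1]] <- list(domain = dom, label = lab,
                                           pose = b$pose, kind = "boundary")
  }
  # unassigned bands: dfg between intervals; aloop distance between boxes;
  # ploop features outside both class boxes
  unas <- list(
    list(pose = list(dfg_pseudodihedral = 0),
         label = list(dfg = "unassigned", aloop = "open_dfg_out",
                      ploop = "stretched", alphac = "in")),
    list(pose = c(list(xi_dfg_m1_d = .mid(config$aloop$classes$open_dfg_out$xi_dfg_m1_d),
                       xi_dfg_f_g = .mid(config$aloop$classes$open_dfg_out$xi_dfg_f_g),
                       d_hrd_m4__dfg_p3 = config$aloop$classes$open_dfg_out$d_hrd_m4__dfg_p3[1] - 0.5)),
         label = list(dfg = "in", aloop = "unassigned", ploop = "stretched",
                      alphac = "in")),
    list(pose = list(psi_gmotif_m1 = 50, psi_gmotif_p1 = 50,
                     xi_gmotif_p1_p2 = 70, d_phi__hrd_p4 = 16.5),
         label = list(dfg = "in", aloop = "open_dfg_out",
                      ploop = "unassigned", alphac = "in")))
  for (u in unas) {
    k <- k + 1L
    dom <- make_scaffold(u$pose, seed = seed * 1000L + k,
                         name = sprintf("unassigned_%02d", k),
                         config = config)
    entries[[length(entries) + 1]] <- list(domain = dom, label = u$label,
                                           pose = u$pose,
                                           kind = "unassigned_band")
  }
  entries
}

#' Synthetic donor library (6 N-lobe + 3 A-loop donors)
#'
#' All donors are DFG-out scaffolds posed at class midpoints; the library
#' passes [validate_donor_library()] by construction.
#'
#' @param config validated configuration.
#' @param seed integer base seed.
#' @return a `donor_library`.
#' @export
make_donor_library <- function(config = default_config(), seed = 1L) {
  dfg_out_mid <- .mid(config$dfg$out_interval)
  nlobe <- list()
  k <- 0L
  for (pl in .PLOOP_CLASSES) {
    for (ac in .ALPHAC_CLASSES) {
      k <- k + 1L
      key <- paste(pl, ac, sep = "/")
      pose <- c(.ploop_pose(pl, config), .alphac_pose(ac),
                list(dfg_pseudodihedral = dfg_out_mid))
      nlobe[[key]] <- list(
        domain = make_scaffold(pose, seed = seed * 100L + k,
                               name = sprintf("nlobe_%s_%s", pl, ac),
                               config = config),
        ploop = pl, alphac = ac,
        id = sprintf("synthetic:nlobe:%s", key))
    }
  }
  aloop <- list()
  for (al in .ALOOP_CLASSES) {
    k <- k + 1L
    pose <- c(.aloop_pose(al, config), list(dfg_pseudodihedral = dfg_out_mid))
    aloop[[al]] <- list(
      domain = make_scaffold(pose, seed = seed * 100L + k,
                             name = sprintf("aloop_%s", al),
                             config = config),
      aloop = al, id = sprintf("synthetic:aloop:%s", al))
  }
  donor_library(nlobe, aloop, config)
}

#' Synthetic DFG-in acceptor scaffold
#'
#' The default scaffold pose: DFG-in, alphaC-in, stretched P-loop, open
#' A-loop.
#'
#' @param config validated configuration.
#' @param seed integer seed.
#' @return a `numbered_domain`.
#' @export
make_acceptor <- function(config = default_config(), seed = 1L) {
  make_scaffold(list(), seed = seed, name = "synthetic_acceptor",
                config = config)
}
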