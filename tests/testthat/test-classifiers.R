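test_that("alphaC classifier reproduces the published thresholds", {
  cfg <- fx_config()
  cases <- list(
    list(d = 3.5, chi = NA, expect = "in"),
    list(d = 9.0, chi = NA, expect = "out"),
    list(d = 6.0, chi = 90, expect = "inter"),
    list(d = 6.0, chi = 120, expect = "in"),
    list(d = 4.0, chi = NA, expect = "in"),      # boundary inclusive
    list(d = 8.5, chi = NA, expect = "out"),     # boundary inclusive
    list(d = 6.0, chi = 100, expect = "inter"))  # chi boundary inclusive
  for (cs in cases) {
    fv <- if (is.na(cs$chi)) feature_vector(d_lys_glu = cs$d)
    else feature_vector(d_lys_glu = cs$d, chi_glu = cs$chi)
    expect_equal(classify_alphac(fv, cfg)$class, cs$expect,
                 info = sprintf("d=%s chi=%s", cs$d, cs$chi))
  }
  # unavailability handling
  expect_equal(classify_alphac(feature_vector(chi_glu = 90), cfg)$class,
               "unassigned")
  res <- classify_alphac(feature_vector(d_lys_glu = 6), cfg)
  expect_equal(res$class, "unassigned")
  expect_match(res$reason, "chi needed")
})

test_that("alphaC class is a monotone step function of the salt-bridge distance", {
  cfg <- fx_config()
  ds <- seq(2, 10, by = 0.01)
  cls <- vapply(ds, function(d) {
    classify_alphac(feature_vector(d_lys_glu = d, chi_glu = 90), cfg)$class
  }, character(1))
  # exactly two change points, in the right order
  changes <- which(cls[-1] != cls[-length(cls)])
  expect_equal(length(changes), 2)
  expect_equal(unique(cls), c("in", "inter", "out"))
  expect_equal(ds[changes[1]], 4.00, tolerance = 0.011)
  expect_equal(ds[changes[2] + 1], 8.50, tolerance = 0.011)
})

test_that("P-loop rule counts conditions and requires a strict majority class", {
  cfg <- fx_config()
  st <- cfg$ploop$classes$stretched
  co <- cfg$ploop$classes$collapsed
  mid <- function(iv) (iv[1] + iv[2]) / 2
  # all four collapsed conditions -> collapsed
  fv4 <- feature_vector(psi_gmotif_m1 = mid(co$psi_gmotif_m1),
                        psi_gmotif_p1 = mid(co$psi_gmotif_p1),
                        xi_gmotif_p1_p2 = mid(co$xi_gmotif_p1_p2),
                        d_phi__hrd_p4 = mid(co$d_phi__hrd_p4))
  expect_equal(classify_ploop(fv4, cfg)$class, "collapsed")
  # exactly three stretched conditions (distance off) -> stretched
  fv3 <- feature_vector(psi_gmotif_m1 = mid(st$psi_gmotif_m1),
                        psi_gmotif_p1 = mid(st$psi_gmotif_p1),
                        xi_gmotif_p1_p2 = mid(st$xi_gmotif_p1_p2),
                        d_phi__hrd_p4 = st$d_phi__hrd_p4[2] + 5)
  r3 <- classify_ploop(fv3, cfg)
  expect_equal(r3$class, "stretched")
  expect_equal(length(r3$evidence$fired$stretched), 3)
  # two conditions only -> unassigned
  fv2 <- feature_vector(psi_gmotif_m1 = mid(st$psi_gmotif_m1),
                        psi_gmotif_p1 = mid(st$psi_gmotif_p1),
                        xi_gmotif_p1_p2 = mid(co$xi_gmotif_p1_p2) ,
                        d_phi__hrd_p4 = (co$d_phi__hrd_p4[2] +
                                           st$d_phi__hrd_p4[1]) / 2)
  expect_equal(classify_ploop(fv2, cfg)$class, "unassigned")
  # more than one feature unavailable -> unassigned
  fvna <- feature_vector(psi_gmotif_m1 = mid(st$psi_gmotif_m1),
                         psi_gmotif_p1 = mid(st$psi_gmotif_p1))
  expect_equal(classify_ploop(fvna, cfg)$class, "unassigned")
})

test_that("overlapping P-loop class boxes with equal counts are ambiguous", {
  cfg <- fx_config()
  cfg2 <- unclass(cfg)
  cfg2$ploop$classes$stretched <- cfg2$ploop$classes$collapsed
  cfg2 <- validate_config(cfg2)
  co <- cfg2$ploop$classes$collapsed
  mid <- function(iv) (iv[1] + iv[2]) / 2
  fv <- feature_vector(psi_gmotif_m1 = mid(co$psi_gmotif_m1),
                       psi_gmotif_p1 = mid(co$psi_gmotif_p1),
                       xi_gmotif_p1_p2 = mid(co$xi_gmotif_p1_p2),
                       d_phi__hrd_p4 = mid(co$d_phi__hrd_p4))
  res <- classify_ploop(fv, cfg2)
  expect_equal(res$class, "unassigned")
  expect_match(res$reason, "ambiguous")
})

test_that("A-loop classes are mutually exclusive interval boxes", {
  cfg <- fx_config()
  mid <- function(iv) (iv[1] + iv[2]) / 2
  for (cl in names(cfg$aloop$classes)) {
    box <- cfg$aloop$classes[[cl]]
    fv <- feature_vector(xi_dfg_m1_d = mid(box$xi_dfg_m1_d),
                         xi_dfg_f_g = mid(box$xi_dfg_f_g),
                         d_hrd_m4__dfg_p3 = mid(box$d_hrd_m4__dfg_p3))
    expect_equal(classify_aloop(fv, cfg)$class, cl)
  }
  # distance outside every box -> unassigned
  fv_out <- feature_vector(
    xi_dfg_m1_d = mid(cfg$aloop$classes$open_dfg_out$xi_dfg_m1_d),
    xi_dfg_f_g = mid(cfg$aloop$classes$open_dfg_out$xi_dfg_f_g),
    d_hrd_m4__dfg_p3 = 50)
  expect_equal(classify_aloop(fv_out, cfg)$class, "unassigned")
  # missing feature -> unassigned with reason
  res <- classify_aloop(feature_vector(xi_dfg_m1_d = 90), cfg)
  expect_equal(res$class, "unassigned")
  expect_match(res$reason, "unavailable")
})

test_that("DFG classifier separates in/out intervals with an unassigned gap", {
  cfg <- fx_config()
  mid <- function(iv) (iv[1] + iv[2]) / 2
  expect_equal(classify_dfg(feature_vector(
    dfg_pseudodihedral = mid(cfg$dfg$out_interval)), cfg)$class, "out")
  expect_equal(classify_dfg(feature_vector(
    dfg_pseudodihedral = mid(cfg$dfg$in_interval)), cfg)$class, "in")
  expect_equal(classify_dfg(feature_vector(dfg_pseudodihedral = 0),
                            cfg)$class, "unassigned")
  expect_equal(classify_dfg(feature_vector(d_lys_glu = 3), cfg)$class,
               "unassigned")
})

test_that("config validation enforces the structural constraints", {
  cfg <- unclass(fx_config())
  bad1 <- cfg; bad1$alphac$d_in_max <- 9
  expect_error(validate_config(bad1), "d_in_max")
  bad2 <- cfg; bad2$ploop$min_conditions <- 0
  expect_error(validate_config(bad2), "1..4")
  bad3 <- cfg
  bad3$aloop$classes$closed_type2 <- bad3$aloop$classes$open_dfg_out
  expect_error(validate_config(bad3), "overlap")
  bad4 <- cfg; bad4$aloop$classes$open_dfg_out$xi_dfg_f_g <- c(50, 10)
  expect_error(validate_config(bad4), "malformed interval")
  bad5 <- cfg; bad5$boundaries$aloop_start <- 190
  expect_error(validate_config(bad5), "184-186")
})

test_that("classification is invariant under rigid motion of the structure", {
  dom <- fx_scaffold()
  lab <- classify_structure(dom)
  set.seed(99)
  for (i in 1:3) {
    moved <- transform_domain(dom, random_rigid())
    lab2 <- classify_structure(moved)
    expect_equal(lab2$dfg, lab$dfg)
    expect_equal(lab2$aloop, lab$aloop)
    expect_equal(lab2$ploop, lab$ploop)
    expect_equal(lab2$alphac, lab$alphac)
    expect_equal(lab2$features$values, lab$features$values, tolerance = 1e-6)
  }
})

test_that("feature computation flags unavailable observables instead of NaN", {
  dom <- fx_scaffold()
  cut <- dom
  cut$atoms <- cut$atoms[!(cut$atoms$ref_id == 91 &
                             !cut$atoms$name %in% c("N", "CA", "C", "O")), ]
  fv <- compute_features(cut)
  expect_false(fv$available[["d_lys_glu"]])
  expect_false(fv$available[["chi_glu"]])
  expect_match(fv$notes[["d_lys_glu"]], "missing")
  expect_true(fv$available[["xi_dfg_m1_d"]])
  expect_error(feature_vector(not_a_feature = 1), "unknown feature")
})
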