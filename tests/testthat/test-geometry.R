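test_that("dihedral handles canonical planar arrangements and degeneracies", {
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               0)
  # collinear first triple -> undefined
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
  expect_error(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               "zero length")
})

test_that("dihedral agrees with two independent oracles on random quadruples", {
  set.seed(101)
  for (i in 1:100) {
    p <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    d <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_lt(abs(wrap_angle(d - oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]))),
              1e-9)
    d_bio3d <- bio3d::torsion.xyz(as.vector(t(p)))
    expect_lt(abs(wrap_angle(d - d_bio3d)), 1e-6)
  }
})

test_that("dihedral symmetry properties hold under random inputs", {
  set.seed(202)
  for (i in 1:30) {
    p <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    d <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    # reversal invariance
    expect_equal(dihedral_angle(p[4, ], p[3, ], p[2, ], p[1, ]), d,
                 tolerance = 1e-9)
    # mirror antisymmetry
    pm <- p; pm[, 1] <- -pm[, 1]
    expect_equal(dihedral_angle(pm[1, ], pm[2, ], pm[3, ], pm[4, ]),
                 wrap_angle(-d), tolerance = 1e-9)
    # rigid-motion invariance
    tr <- random_rigid()
    pt <- apply_transform(p, tr)
    expect_equal(dihedral_angle(pt[1, ], pt[2, ], pt[3, ], pt[4, ]), d,
                 tolerance = 1e-8)
  }
})

test_that("place_atom realises requested internal coordinates exactly", {
  set.seed(303)
  for (i in 1:25) {
    p <- matrix(stats::rnorm(9, sd = 4), 3, 3)
    tor <- stats::runif(1, -179, 180)
    ang <- stats::runif(1, 30, 150)
    bond <- stats::runif(1, 1, 4)
    x <- place_atom(p[1, ], p[2, ], p[3, ], bond, ang, tor)
    expect_equal(sqrt(sum((x - p[3, ])^2)), bond, tolerance = 1e-10)
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], x), tor,
                 tolerance = 1e-9)
  }
})

test_that("Kabsch superposition recovers known transforms with proper rotations", {
  set.seed(404)
  x <- matrix(stats::rnorm(60, sd = 5), 20, 3)
  # identical sets
  sp0 <- superpose(x, x)
  expect_lt(sp0$rmsd, 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-8)
  # known transform recovery
  for (i in 1:10) {
    tr <- random_rigid()
    y <- apply_transform(x, tr)
    sp <- superpose(y, x)
    expect_lt(sp$rmsd, 1e-8)
    expect_equal(sp$rotation %*% tr$rotation, diag(3), tolerance = 1e-8)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  }
  # reflection: fit is imperfect but the rotation stays proper
  xr <- x; xr[, 1] <- -xr[, 1]
  spr <- superpose(xr, x)
  expect_gt(spr$rmsd, 0.1)
  expect_equal(det(spr$rotation), 1, tolerance = 1e-8)
  expect_error(superpose(x[1:2, ], x[1:2, ]), "at least 3")
})

test_that("superposition rmsd agrees with the bio3d reference implementation", {
  set.seed(505)
  a <- matrix(stats::rnorm(45, sd = 4), 15, 3)
  b <- a + matrix(stats::rnorm(45, sd = 0.3), 15, 3)
  sp <- superpose(a, b)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a))))
  rmsd_ref <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - b)^2)))
  expect_equal(sp$rmsd, rmsd_ref, tolerance = 1e-6)
})

test_that("domain-level distances and pseudotorsions behave on scaffolds", {
  dom <- fx_scaffold()
  expect_equal(ca_distance(dom, 160, 189), ca_distance(dom, 189, 160))
  expect_equal(ca_distance(dom, 72, 72), 0)
  # min_atom_distance picks the closer OE and errors when both are gone
  d_min <- min_atom_distance(dom, 72, "NZ", 91, c("OE1", "OE2"))
  d1 <- min_atom_distance(dom, 72, "NZ", 91, "OE1")
  d2 <- min_atom_distance(dom, 72, "NZ", 91, "OE2")
  expect_equal(d_min, min(d1, d2))
  cut <- dom
  cut$atoms <- cut$atoms[!(cut$atoms$ref_id == 91 &
                             cut$atoms$name %in% c("OE1", "OE2")), ]
  expect_error(min_atom_distance(cut, 72, "NZ", 91, c("OE1", "OE2")),
               "missing atoms")
  # missing CA is a named error
  cut2 <- dom
  cut2$atoms <- cut2$atoms[!(cut2$atoms$ref_id == 57 & cut2$atoms$name == "CA"), ]
  expect_error(ca_pseudotorsion(cut2, 55), "missing CA at reference 57")
  # sidechain chi: Gly has none
  expect_error(sidechain_chi(dom, 186), "no sidechain chi")
})

test_that("backbone rmsd is zero on self, invariant under rigid motion, and honest unfitted", {
  dom <- fx_scaffold()
  expect_equal(as.numeric(backbone_rmsd(dom, dom)), 0, tolerance = 1e-10)
  tr <- list(rotation = diag(3), translation = c(5, 0, 0))
  moved <- transform_domain(dom, tr)
  expect_lt(as.numeric(backbone_rmsd(dom, moved, fit = TRUE)), 1e-8)
  expect_equal(as.numeric(backbone_rmsd(dom, moved, fit = FALSE)), 5,
               tolerance = 1e-9)
})
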