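single_atom <- make_structure_tbl(chain = "A", resno = 1L, elety = "X1",
                                  element = "C", x = 0, y = 0, z = 0)

test_that("an isolated atom matches the closed-form sphere area", {
  r <- sasa(single_atom, probe = 1.4, n_points = 960)
  expect_equal(r$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-12)
  # custom radius through the table override
  s <- make_structure_tbl(chain = "A", resno = 1L, elety = "X", element = "FE",
                          x = 0, y = 0, z = 0)
  r2 <- sasa(s, probe = 1.4, radii = vdw_radii(FE = 2.0))
  expect_equal(r2$total, 4 * pi * 3.4^2, tolerance = 1e-12)
  expect_error(sasa(s), "unknown element")
})

test_that("two intersecting spheres match the analytic cap formula and a dense oracle", {
  two <- make_structure_tbl(chain = c("A", "B"), resno = c(1L, 2L),
                            elety = c("X1", "X2"), element = "C",
                            x = c(0, 2), y = 0, z = 0)
  got <- sasa(two, probe = 1.4, n_points = 10000)$total
  analytic <- two_sphere_sasa(R = 1.7 + 1.4, d = 2)
  expect_equal(got, analytic, tolerance = 0.01)
  dense <- sasa(two, probe = 1.4, n_points = 1e5)$total
  expect_equal(got, dense, tolerance = 0.01)
})

test_that("areas are additive for atoms beyond contact range", {
  apart <- make_structure_tbl(chain = c("A", "B"), resno = c(1L, 2L),
                              elety = c("X1", "X2"), element = c("C", "S"),
                              x = c(0, 10), y = 0, z = 0)
  r <- sasa(apart)
  expect_equal(r$total, 4 * pi * (3.1^2 + 3.2^2), tolerance = 1e-12)
  expect_equal(r$per_atom, c(4 * pi * 3.1^2, 4 * pi * 3.2^2), tolerance = 1e-12)
})

test_that("SASA converges: 960 vs 10000 points differ by under 2 percent", {
  s <- make_toy_complex(21, "contacting")
  coarse <- sasa(s, n_points = 960)$total
  fine <- sasa(s, n_points = 10000)$total
  expect_lt(abs(coarse - fine) / fine, 0.02)
})

test_that("SASA, footprints and clash counts are rigid-motion invariant", {
  s <- make_toy_complex(22, "contacting")
  R0 <- rot_mat(c(1, -1, 2), 1.1)
  moved <- s
  xyz <- sweep(as.matrix(s[, c("x", "y", "z")]) %*% t(R0), 2, c(10, -5, 3), "+")
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  expect_equal(sasa(moved, n_points = 10000)$total,
               sasa(s, n_points = 10000)$total, tolerance = 1e-3)
  # the footprint is a small difference of large areas, so its relative
  # lattice noise is larger; checked at a denser sampling
  fp0 <- interface_footprint(s, "A", "B", n_points = 10000)
  fp1 <- interface_footprint(moved, "A", "B", n_points = 10000)
  expect_equal(fp1$side_a_buried, fp0$side_a_buried, tolerance = 5e-3)
  k <- make_toy_complex(23, "clashing", k_clashes = 5)
  km <- k
  xyz <- sweep(as.matrix(k[, c("x", "y", "z")]) %*% t(R0), 2, c(-3, 7, 1), "+")
  km$x <- xyz[, 1]; km$y <- xyz[, 2]; km$z <- xyz[, 3]
  expect_equal(nrow(detect_clashes(km, "A", "B")), nrow(detect_clashes(k, "A", "B")))
})

test_that("separated groups bury nothing; contacting groups match the dense oracle", {
  sep <- make_toy_complex(24, "separated")
  fp <- interface_footprint(sep, "A", "B")
  expect_equal(fp$side_a_buried, 0)
  expect_equal(fp$side_b_buried, 0)
  expect_equal(nrow(fp$contacts), 0)

  con <- make_toy_complex(24, "contacting", with_expectations = TRUE)
  exp <- attr(con, "expectations")
  fp2 <- interface_footprint(con, "A", "B", n_points = 10000)
  expect_gt(fp2$side_a_buried, 0)
  expect_equal(fp2$side_a_buried, exp$side_a_buried,
               tolerance = 0.01)
  expect_equal(fp2$side_b_buried, exp$side_b_buried,
               tolerance = 0.01)
  # per-residue decomposition sums to the group totals
  expect_equal(sum(fp2$per_residue$dsasa[fp2$per_residue$group == "A"]),
               fp2$side_a_buried)
})

test_that("buried areas are both zero iff no atom pair is in contact range", {
  # property over random geometries: zero footprint <=> contact-free
  for (seed in 1:6) {
    s <- make_toy_complex(seed, sample(c("contacting", "separated"), 1))
    fp <- interface_footprint(s, "A", "B")
    a <- s[s$chain == "A", ]; b <- s[s$chain == "B", ]
    dmin <- min(dualfv:::proxy_dist(a, b))
    contact_free <- dmin > 2 * (1.8 + 1.4) # max radius + probe, both sides
    if (contact_free) {
      expect_equal(fp$side_a_buried, 0)
      expect_equal(fp$side_b_buried, 0)
    } else {
      expect_gte(fp$side_a_buried, 0)
      expect_gte(fp$side_b_buried, 0)
    }
  }
})

test_that("engineered clash fixtures report exactly the embedded severe pairs", {
  for (k in c(3, 7)) {
    s <- make_toy_complex(31, "clashing", k_clashes = k)
    cl <- detect_clashes(s, "A", "B")
    expect_equal(nrow(cl), k)
    expect_true(all(cl$overlap > 0.4))
  }
  # overlapping groups are rejected in footprints
  s <- make_toy_complex(32, "contacting")
  expect_error(interface_footprint(s, c("A", "B"), "B"), "overlapping")
})

test_that("footprint attribution assigns buried area to the contacting CDRs", {
  ac <- make_antibody_complex(41, side = "H-side")
  ann <- annotate_regions(tmpl_nfv, "union")
  fp <- interface_footprint(ac, c("H", "L"), "G",
                            region_map = footprint_region_map(ann))
  attr_tbl <- fp$cdr_attribution
  hside <- attr_tbl$buried[attr_tbl$region %in% c("HCDR1", "HCDR3", "LCDR2")]
  expect_length(hside, 3)
  expect_true(all(hside > 0))
  # L-side CDRs face away and bury nothing
  lside <- attr_tbl$buried[attr_tbl$region %in% c("LCDR1", "LCDR3", "HCDR2")]
  expect_true(all(lside < 1e-6))
})
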