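test_that("dihedral_angle: trans planar is 180, chirality flips the sign", {
  p <- list(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(do.call(dihedral_angle, p), 180)
  gauche <- list(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))
  a1 <- do.call(dihedral_angle, gauche)
  mirror <- lapply(gauche, function(q) q * c(1, 1, -1))
  expect_equal(do.call(dihedral_angle, mirror), -a1)
  # matches the independent sign/magnitude oracle on random quadruples
  set.seed(51)
  for (i in 1:10) {
    q <- lapply(1:4, function(j) rnorm(3))
    expect_equal(do.call(dihedral_angle, q), do.call(oracle_dihedral, q),
                 tolerance = 1e-10)
  }
})

test_that("sheet_twist of the untwisted builder is 0 and grows with layer twist", {
  s0 <- build_fibril("phf")
  map <- build_assembly_map(s0)
  expect_equal(sheet_twist(s0, map), 0, tolerance = 1e-6)
  # expected dihedral from the independent rotation-matrix construction
  tw <- vapply(c(2, 5, 10), function(th) {
    s <- build_fibril("phf", twist_deg = th)
    abs(sheet_twist(s, build_assembly_map(s)))
  }, numeric(1))
  expect_true(all(diff(tw) > 0))          # monotone in the layer twist
  # oracle: apply the same rotation to the four probe points directly
  th <- 5
  s <- build_fibril("phf", twist_deg = th)
  map5 <- build_assembly_map(s)
  a <- s0$atoms
  grab <- function(ch, res) as.numeric(a[a$chain == ch & a$resid == res &
                                           a$name == "CA", c("x", "y", "z")])
  axis_xy <- c(mean(a$x[a$name == "CA"]), mean(a$y[a$name == "CA"]))
  rot <- function(p, ang) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    c(axis_xy + R %*% (p[1:2] - axis_xy), p[3])
  }
  ang <- th * pi / 180
  expected <- oracle_dihedral(grab("A", 306), grab("A", 310),
                              rot(grab("B", 310), ang), rot(grab("B", 306), ang))
  expect_equal(sheet_twist(s, map5), expected, tolerance = 1e-6)
  # mirror image flips the sign
  sm <- s
  sm$atoms$z <- -sm$atoms$z
  mapm <- build_assembly_map(sm)
  expect_equal(sheet_twist(sm, mapm), -sheet_twist(s, map5), tolerance = 1e-6)
})

single_atom <- function(el = "C") {
  taufield:::new_structure(data.frame(
    name = el, resname = "ALA", chain = "A", resid = 1L,
    x = 0, y = 0, z = 0, element = el, stringsAsFactors = FALSE))
}

test_that("sasa: analytic sphere, additivity, and two-sphere overlap", {
  s1 <- sasa(single_atom())$total
  expect_equal(s1, 4 * pi * 3.1^2, tolerance = 0.005)   # < 0.5% quadrature error
  two_far <- taufield:::new_structure(data.frame(
    name = "C", resname = "ALA", chain = "A", resid = 1:2,
    x = c(0, 10), y = 0, z = 0, element = "C", stringsAsFactors = FALSE))
  expect_equal(sasa(two_far)$total, 2 * s1, tolerance = 1e-9)
  # fused spheres: closed-form spherical caps, equal radii R at distance d:
  # each sphere loses a cap of height h = R - d/2; area = 2 pi R h
  d_nm <- 0.4
  two_near <- taufield:::new_structure(data.frame(
    name = "C", resname = "ALA", chain = "A", resid = 1:2,
    x = c(0, d_nm), y = 0, z = 0, element = "C", stringsAsFactors = FALSE))
  R <- 3.1; d <- d_nm * 10
  cap <- 2 * pi * R * (R - d / 2)
  expected <- 2 * (4 * pi * R^2 - cap)
  expect_equal(sasa(two_near)$total, expected, tolerance = 0.005)
  # monotone non-increasing in probe radius for a convex body
  expect_gt(sasa(single_atom(), probe = 0.14)$total,
            sasa(single_atom(), probe = 0.10)$total)
  expect_error(sasa(taufield:::new_structure(data.frame(
    name = "X", resname = "UNK", chain = "A", resid = 1L, x = 0, y = 0, z = 0,
    element = "X", stringsAsFactors = FALSE))), "radius")
})

test_that("sasa is invariant under rigid motion up to quadrature error", {
  # the spiral quadrature grid is fixed in the lab frame, so invariance holds
  # only to the quadrature tolerance of the point set
  s <- build_fibril("phf", n_protofilaments = 1)
  a0 <- sasa(s)$total
  a <- s$atoms
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + 2; a$y <- xyz[, 2]; a$z <- xyz[, 3] - 1
  expect_equal(sasa(taufield:::new_structure(a))$total, a0, tolerance = 0.02)
})

test_that("interface area: PHF > SF on default builds, 0 at large separation, symmetric", {
  phf <- build_fibril("phf"); map_p <- build_assembly_map(phf)
  sf <- build_fibril("sf"); map_s <- build_assembly_map(sf)
  ia_p <- interface_area(phf, map_p, n_points = 240)
  ia_s <- interface_area(sf, map_s, n_points = 240)
  expect_gt(ia_p$interface_area, ia_s$interface_area)
  expect_gte(ia_p$interface_area, 0)
  expect_gt(ia_p$interface_area, 50)   # a real, nonzero contact surface
  # symmetric in the two pentamers
  expect_equal(ia_p$sasa_pentamer_a + ia_p$sasa_pentamer_b - ia_p$sasa_decamer,
               ia_p$interface_area)
  # translate b 10 nm away -> interface vanishes
  a <- phf$atoms
  bmask <- a$chain %in% protofilament_chains(map_p, "b")
  a$y[bmask] <- a$y[bmask] + 10
  ia_far <- interface_area(taufield:::new_structure(a), map_p, n_points = 240)
  expect_equal(ia_far$interface_area, 0, tolerance = 1e-6)
})
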