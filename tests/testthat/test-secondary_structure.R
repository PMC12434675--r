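test_that("hbond_energy reproduces the Kabsch-Sander closed form", {
  # all four distances equal -> terms cancel exactly: N and H on the
  # perpendicular bisector plane of O-C
  O <- c(0, 0, 0); C <- c(0.2, 0, 0)
  N <- c(0.1, 0.15, 0); H <- c(0.1, -0.15, 0)
  expect_equal(hbond_energy(O, C, N, H), 0, tolerance = 1e-12)
  # explicit four-point geometry evaluated against the closed form by hand
  O <- c(0, 0, 0); C <- c(0.123, 0, 0)      # carbonyl along +x
  N <- c(-0.05, 0.29, 0); H <- c(-0.02, 0.19, 0)
  dA <- function(p, q) sqrt(sum((p - q)^2)) * 10
  e_hand <- 0.084 * 332 * (1 / dA(O, N) + 1 / dA(C, H) - 1 / dA(O, H) - 1 / dA(C, N))
  expect_equal(hbond_energy(O, C, N, H), e_hand, tolerance = 1e-12)
  expect_lt(e_hand, -0.5)                   # a bona fide hydrogen bond
  # distant donor/acceptor: negligible energy
  e_far <- hbond_energy(c(0, 0, 0), c(0.1, 0, 0), c(20, 0, 0), c(19.9, 0, 0))
  expect_lt(abs(e_far), 0.01)
  # degenerate geometry
  expect_error(hbond_energy(c(0, 0, 0), c(0.01, 0, 0), c(1, 0, 0), c(0.9, 0, 0)),
               "degenerate")
})

test_that("hbond_energy is invariant under rigid motion", {
  set.seed(5)
  O <- c(0, 0, 0); C <- c(0.1, 0.05, 0); N <- c(0.29, 0, 0); H <- c(0.19, 0, 0)
  e0 <- hbond_energy(O, C, N, H)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr <- c(1.2, -0.4, 2.2)
  mv <- function(p) as.numeric(R %*% p) + tr
  expect_equal(hbond_energy(mv(O), mv(C), mv(N), mv(H)), e0, tolerance = 1e-12)
})

test_that("assign_ss agrees with the independent Kabsch-Sander oracle", {
  fixtures <- list(
    helix = build_ideal_peptide(15, -57, -47),
    extended_single = build_ideal_peptide(12, -120, 120),
    pentamer = build_fibril("phf", n_protofilaments = 1)
  )
  for (nm in names(fixtures)) {
    pkg <- assign_ss(fixtures[[nm]])$code
    ora <- oracle_dssp(fixtures[[nm]])
    expect_gte(mean(pkg == ora), 0.95)
  }
})

test_that("ideal helix is H inside, isolated extended chain has no E", {
  hel <- assign_ss(build_ideal_peptide(15, -57, -47))
  expect_true(all(hel$code[3:12] == "H"))
  ext <- assign_ss(build_ideal_peptide(12, -120, 120))
  expect_false(any(ext$code == "E"))   # bridges need a partner strand
})

test_that("builder decamer: interior-chain strand residues are mostly E, turn is not", {
  s <- build_fibril("phf")
  ss <- assign_ss(s)
  roles <- builder_roles()
  strand <- roles$resid[roles$role == "strand"]
  for (ch in c("B", "C", "D")) {           # interior chains of protofilament a
    codes <- ss$code[ss$chain == ch]
    resid <- ss$resid[ss$chain == ch]
    expect_gte(mean(codes[resid %in% strand] == "E"), 0.60)
    expect_true(all(codes[resid %in% 341:349] != "E"))
  }
})

test_that("beta_fraction tracks the designed strand coverage and is chain-invariant", {
  s <- build_fibril("phf")
  traj <- perturb_trajectory(s, n_frames = 2, seed = 1)   # two identical frames
  bf <- beta_fraction(traj)
  roles <- builder_roles()
  coverage <- mean(roles$role == "strand")
  expect_equal(bf$beta_fraction[1], bf$beta_fraction[2])
  expect_lte(bf$beta_fraction[1], coverage)          # E never exceeds design
  expect_gte(bf$beta_fraction[1], 0.6 * coverage)    # edge losses bounded
  expect_error(beta_fraction(traj, residues = 9999), "empty")
  # selection on a mid-arm strand window of an interior chain: fully beta
  bf_core <- beta_fraction(traj, chains = "C", residues = 315:330)
  expect_equal(bf_core$beta_fraction[1], 1.0)
})

test_that("count_bridges = TRUE is a superset of the ladder-only assignment", {
  s <- build_fibril("phf", n_protofilaments = 1)
  e_only <- assign_ss(s)$code == "E"
  e_plus_b <- assign_ss(s, count_bridges = TRUE)$code == "E"
  expect_true(all(e_plus_b[e_only]))
  expect_gte(sum(e_plus_b), sum(e_only))
})

test_that("aggregate_series over identical runs has zero band width", {
  s <- build_fibril("phf", n_protofilaments = 1)
  traj <- perturb_trajectory(s, n_frames = 2, seed = 1)
  bf <- beta_fraction(traj)
  agg <- aggregate_series(list(bf, bf, bf), value = "beta_fraction")
  expect_equal(agg$sd, rep(0, nrow(agg)))
  expect_equal(agg$mean, bf$beta_fraction)
  expect_equal(agg$n_runs, rep(3L, nrow(agg)))
})

test_that("all-coil input yields zero beta fraction at every frame", {
  coil <- build_ideal_peptide(10, -75, 145)   # irregular extended-ish, isolated
  traj <- perturb_trajectory(coil, n_frames = 3, terminus_sigma = 0.02, seed = 2)
  bf <- beta_fraction(traj)
  expect_equal(bf$beta_fraction, rep(0, 3))
})
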