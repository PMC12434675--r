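# Contact-class definitions and survival fractions, checked against boundary
# constructions and the exhaustive O(n^2) oracle.

toy_two_chain <- function(d_nm, resid_a = 1L, resid_b = 1L, chains = c("A", "B")) {
  atoms <- data.frame(
    name = "CA", resname = "GLY",
    chain = chains, resid = c(resid_a, resid_b),
    x = c(0, d_nm), y = 0, z = 0, element = "C", stringsAsFactors = FALSE)
  taufield:::new_structure(atoms)
}

test_that("interpeptide boundary: 0.79 nm in, 0.81 nm out (strict inequality)", {
  s_in <- toy_two_chain(0.79)
  s_out <- toy_two_chain(0.81)
  expect_equal(sum(reference_contacts(s_in)$class == "interpeptide"), 1L)
  expect_equal(sum(reference_contacts(s_out)$class == "interpeptide"), 0L)
})

test_that("same-chain pair at sequence separation 3 is never intrapeptide", {
  atoms <- data.frame(name = "CA", resname = "GLY", chain = "A",
                      resid = c(1L, 4L), x = c(0, 0.3), y = 0, z = 0,
                      element = "C", stringsAsFactors = FALSE)
  s <- taufield:::new_structure(atoms)
  expect_equal(nrow(reference_contacts(s)), 0L)
  atoms$resid <- c(1L, 5L)   # separation 4: now counted
  s <- taufield:::new_structure(atoms)
  expect_equal(reference_contacts(s)$class, "intrapeptide")
})

test_that("chains 5 nm apart have no interpeptide or interprotofilament contacts", {
  s <- build_fibril("phf", n_protofilaments = 1)
  a2 <- s$atoms
  a2$chain <- "Z"
  a2$y <- a2$y + 5
  both <- taufield:::new_structure(rbind(s$atoms[s$atoms$chain == "A", ], a2[a2$resid < 330, ]))
  refs <- reference_contacts(both)
  expect_equal(sum(refs$class == "interpeptide"), 0L)
})

test_that("contact_fraction equals the brute-force oracle exactly on a toy assembly", {
  set.seed(23)
  # random 20-residue toy assembly: 4 chains x 5 residues, 2 protofilaments
  atoms <- data.frame(
    name = "CA", resname = "GLY",
    chain = rep(c("A", "B", "C", "D"), each = 5),
    resid = rep(1:5, 4),
    x = rnorm(20, rep(c(0, 0.3, 0.9, 1.2), each = 5), 0.35),
    y = rnorm(20, 0, 0.4),
    z = rep(seq(0, 1.6, 0.4), 4) + rnorm(20, 0, 0.1),
    element = "C", stringsAsFactors = FALSE)
  s <- taufield:::new_structure(atoms)
  map <- list(chain_ids = c("A", "B", "C", "D"),
              protofilament_of = setNames(c("a", "a", "b", "b"), c("A", "B", "C", "D")),
              stack_index_of = setNames(c(1L, 2L, 1L, 2L), c("A", "B", "C", "D")),
              label_of = setNames(c("1a", "2a", "1b", "2b"), c("A", "B", "C", "D")),
              central_chains = c("A", "C"))
  class(map) <- "assembly_map"
  traj <- perturb_trajectory(s, map = map, n_frames = 4, terminus_sigma = 0.15,
                             n_terminus = 2, seed = 9)
  refset <- reference_contacts(s, map)
  got <- contact_fraction(traj, refset)
  want <- oracle_contact_fraction(traj, map)
  for (f in 1:4) for (cl in unique(want$class)) {
    g <- got$fraction[got$class == cl][f]
    w <- want$fraction[want$class == cl & want$frame == f]
    expect_identical(unname(g), unname(w))
  }
})

test_that("fractions are 1 at the reference frame and drop to 0 on separation", {
  s <- build_fibril("sf")
  map <- build_assembly_map(s)
  sep_at <- 6L
  traj <- perturb_trajectory(taufield:::ca_only_structure(s), map = map,
                             n_frames = 10, separation_frame = sep_at,
                             separation_velocity = 2.5, seed = 3)
  refset <- reference_contacts(get_frame(traj, 1), map)
  cf <- contact_fraction(traj, refset)
  ipf <- cf$fraction[cf$class == "interprotofilament"]
  expect_equal(cf$fraction[cf$time_ns == 0], rep(1, 3))   # all classes at ref
  expect_true(all(ipf[1:(sep_at - 1)] == 1))
  expect_true(all(ipf[sep_at:10] == 0))                    # gap > 1 nm after
  # monotone under rigid separation
  expect_true(all(diff(ipf) <= 0))
})

test_that("per-residue grouping: 'any' survival dominates the pair average", {
  s <- build_fibril("sf")
  map <- build_assembly_map(s)
  traj <- perturb_trajectory(taufield:::ca_only_structure(s), map = map,
                             n_frames = 4, terminus_sigma = 0.3, seed = 6)
  refset <- reference_contacts(get_frame(traj, 1), map)
  pr_mean <- contact_fraction(traj, refset, group_by = "residue")
  pr_any <- contact_fraction(traj, refset, group_by = "residue",
                             per_residue_stat = "any")
  expect_equal(nrow(pr_mean), nrow(pr_any))
  expect_true(all(pr_any$fraction >= pr_mean$fraction - 1e-12))
  expect_true(all(pr_any$fraction %in% c(0, 1)))
})

test_that("reference class counts are invariant under global rigid motion", {
  s <- build_fibril("phf")
  map <- build_assembly_map(s)
  refs0 <- contact_counts(reference_contacts(taufield:::ca_only_structure(s), map))
  th <- 0.9
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + 3; a$y <- xyz[, 2] - 1; a$z <- xyz[, 3] + 0.5
  s2 <- taufield:::new_structure(a)
  refs1 <- contact_counts(reference_contacts(taufield:::ca_only_structure(s2), map))
  expect_equal(as.integer(refs0), as.integer(refs1))
})

test_that("missing Calpha and empty contact sets raise errors", {
  s <- build_fibril("phf", n_protofilaments = 1)
  broken <- s
  broken$atoms <- broken$atoms[!(broken$atoms$chain == "A" &
                                   broken$atoms$resid == 310 &
                                   broken$atoms$name == "CA"), ]
  expect_error(reference_contacts(broken), "A:310")
  traj <- perturb_trajectory(s, n_frames = 2, seed = 1)
  refset <- reference_contacts(get_frame(traj, 1))
  empty <- refset[0, ]
  attr(empty, "ca_order") <- attr(refset, "ca_order")
  expect_error(contact_fraction(traj, empty), "empty contact set")
})
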