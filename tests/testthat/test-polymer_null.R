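test_that("sphere radius inverts the volume formula to 1e-9 relative tolerance", {
  expect_equal(sphere_radius_from_volume(4 * pi / 3), 1)
  r <- sphere_radius_from_volume(213)
  expect_equal(r, 3.704, tolerance = 1e-3)
  expect_equal((4 / 3) * pi * r^3, 213, tolerance = 1e-9)
  # the measured pro-B mean nuclear volume
  r2 <- sphere_radius_from_volume(210.4)
  expect_equal((4 / 3) * pi * r2^3, 210.4, tolerance = 1e-9)
  expect_error(sphere_radius_from_volume(0), "positive")
  expect_error(sphere_radius_from_volume(-3), "positive")
})

test_that("locus volume scaling preserves base-pair density and checks its domain", {
  G <- 2.73e9
  expect_equal(scale_locus_volume(100, G, G), 100)
  expect_equal(scale_locus_volume(213, 20e6, G), 213 * 20e6 / G)
  expect_equal(scale_locus_volume(881, 3.31e6, G), 881 * 3.31e6 / G)
  expect_error(scale_locus_volume(213, 2 * G, G), "exceed")
  expect_error(scale_locus_volume(-1, 1, 2), "positive")
  # nm radius composition
  expect_equal(confinement_radius_nm(213, 3.31e6, G),
               1000 * sphere_radius_from_volume(213 * 3.31e6 / G))
})

test_that("parameter invariants are enforced", {
  expect_error(polymer_params(confinement_radius = 40), "confinement_radius")
  expect_error(polymer_params(confinement_radius = 400, contact_threshold = 50),
               "contact_threshold")
  expect_error(polymer_params(confinement_radius = 400, bead_diameter = -1),
               "bead_diameter")
  p <- polymer_params(n_beads = 2000, bp_per_bead = 20e6 / 2000,
                      confinement_radius = 779)
  expect_equal(p$bp_per_bead, 10000)
})

test_that("a single unconstrained bead is uniform in the allowed sphere", {
  p <- polymer_params(n_beads = 1, confinement_radius = 500, n_chains = 4000, seed = 5)
  e <- sample_ensemble(p)
  expect_true(all(e$weights == e$weights[1])) # no feasibility weighting
  r <- sqrt(colSums(e$coords[1, , ]^2))
  rmax <- 500 - 51 / 2
  # radius CDF of a uniform ball is (r/rmax)^3
  ks <- stats::ks.test(r, function(q) pmin((q / rmax)^3, 1))
  expect_gt(ks$p.value, 0.001)
  expect_lte(max(r), rmax)
})

test_that("three-bead bond angles match the rejection-sampling uniform ensemble", {
  set.seed(31)
  orc <- oracle_reject_chains(30000, 3, confinement_radius = 5000)
  p <- polymer_params(n_beads = 3, confinement_radius = 5000, n_chains = 30000, seed = 8)
  e <- sample_ensemble(p)
  v1 <- e$coords[1, , ] - e$coords[2, , ]
  v2 <- e$coords[3, , ] - e$coords[2, , ]
  cosang <- colSums(v1 * v2) / 51^2
  expect_lt(weighted_ks(cosang, e$weights, orc$cos_angle), 0.02)
  # self-avoidance truncates the angle: cos(angle) <= 1/2 exactly
  expect_lte(max(cosang), 0.5)
})

test_that("short-chain end-to-end distances match the rejection oracle (KS < 0.02)", {
  set.seed(77)
  orc <- oracle_reject_chains(30000, 8, confinement_radius = 2000)
  p <- polymer_params(n_beads = 8, confinement_radius = 2000, n_chains = 30000, seed = 9)
  e <- sample_ensemble(p)
  e2e <- sqrt(colSums((e$coords[8, , ] - e$coords[1, , ])^2))
  expect_lt(weighted_ks(e2e, e$weights, orc$e2e), 0.02)
})

test_that("ensembles are reproducible under a fixed seed", {
  p <- polymer_params(n_beads = 30, confinement_radius = 400, n_chains = 50, seed = 123)
  e1 <- sample_ensemble(p)
  e2 <- sample_ensemble(p)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$weights, e2$weights)
  m1 <- ensemble_contact_matrix(e1, toy_binned(30))
  m2 <- ensemble_contact_matrix(e2, toy_binned(30))
  expect_identical(m1$values, m2$values)
})

test_that("every emitted chain is self-avoiding, bonded at one diameter, and confined", {
  p <- polymer_params(n_beads = 120, confinement_radius = 350, n_chains = 300, seed = 2)
  e <- sample_ensemble(p)
  inv <- ensemble_invariants(e)
  expect_gte(min(inv$min_nonbonded), 51)
  expect_lte(max(inv$max_norm), 350 - 51 / 2)
  expect_equal(inv$min_bond, rep(51, 300), tolerance = 1e-6)
  expect_equal(inv$max_bond, rep(51, 300), tolerance = 1e-6)
})

test_that("subsegment start offsets are uniform and weights are inherited", {
  p <- polymer_params(n_beads = 50, confinement_radius = 2000, n_chains = 1, seed = 4)
  set.seed(10)
  ch <- sample_chain(p)
  expect_identical(subsegment(ch, 50)$coords, ch$coords)
  s1 <- subsegment(ch, 1)
  expect_equal(nrow(s1$coords), 1L)
  expect_identical(s1$log_weight, ch$log_weight)
  expect_error(subsegment(ch, 51), "exceeds")
  # chi-square uniformity of the offset over {1..40} for length 11
  set.seed(20)
  offs <- replicate(20000, subsegment(ch, 11)$offset)
  tab <- tabulate(offs, nbins = 40)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("contact matrices follow the inclusive 80 nm centre-distance rule", {
  # straight chain: |i-j| = 1 at 51 nm is a contact, |i-j| = 2 at 102 nm is not
  straight <- cbind(seq(0, by = 51, length.out = 10), 0, 0)
  e <- manual_ensemble(list(straight))
  M <- ensemble_contact_matrix(e, toy_binned(10))
  expect_equal(M$values[cbind(1:9, 2:10)], rep(1, 9))
  expect_equal(M$values[cbind(1:8, 3:10)], rep(0, 8))
  expect_equal(diag(M$values), rep(0, 10))

  # folded chain with beads 1 and 10 exactly 79 nm apart -> contact at the
  # chain's weight; mirror symmetry enforced
  theta <- seq(0, pi, length.out = 10)
  fold <- cbind(39.5 * cos(theta), 39.5 * sin(theta), 0) # chord 1-10 = 79 nm
  # rescale consecutive bonds to exactly 51 nm by construction on a circle:
  # use a circle of radius r with chord between consecutive points = 51
  r <- 51 / (2 * sin(pi / 18))
  fold <- cbind(r * cos(theta), r * sin(theta), 0)
  d110 <- sqrt(sum((fold[1, ] - fold[10, ])^2))
  e2 <- manual_ensemble(list(fold, straight), weights = c(0.25, 0.75))
  M2 <- ensemble_contact_matrix(e2, toy_binned(10))
  if (d110 <= 80) expect_equal(M2$values[1, 10], 0.25) else expect_equal(M2$values[1, 10], 0)
  expect_identical(M2$values, t(M2$values))
})

test_that("contact frequency decays with separation in a wide-confinement ensemble", {
  p <- polymer_params(n_beads = 40, confinement_radius = 2000, n_chains = 500,
                      resample_threshold = 0, seed = 6)
  e <- sample_ensemble(p)
  dd <- distance_decay(e, n_blocks = 10)
  # independent chains: block SEs are valid; exclude the end-pair stratum,
  # which the uniform ensemble genuinely enriches
  dd <- dd[dd$separation >= 2 & dd$separation <= 38, ]
  dfreq <- diff(dd$frequency)
  sed <- sqrt(dd$se[-1]^2 + dd$se[-nrow(dd)]^2)
  expect_true(all(dfreq <= 3 * sed))
  # and the overall trend is strongly decreasing
  expect_lt(stats::cor(dd$separation, dd$frequency, method = "spearman"), -0.8)
})

test_that("null distributions are the sorted unmasked long-range cells", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 0.2
  v[2, 3] <- v[3, 2] <- 0.1
  v[1, 3] <- v[3, 1] <- 0.5
  M <- toy_matrix(v)
  nd <- null_distribution(M, min_separation = 1)
  expect_equal(nd$values, c(0.1, 0.2, 0.5))

  cm <- toy_matrix(matrix(0.3, 4, 4))
  nd2 <- null_distribution(cm, min_separation = 1)
  expect_true(all(nd2$values == 0.3))

  # cardinality at min_separation 2 for a 283-bin matrix
  n <- 283
  big <- toy_matrix(matrix(1, n, n))
  nd3 <- null_distribution(big, min_separation = 2)
  expect_equal(length(nd3$values), n * (n - 1) / 2 - (n - 1))
})

test_that("degenerate geometries fail loudly", {
  expect_error(sample_ensemble(polymer_params(n_beads = 5, confinement_radius = 52,
                                              n_chains = 5, seed = 1)),
               "confinement|dead-end|abandoned")
})
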