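test_that("KR balancing fixes doubly-stochastic matrices and equalizes row sums", {
  # already balanced: returned unchanged with unit factors
  v <- matrix(c(0, 0.5, 0.5,
                0.5, 0, 0.5,
                0.5, 0.5, 0), 3, 3)
  res <- kr_balance(toy_matrix(v))
  expect_equal(res$factors, rep(1, 3), tolerance = 1e-5)
  expect_equal(res$matrix$values, v, tolerance = 1e-5)

  # 2x2 off-diagonal matrix
  res2 <- kr_balance(toy_matrix(matrix(c(0, 2, 2, 0), 2, 2)))
  rs <- rowSums(res2$matrix$values)
  expect_equal(rs[1], rs[2], tolerance = 1e-6)

  # random symmetric positive matrix: row-sum CV < 1e-8 and agreement with
  # a Sinkhorn iteration run to convergence
  set.seed(12)
  A <- matrix(runif(2500, 0.2, 2), 50, 50)
  A <- (A + t(A)) / 2
  res3 <- kr_balance(toy_matrix(A), tol = 1e-10)
  rs3 <- rowSums(res3$matrix$values)
  expect_lt(sd(rs3) / mean(rs3), 1e-8)
  expect_equal(res3$matrix$values, oracle_sinkhorn(A), tolerance = 1e-6)
})

test_that("KR balancing is scale-invariant and masks empty bins", {
  set.seed(13)
  A <- matrix(runif(400, 0.5, 3), 20, 20)
  A <- (A + t(A)) / 2
  b1 <- kr_balance(toy_matrix(A))
  b2 <- kr_balance(toy_matrix(7.3 * A))
  expect_equal(b1$matrix$values, b2$matrix$values, tolerance = 1e-6)

  A0 <- A
  A0[5, ] <- 0
  A0[, 5] <- 0
  b3 <- kr_balance(toy_matrix(A0))
  expect_false(b3$matrix$mask[5])
  expect_true(is.na(b3$factors[5]))
  rs <- rowSums(b3$matrix$values[-5, -5])
  expect_lt(sd(rs) / mean(rs), 1e-5)

  expect_error(kr_balance(toy_matrix(matrix(0, 3, 3))), "degenerate")
  expect_error(kr_balance(kr_balance(toy_matrix(A))$matrix), "raw")
})

test_that("SCC is 1 on self, ~0 after within-stratum permutation, symmetric", {
  set.seed(14)
  feats <- igh_like_features(200)
  reps <- synth_contact_matrix(200, depth = 50, domains = feats$domains,
                               stripes = feats$stripes, dots = feats$dots, seed = 21)
  A <- reps[[1]]; B <- reps[[2]]
  expect_equal(suppressMessages(scc(A, A)), 1, tolerance = 1e-12)
  expect_equal(suppressMessages(scc(A, B)), suppressMessages(scc(B, A)))

  # permuting entries within each stratum destroys the correlation
  n <- 200
  P <- A$values
  for (k in 1:(n - 1)) {
    i <- 1:(n - k)
    vals <- P[cbind(i, i + k)]
    perm <- sample(vals)
    P[cbind(i, i + k)] <- perm
    P[cbind(i + k, i)] <- perm
  }
  Ap <- toy_matrix(P)
  expect_lt(abs(suppressMessages(scc(Ap, B, max_separation = 150))), 0.05)
})

test_that("Poisson replicates of a structured locus pass the SCC > 0.9 merge gate", {
  feats <- igh_like_features(200)
  reps <- synth_contact_matrix(200, domains = feats$domains,
                               stripes = feats$stripes, dots = feats$dots, seed = 22)
  expect_gt(suppressMessages(scc(reps[[1]], reps[[2]])), 0.9)
})

test_that("replicate merging is an element-wise sum with union of invalid bins", {
  set.seed(15)
  v <- matrix(rpois(100, 5) * 1.0, 10, 10); v <- v + t(v)
  M <- toy_matrix(v)
  Z <- toy_matrix(matrix(0, 10, 10))
  expect_equal(merge_replicates(list(M, Z))$values, M$values)
  expect_error(merge_replicates(list()), "non-empty")

  # Poisson additivity: mean of merge of two rate-L replicates ~ 2L within 3 sigma
  L <- 40
  mk <- function() {
    m <- matrix(0, 100, 100)
    ut <- upper.tri(m, diag = TRUE)
    m[ut] <- rpois(sum(ut), L)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    toy_matrix(m)
  }
  mm <- merge_replicates(list(mk(), mk()))
  cells <- matrix_cells(mm, min_separation = 1)
  se <- sqrt(2 * L / nrow(cells))
  expect_lt(abs(mean(cells$value) - 2 * L), 3 * se)

  # masked bin in one replicate is masked in the merge
  Mm <- toy_matrix(v, mask = c(FALSE, rep(TRUE, 9)))
  expect_false(merge_replicates(list(M, Mm))$mask[1])
})

test_that("quantile normalization maps ranks onto the target distribution", {
  # 4x4 matrix has exactly 3 cells at separation >= 2: (1,3), (1,4), (2,4)
  v <- matrix(0, 4, 4)
  v[1, 3] <- v[3, 1] <- 5
  v[1, 4] <- v[4, 1] <- 1
  v[2, 4] <- v[4, 2] <- 9
  M <- toy_matrix(v)
  target <- structure(list(values = c(0.1, 0.2, 0.7), min_separation = 2L),
                      class = "null_distribution")
  Q <- quantile_normalize(M, target)
  expect_equal(Q$values[1, 3], 0.2)
  expect_equal(Q$values[1, 4], 0.1)
  expect_equal(Q$values[2, 4], 0.7)
  expect_identical(Q$kind, "quantile_normalized")
  # multiset equality and rank preservation
  expect_equal(sort(matrix_cells(Q)$value), sort(target$values))
  expect_equal(rank(matrix_cells(Q)$value), rank(matrix_cells(M)$value))
  # fixed point / idempotence
  Q2 <- quantile_normalize(
    contact_matrix(ifelse(is.na(Q$values), 0, Q$values), Q$binned, kind = "raw"),
    target)
  expect_equal(matrix_cells(Q2)$value, matrix_cells(Q)$value)
  # cardinality mismatch errors unless interpolation is requested
  big <- toy_matrix(matrix(1, 10, 10))
  expect_error(quantile_normalize(big, target), "cardinality mismatch")
  expect_silent(quantile_normalize(big, target, interpolate = TRUE))
})

test_that("quantile normalization agrees with the limma implementation", {
  skip_if_not_installed("limma")
  set.seed(16)
  n <- 40
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  m[ut] <- rgamma(sum(ut), 4, 0.2) # continuous: no ties
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  M <- toy_matrix(m)
  tv <- sort(rexp(length(matrix_cells(M)$value)))
  target <- structure(list(values = tv, min_separation = 2L),
                      class = "null_distribution")
  Q <- quantile_normalize(M, target)
  ln <- limma::normalizeQuantiles(cbind(matrix_cells(M)$value, sample(tv)))
  # limma maps both columns to the averaged sorted target; compare ranks and
  # multisets rather than exact tie conventions
  expect_equal(sort(matrix_cells(Q)$value), sort(tv), tolerance = 1e-12)
  expect_equal(order(matrix_cells(Q)$value), order(ln[, 1]))
})

test_that("quantile normalization removes between-replicate depth effects", {
  # two Poisson replicates of one structured locus, each normalized to the
  # same null target: element-wise differences center on zero with no
  # separation-dependent trend
  feats <- igh_like_features(120)
  reps <- synth_contact_matrix(120, domains = feats$domains,
                               dots = feats$dots, n_replicates = 2, seed = 31)
  set.seed(33)
  tv <- sort(rexp(nrow(matrix_cells(reps[[1]]))))
  target <- structure(list(values = tv, min_separation = 2L),
                      class = "null_distribution")
  q1 <- quantile_normalize(reps[[1]], target)
  q2 <- quantile_normalize(reps[[2]], target)
  cells <- matrix_cells(difference_map(q1, q2))
  expect_lt(abs(mean(cells$value)), 0.05 * mean(tv))
  fit <- stats::lm(value ~ I(j - i), data = cells)
  ci <- stats::confint(fit)["I(j - i)", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  # tie-averaging preserves the target total, so both maps carry the same
  # aggregate signal regardless of replicate depth
  expect_equal(sum(matrix_cells(q1)$value), sum(tv))
  expect_equal(sum(matrix_cells(q2)$value), sum(tv))
})

test_that("difference maps are anti-symmetric and expose planted contacts", {
  feats <- igh_like_features(120)
  set.seed(17)
  base <- synth_contact_matrix(120, depth = 60, domains = feats$domains,
                               n_replicates = 2, seed = 41)
  # pro-B-like carries a corner dot absent from the MEF-like map
  prob <- synth_contact_matrix(120, depth = 60, domains = feats$domains,
                               dots = list(list(i = 30, j = 70, strength = 10)),
                               n_replicates = 1, seed = 42)[[1]]
  mef <- base[[1]]
  ncells <- nrow(matrix_cells(prob))
  target <- structure(list(values = sort(rexp(ncells)), min_separation = 2L),
                      class = "null_distribution")
  qa <- quantile_normalize(prob, target)
  qb <- quantile_normalize(mef, target)
  D <- difference_map(qa, qb)
  expect_identical(D$kind, "difference")
  # self-difference is zero
  D0 <- difference_map(qa, qa)
  expect_true(all(abs(D0$values) < 1e-12, na.rm = TRUE))
  # anti-symmetry in the arguments
  Dba <- difference_map(qb, qa)
  expect_equal(D$values, -Dba$values)
  # the planted dot is the locus-wide positive maximum (top 0.1% of cells)
  cells <- matrix_cells(D)
  dot_val <- D$values[30, 70]
  expect_gte(dot_val, stats::quantile(cells$value, 0.999))
  expect_error(difference_map(qa, mef), "quantile-normalized")
})
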