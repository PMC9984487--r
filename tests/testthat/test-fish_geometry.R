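test_that("pairwise distances follow the fixed label order", {
  a <- fish_allele("a1", c("Emu", "SiteI3", "EVH1"),
                   rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 0)))
  expect_equal(unname(pairwise_distances(a)), c(5, 0, 5))
  b <- fish_allele("a2", c("p1", "p2", "p3"), matrix(1, 3, 3))
  expect_equal(unname(pairwise_distances(b)), c(0, 0, 0))
  set.seed(71)
  for (i in 1:20) {
    m <- matrix(runif(9), 3, 3)
    al <- fish_allele("x", c("p1", "p2", "p3"), m)
    expect_equal(unname(pairwise_distances(al)),
                 c(sqrt(sum((m[1, ] - m[2, ])^2)),
                   sqrt(sum((m[1, ] - m[3, ])^2)),
                   sqrt(sum((m[2, ] - m[3, ])^2))))
  }
  expect_error(fish_allele("bad", c("p1", "p1", "p3"), matrix(1, 3, 3)), "distinct")
})

test_that("the classifier reproduces the published configuration definitions", {
  expect_equal(as.character(classify_configuration(0.1, 0.1, 0.1)), "THREE_WAY")
  expect_equal(as.character(classify_configuration(0.2, 0.6, 0.2)), "STRING_MID_2")
  expect_equal(as.character(classify_configuration(0.2, 0.2, 0.6)), "STRING_MID_1")
  expect_equal(as.character(classify_configuration(0.6, 0.2, 0.2)), "STRING_MID_3")
  expect_equal(as.character(classify_configuration(0.25, 0.8, 0.9)), "PAIR_12")
  expect_equal(as.character(classify_configuration(0.8, 0.25, 0.9)), "PAIR_13")
  expect_equal(as.character(classify_configuration(0.8, 0.9, 0.25)), "PAIR_23")
  expect_equal(as.character(classify_configuration(0.4, 0.4, 0.4)), "ALL_MID")
  expect_equal(as.character(classify_configuration(0.6, 0.6, 0.6)), "ALL_FAR")
  expect_equal(as.character(classify_configuration(0.4, 0.6, 0.7)), "OTHER")
  # band edges: contact is inclusive at 0.30, mid band is (0.30, 0.50]
  expect_equal(as.character(classify_configuration(0.3, 0.3, 0.3)), "THREE_WAY")
  expect_equal(as.character(classify_configuration(0.5, 0.5, 0.5)), "ALL_MID")
  expect_error(classify_configuration(-0.1, 0.2, 0.2), "non-negative")
})

test_that("classification agrees with the brute-force predicate oracle on random triples", {
  set.seed(72)
  n <- 100000
  d12 <- runif(n, 0, 1.2); d13 <- runif(n, 0, 1.2); d23 <- runif(n, 0, 1.2)
  got <- as.character(classify_configuration(d12, d13, d23))
  idx <- sample.int(n, 20000) # oracle is scalar; check a large random subset
  want <- vapply(idx, function(i) oracle_fish_category(d12[i], d13[i], d23[i]), "")
  expect_identical(got[idx], want)
  # all ten categories occur and frequencies sum to 1
  expect_setequal(unique(got), levels(classify_configuration(0.1, 0.1, 0.1)))
  expect_equal(sum(prop.table(table(got))), 1)
})

test_that("the ten categories partition the grid of distance triples", {
  # coarse exhaustive scan; the acceptance suite runs the full 0.01 step grid
  g <- seq(0, 1.2, by = 0.05)
  gr <- expand.grid(d12 = g, d13 = g, d23 = g)
  cats <- classify_configuration(gr$d12, gr$d13, gr$d23)
  expect_false(anyNA(cats))
  expect_equal(length(cats), nrow(gr))
})

test_that("configuration frequencies compare genotypes with chi-square tests", {
  set.seed(73)
  wa <- c(THREE_WAY = 0.2, ALL_MID = 0.3, ALL_FAR = 0.5)
  wb <- c(THREE_WAY = 0.05, ALL_MID = 0.3, ALL_FAR = 0.65)
  aa <- synth_fish_alleles(wa, 400, genotype = "WT", seed = 81)
  bb <- synth_fish_alleles(wb, 400, genotype = "KO", seed = 82)
  cls <- classify_alleles(c(aa, bb))
  res <- suppressMessages(configuration_frequencies(cls, c("WT", "KO")))
  expect_equal(unname(colSums(res$table$proportions)), c(1, 1))
  p_tw <- res$tests$p_value[res$tests$category == "THREE_WAY"]
  expect_lt(p_tw, 0.01)

  # identical samples: no category differs
  res0 <- suppressMessages(configuration_frequencies(
    rbind(transform(cls[cls$genotype == "WT", ], genotype = "A"),
          transform(cls[cls$genotype == "WT", ], genotype = "B")), c("A", "B")))
  ps <- res0$tests$p_value
  expect_true(all(ps[!is.na(ps)] > 0.999))

  # single category in all alleles
  one <- data.frame(genotype = rep(c("A", "B"), each = 5),
                    category = "THREE_WAY")
  res1 <- suppressMessages(configuration_frequencies(one, c("A", "B")))
  expect_equal(unname(res1$table$proportions["THREE_WAY", ]), c(1, 1))
})

test_that("planted category mixtures reach the stated chi-square power", {
  # THREE_WAY 0.2 vs 0.05 at n = 400/genotype: significant at alpha = 0.01
  # in >= 90% of seeded draws (scaled-down count here; acceptance runs 200)
  hits <- 0L
  n_draws <- 40L
  for (s in seq_len(n_draws)) {
    a <- stats::rbinom(1, 400, 0.2)
    b <- stats::rbinom(1, 400, 0.05)
    m <- rbind(c(a, b), c(400 - a, 400 - b))
    p <- stats::chisq.test(m, correct = FALSE)$p.value
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits / n_draws, 0.9)
})

test_that("distance summaries use two-tailed rank tests with guards", {
  set.seed(74)
  mk <- function(n, shift, genotype) {
    lapply(seq_len(n), function(i) {
      d <- abs(rnorm(1, 0.5 + shift, 0.3))
      fish_allele(paste0(genotype, i), c("p1", "p2", "p3"),
                  rbind(c(0, 0, 0), c(d, 0, 0), c(5, 5, 5)), genotype)
    })
  }
  cls <- classify_alleles(c(mk(400, 0, "WT"), mk(400, 0.2, "KO")))
  out <- distance_summary(cls, "d12", c("WT", "KO"))
  expect_lt(out$p_value, 0.001)
  expect_equal(out$summary$n, c(400, 400))

  same <- classify_alleles(c(mk(50, 0, "A"), mk(50, 0, "B")))
  expect_gt(distance_summary(same, "d12", c("A", "B"))$p_value, 0.01)

  tiny <- classify_alleles(c(mk(2, 0, "A"), mk(5, 0, "B")))
  expect_error(distance_summary(tiny, "d12", c("A", "B")), "at least 3")
})

test_that("compaction curves reproduce printed probe separations and scaling", {
  probes <- list(
    Emu    = parse_interval("chr12:113425893-113430719"),
    SiteI3 = parse_interval("chr12:113987323-113994353"),
    EVH1   = parse_interval("chr12:114184075-114191532")
  )
  # separations from the printed 5' starts: Emu-SiteI3 ~561 kb, Emu-EVH1 ~758 kb
  set.seed(75)
  alleles <- lapply(1:10, function(i) {
    fish_allele(i, c("Emu", "SiteI3", "EVH1"), matrix(runif(9), 3, 3), "WT")
  })
  cc <- compaction_curve(alleles, "Emu", probes)
  expect_equal(cc$separation_bp[cc$probe == "Emu"], 0)
  expect_equal(cc$mean_um[cc$probe == "Emu"], 0)
  sep_evh1 <- cc$separation_bp[cc$probe == "EVH1"]
  expect_equal(sep_evh1 / 1000, 758, tolerance = 0.001)
  expect_true(!is.unsorted(cc$separation_bp))
  expect_error(compaction_curve(alleles, "Emu", probes[1:2]), "no genomic coordinates")

  # random-walk alleles: mean distance grows with genomic separation
  walk_probes <- list(p1 = genomic_interval("chr1", 0, 1000),
                      p2 = genomic_interval("chr1", 2e5, 2.01e5),
                      p3 = genomic_interval("chr1", 1e6, 1.001e6))
  walks <- lapply(1:300, function(i) {
    steps <- matrix(rnorm(6, sd = 0.1), 2, 3)
    pos <- rbind(c(0, 0, 0),
                 sqrt(2) * steps[1, ],
                 sqrt(10) * (steps[1, ] + steps[2, ]) / sqrt(2))
    fish_allele(i, c("p1", "p2", "p3"), pos, "WT")
  })
  ccw <- compaction_curve(walks, "p1", walk_probes)
  expect_true(all(diff(ccw$mean_um) > 0))
})

test_that("FISH CSV input round-trips through classification output", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(allele_id = rep(c("al1", "al2"), each = 3),
                   genotype = rep(c("WT", "KO"), each = 3),
                   probe_label = rep(c("Emu", "SiteI3", "EVH1"), 2),
                   x_um = c(0, 0.1, 0.2, 0, 1, 2),
                   y_um = 0, z_um = 0)
  write.csv(df, path, row.names = FALSE)
  alleles <- read_fish_csv(path)
  expect_length(alleles, 2)
  cls <- classify_alleles(alleles)
  expect_equal(as.character(cls$category[cls$allele_id == "al1"]), "THREE_WAY")
  expect_equal(as.character(cls$category[cls$allele_id == "al2"]), "ALL_FAR")
  out <- withr::local_tempfile(fileext = ".csv")
  write_fish_classification(cls, out)
  expect_equal(nrow(read.csv(out)), 2)
})
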