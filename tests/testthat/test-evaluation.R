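test_that("the overlap p-value matches the hypergeometric oracle", {
  # 2x2 table with all cells 1: P(X >= 1) = 1 - C(2,0)C(2,2)/C(4,2) = 5/6
  r <- fisher_overlap_counts(both = 1, n_a = 2, n_b = 2, universe_size = 4)
  expect_equal(r$p_value, 5 / 6)
  expect_equal(unlist(r$table[, c("both", "a_only", "b_only", "neither")]),
    c(both = 1, a_only = 1, b_only = 1, neither = 1)
  )

  set.seed(2)
  for (rep in 1:25) {
    universe <- sample(20:200, 1)
    n_a <- sample.int(universe, 1)
    n_b <- sample.int(universe, 1)
    both <- sample(max(0, n_a + n_b - universe):min(n_a, n_b), 1)
    r <- fisher_overlap_counts(both, n_a, n_b, universe)
    expect_equal(r$p_value, brute_force_overlap_p(both, n_a, n_b, universe),
      tolerance = 1e-12
    )
    # cross-check against the one-sided Fisher exact test
    tab <- matrix(c(both, n_a - both, n_b - both, universe - n_a - n_b + both), 2)
    expect_equal(r$p_value,
      stats::fisher.test(tab, alternative = "greater")$p.value,
      tolerance = 1e-9
    )
  }
})

test_that("the overlap test works on gene sets and is monotone in the overlap", {
  universe <- sprintf("g%03d", 1:100)
  r <- fisher_overlap_test(universe[1:20], universe[15:40], 100)
  expect_equal(r$table$both, 6)
  # increasing the overlap at fixed margins never increases p
  ps <- vapply(0:10, function(b) {
    fisher_overlap_counts(b, 10, 10, 100)$p_value
  }, 0)
  expect_true(all(diff(ps) <= 1e-15))
  # extreme enrichment still reports a finite log10 p
  deep <- fisher_overlap_counts(400, 500, 500, 30000)
  expect_equal(deep$p_value, 0) # underflows as a plain double
  expect_true(is.finite(deep$log10_p) && deep$log10_p < -300)
  expect_error(fisher_overlap_counts(30, 20, 50, 100), "inconsistent")
})

test_that("overlap p-values are roughly uniform under random same-sized sets", {
  # set sizes large enough that the discrete p-value support is fine-grained
  set.seed(13)
  universe <- sprintf("g%04d", 1:1000)
  ps <- replicate(500, {
    na <- sample(100:400, 1)
    nb <- sample(100:400, 1)
    fisher_overlap_test(sample(universe, na), sample(universe, nb), 1000)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("expression comparison is calibrated under the null and powered under a shift", {
  set.seed(21)
  genes <- sprintf("g%04d", 1:2000)
  rejections <- 0
  for (i in 1:1000) {
    expr <- tibble::tibble(gene_id = genes, expression = exp(rnorm(2000, 2, 1)))
    p <- compare_expression(sample(genes, 200), expr)$p_value
    rejections <- rejections + (p < 0.05)
  }
  expect_gt(rejections / 1000, 0.03)
  expect_lt(rejections / 1000, 0.07)

  for (s in 1:20) {
    set.seed(s)
    cand <- sample(genes, 200)
    lo <- rnorm(2000, 2, 1) + (genes %in% cand)
    expr <- tibble::tibble(gene_id = genes, expression = exp(lo))
    res <- compare_expression(cand, expr)
    expect_lt(res$p_value, 0.01)
    expect_gt(res$median_candidates, res$median_background)
  }

  expect_error(
    compare_expression("g0001", tibble::tibble(
      gene_id = c("g0001", "g0002"), expression = c(1, 2)
    )),
    "at least two"
  )
})

test_that("count-breadth correlation matches a direct rank computation", {
  mk <- function(count, breadth) {
    manual_features(
      sprintf("g%02d", seq_along(count)),
      list("d1.count" = count, "d1.breadth" = breadth),
      tibble::tibble(
        column = c("d1.count", "d1.breadth"), dataset_id = "d1",
        feature_type = c("count", "breadth"), assay_class = "epigenetic"
      )
    )
  }
  r <- feature_correlations(mk(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(r$rho, 1)

  # ties: average-rank formula oracle at n = 8
  count <- c(1, 1, 2, 2, 3, 3, 4, 5)
  breadth <- c(5, 7, 7, 9, 9, 9, 12, 11)
  r <- feature_correlations(mk(count, breadth), restrict_to_marked = FALSE)
  expect_equal(r$rho, brute_force_spearman(count, breadth))
  # invariance under strictly monotone transforms
  r2 <- feature_correlations(mk(count, exp(breadth / 3)), restrict_to_marked = FALSE)
  expect_equal(r2$rho, r$rho)

  # independence: near-zero pooled correlation
  set.seed(4)
  big <- mk(1 + rpois(2000, 2), exp(rnorm(2000, 7, 0.5)))
  expect_lt(abs(pooled_count_breadth_rho(big)), 0.05)

  # genes without signal are excluded when restricting to marked genes
  count0 <- c(0, 0, 1, 2, 3, 4)
  r3 <- feature_correlations(mk(count0, c(99, 98, 1, 2, 3, 4)))
  expect_equal(r3$n, 4L)
  expect_equal(r3$rho, 1)

  expect_warning(
    r4 <- feature_correlations(mk(c(0, 0, 0, 1, 2), c(1, 2, 3, 4, 5))),
    "fewer than 3"
  )
  expect_equal(nrow(r4), 0)
})

test_that("distance summaries exclude the sentinel and measure the tails", {
  mk <- function(dist, count = NULL) {
    count <- count %||% rep(1, length(dist))
    manual_features(
      sprintf("g%05d", seq_along(dist)),
      list("d1.count" = count, "d1.distance" = dist),
      tibble::tibble(
        column = c("d1.count", "d1.distance"), dataset_id = "d1",
        feature_type = c("count", "distance"), assay_class = "epigenetic"
      )
    )
  }
  s <- distance_distribution_summary(mk(rep(0, 10)), "d1")
  expect_equal(s$frac_within_10kb, 1)
  expect_equal(s$frac_beyond_100kb, 0)

  # symmetric distances have near-zero median; sentinels are dropped first
  set.seed(7)
  d <- c(round(plurisig:::rlaplace(500, 0, 5000)), rep(1e6, 50))
  s <- distance_distribution_summary(mk(d), "d1")
  expect_equal(s$n, 500L)
  expect_lt(abs(s$median), 700)

  # a planted 10% far tail is recovered
  set.seed(8)
  n <- 2000
  far <- runif(n) < 0.1
  d <- ifelse(far, sample(c(-1, 1), n, TRUE) * runif(n, 150000, 400000),
    round(plurisig:::rlaplace(n, 0, 3000))
  )
  s <- distance_distribution_summary(mk(d), "d1")
  expect_equal(s$frac_beyond_100kb, 0.1, tolerance = 0.02 / 0.1)

  # all-sentinel column is flagged rather than summarized
  s <- distance_distribution_summary(mk(rep(1e6, 5)), "d1")
  expect_true(s$all_missing)
  expect_error(distance_distribution_summary(mk(rep(0, 5)), character()), "empty")
})
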