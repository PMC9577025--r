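test_that("coefficients reproduce hand-computed values", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)

  expect_equal(spearman_cor(c(2, 5, 9, 30), c(1, 2, 3, 7))$r, 1) # monotone
  expect_equal(rank(c(1, 2, 2, 3)), c(1, 2.5, 2.5, 4)) # mid-rank convention
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)

  expect_equal(kendall_tau_b(c(1, 2, 3), c(1, 3, 2))$r, 1 / 3)
  x <- c(4, 1, 9, 2, 7)
  expect_equal(kendall_tau_b(x, -x)$r, -1)
  # tie-corrected value against the exhaustive oracle
  expect_equal(kendall_tau_b(c(1, 1, 2), c(1, 2, 2))$r,
    oracle_tau_b(c(1, 1, 2), c(1, 2, 2)))
})

test_that("constant vectors give flagged undefined results, not zero", {
  res <- pearson_cor(rep(2, 5), 1:5)
  expect_true(is.na(res$r) && is.na(res$p))
  expect_true(is.na(kendall_tau_b(rep(1, 4), c(1, 2, 3, 4))$r))
  expect_true(is.na(spearman_cor(1:4, rep(7, 4))$r))
})

test_that("coefficients are symmetric and rank methods are monotone-invariant", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      x <- rpois(15, 3) + runif(15)
      y <- rpois(15, 3) + runif(15)
      for (f in list(pearson_cor, spearman_cor, kendall_tau_b)) {
        expect_equal(f(x, y)$r, f(y, x)$r, tolerance = 1e-12)
        expect_lte(abs(f(x, y)$r), 1)
      }
      # strictly increasing transform leaves rank methods unchanged
      expect_equal(spearman_cor(log(x + 1), y)$r, spearman_cor(x, y)$r)
      expect_equal(kendall_tau_b(exp(x / 5), y)$r, kendall_tau_b(x, y)$r)
    }
    # Pearson generally is not transform-invariant
    x <- c(1, 2, 3, 50)
    y <- c(1, 2, 3, 4)
    expect_false(isTRUE(all.equal(pearson_cor(log(x), y)$r, pearson_cor(x, y)$r)))
  })
})

test_that("tau-b equals simple tau on tie-free data and matches stats oracles", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      x <- sample(100, 12) + runif(12) # tie-free
      y <- sample(100, 12) + runif(12)
      n <- length(x)
      conc <- 0
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        conc <- conc + sign(x[i] - x[j]) * sign(y[i] - y[j])
      }
      expect_equal(kendall_tau_b(x, y)$r, conc / choose(n, 2), tolerance = 1e-12)
      # independent library oracles
      expect_equal(kendall_tau_b(x, y)$r, cor(x, y, method = "kendall"),
        tolerance = 1e-12)
      expect_equal(spearman_cor(x, y)$r, cor(x, y, method = "spearman"),
        tolerance = 1e-12)
      # mid-rank equivalence under ties
      xt <- rpois(12, 2); yt <- rpois(12, 2)
      if (sd(xt) > 0 && sd(yt) > 0) {
        expect_equal(spearman_cor(xt, yt)$r, pearson_cor(rank(xt), rank(yt))$r)
        expect_equal(kendall_tau_b(xt, yt)$r, cor(xt, yt, method = "kendall"),
          tolerance = 1e-12)
      }
    }
  })
})

test_that("parametric p-values follow the stated approximations", {
  x <- c(1, 2, 3, 4, 6, 5, 8, 7, 9, 11)
  y <- c(2, 1, 4, 3, 5, 7, 6, 9, 10, 8)
  pe <- pearson_cor(x, y)
  tval <- pe$r * sqrt((10 - 2) / (1 - pe$r^2))
  expect_equal(pe$p, 2 * pt(-abs(tval), 8), tolerance = 1e-12)
  # perfect correlation has p = 0 under the t approximation
  expect_equal(pearson_cor(1:5, 2 * (1:5))$p, 0)
  ke <- kendall_tau_b(x, y)
  n <- 10
  S <- ke$r * choose(n, 2) # tie-free here
  expect_equal(ke$p, 2 * pnorm(-abs(3 * S / sqrt(n * (n - 1) * (2 * n + 5) / 2))),
    tolerance = 1e-12)
})

test_that("correlate_all is policy-agnostic on zero-free profiles and order-invariant", {
  withr::with_seed(3, {
    m <- matrix(rpois(4 * 40, 6) + 1, 4, 40)
    p <- toy_profile(m)
    base <- correlate_all(p, "spearman", 1)
    for (pol in 2:6) {
      expect_equal(correlate_all(p, "spearman", pol)[, c("taxon_i", "taxon_j", "r", "p", "n_valid")],
        base[, c("taxon_i", "taxon_j", "r", "p", "n_valid")])
    }
    # shuffling taxon rows leaves the canonical output unchanged
    shuf <- p[sample(nrow(p)), ]
    attr(shuf, "zeronet_meta") <- profile_meta(p)
    expect_equal(
      correlate_all(shuf, "kendall", 5)[, 1:5],
      correlate_all(p, "kendall", 5)[, 1:5]
    )
  })
})

test_that("the minimum-overlap rule is strict and undefined pairs are logged", {
  # two taxa sharing exactly 30 then 31 paired-valid samples under policy 5
  build <- function(n_shared) {
    m <- matrix(0, 2, 40)
    m[1, seq_len(n_shared)] <- rpois(n_shared, 4) + 1
    m[2, seq_len(n_shared)] <- rpois(n_shared, 4) + 1
    toy_profile(m)
  }
  withr::with_seed(13, {
    expect_equal(nrow(correlate_all(build(30), "pearson", 5, min_overlap = 30)), 0L)
    expect_equal(skip_log(correlate_all(build(30), "pearson", 5))$n[1], 1L)
    expect_equal(nrow(correlate_all(build(31), "pearson", 5, min_overlap = 30)), 1L)
  })
  # a constant-after-filtering taxon yields an undefined, logged coefficient
  m <- rbind(rep(3, 40), c(rpois(40, 5) + 1))
  res <- correlate_all(toy_profile(m), "pearson", 5)
  expect_equal(nrow(res), 0L)
  expect_equal(skip_log(res)$n[skip_log(res)$reason == "undefined_coefficient"], 1L)
})

test_that("pair subsampling is uniform, seeded and bounded", {
  res <- random_results(12, 1, seed = 2)
  all_rows <- subsample_pairs(res, nrow(res), seed = 1)
  expect_equal(dplyr::arrange(all_rows, taxon_i, taxon_j),
    dplyr::arrange(res, taxon_i, taxon_j))
  s1 <- subsample_pairs(res, 10, seed = 42)
  s2 <- subsample_pairs(res, 10, seed = 42)
  expect_identical(s1, s2)
  expect_equal(nrow(dplyr::distinct(s1, taxon_i, taxon_j)), 10L)
  expect_error(subsample_pairs(res, nrow(res) + 1), "exceeds")
})
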