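# Closed-form Pearson statistic N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)):
# independent oracle for the chi-square implementation.
chisq_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

test_that("inclusion chi-square matches the closed form without correction", {
  out <- chisq_inclusion(30, 10, 10, 30)
  expect_equal(out$statistic, 20)
  expect_equal(out$statistic, chisq_oracle(30, 10, 10, 30))
  expect_false(out$low_count)

  same <- chisq_inclusion(10, 10, 10, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  tiny <- chisq_inclusion(1, 0, 0, 1)
  expect_equal(tiny$statistic, 2)
  expect_true(tiny$low_count)

  withr::local_seed(51)
  for (i in 1:25) {
    t <- sample(1:40, 4L, replace = TRUE)
    got <- chisq_inclusion(t[1], t[2], t[3], t[4])
    expect_equal(got$statistic, chisq_oracle(t[1], t[2], t[3], t[4]))
    expect_equal(got$p, stats::pchisq(got$statistic, 1, lower.tail = FALSE))
  }

  expect_error(chisq_inclusion(0, 0, 5, 5), class = "spliceops_zero_margin")
  expect_error(chisq_inclusion(-1, 2, 3, 4), class = "spliceops_domain_error")
})

test_that("chi-square is invariant to condition and isoform swaps", {
  withr::local_seed(52)
  for (i in 1:10) {
    t <- sample(1:40, 4L, replace = TRUE)
    base <- chisq_inclusion(t[1], t[2], t[3], t[4])$statistic
    expect_equal(chisq_inclusion(t[3], t[4], t[1], t[2])$statistic, base)
    expect_equal(chisq_inclusion(t[2], t[1], t[4], t[3])$statistic, base)
  }
})

test_that("size factors recover exact scalar multiples", {
  m <- cbind(a = c(10, 20, 30), b = 2 * c(10, 20, 30))
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)

  # identical samples and single sample give unit factors
  expect_equal(unname(estimate_size_factors(cbind(c(5, 7), c(5, 7)))),
               c(1, 1))
  expect_equal(unname(estimate_size_factors(matrix(c(5, 7), ncol = 1))), 1)

  withr::local_seed(53)
  base <- rpois(50, 50) + 1
  scal <- c(0.5, 1, 3.2)
  m3 <- sapply(scal, function(s) s * base)
  sf3 <- estimate_size_factors(m3)
  expect_equal(unname(sf3 / exp(mean(log(sf3)))),
               scal / exp(mean(log(scal))), tolerance = 1e-9)

  # no all-positive feature: error, then pseudo-reference fallback
  mz <- cbind(c(0, 5), c(3, 0))
  expect_error(estimate_size_factors(mz),
               class = "spliceops_normalization_error")
  expect_true(all(estimate_size_factors(mz, fallback = "positive") > 0))
})

test_that("BH adjustment follows the step-up construction", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "spliceops_domain_error")

  withr::local_seed(54)
  p <- runif(100)
  q <- bh_adjust(p)
  # monotone in the sorted order, bounded by [p, 1]
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p & q <= 1))
  # idempotent where the step-up construction is a fixed point: constant
  # vectors and step-up plateaus
  expect_equal(bh_adjust(rep(0.2, 5L)), rep(0.2, 5L))
  expect_equal(bh_adjust(rep(0.04, 4L)), rep(0.04, 4L))
})

test_that("NB test returns p = 1 for constant and all-zero features", {
  m <- rbind(c(50, 50, 50, 50, 50, 50),
             c(0, 0, 0, 0, 0, 0),
             c(40, 60, 50, 30, 70, 50))
  rownames(m) <- c("flat", "zero", "noisy")
  res <- diff_counts(m, rep(c("A", "B"), each = 3),
                     size_factors = rep(1, 6))
  expect_equal(res$p[res$feature_id == "flat"], 1)
  expect_equal(res$status[res$feature_id == "zero"], "zero")
  expect_equal(res$p[res$feature_id == "zero"], 1)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_error(diff_counts(m, rep("A", 6)), class = "spliceops_design_error")
})

test_that("NB test holds its size on a Poisson null", {
  withr::local_seed(55)
  m <- matrix(rpois(200 * 6, 100), nrow = 200)
  colnames(m) <- paste0("s", 1:6)
  res <- diff_counts(m, rep(c("A", "B"), each = 3))
  rejected <- sum(res$p < 0.05)
  bounds <- qbinom(c(0.025, 0.975), 200, 0.05)
  expect_gte(rejected, bounds[1L])
  expect_lte(rejected, bounds[2L])
})

test_that("NB test separates direction-balanced 4-fold changes with FDR control", {
  withr::local_seed(56)
  size <- 1 / 0.1          # dispersion alpha = 0.1
  mu_b <- c(rep(400, 100), rep(25, 100), rep(100, 800))
  a <- matrix(rnbinom(1000 * 3, mu = 100, size = size), nrow = 1000)
  b <- matrix(rnbinom(1000 * 3, mu = mu_b, size = size), nrow = 1000)
  m <- cbind(a, b)
  colnames(m) <- paste0("s", 1:6)
  res <- diff_counts(m, rep(c("A", "B"), each = 3))
  true_idx <- 1:200
  expect_lt(median(res$p[true_idx]), median(res$p[-true_idx]))
  hits <- which(res$q < 0.05)
  expect_gt(length(hits), 0L)
  expect_lte(mean(hits > 200), 0.10)
})

test_that("tidy, glance and autoplot work on the diff fit", {
  withr::local_seed(57)
  m <- matrix(rpois(60 * 4, 50), nrow = 60)
  colnames(m) <- paste0("s", 1:4)
  res <- diff_counts(m, c("A", "A", "B", "B"))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("feature_id", "p", "q", "log2_fc") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_features, 60L)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
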