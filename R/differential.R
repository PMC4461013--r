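#' Chi-square test on inclusion counts between two conditions
#'
#' Pearson chi-square (no continuity correction) on the 2x2 table of
#' inclusion/skipping supporting counts in conditions A and B; p from the
#' chi-square distribution with one degree of freedom. Tables with any
#' expected cell below 5 are still tested but flagged `low_count`. A zero row
#' or column margin makes the table untestable and raises an error.
#'
#' Vectorised over its four arguments.
#'
#' @param n_inc_a,n_skip_a,n_inc_b,n_skip_b Non-negative counts.
#' @return A tibble: `statistic`, `p`, `low_count`.
#' @export
chisq_inclusion <- function(n_inc_a, n_skip_a, n_inc_b, n_skip_b) {
  counts <- cbind(n_inc_a, n_skip_a, n_inc_b, n_skip_b)
  if (any(counts < 0)) {
    stop_spliceops("counts must be non-negative", "spliceops_domain_error")
  }
  out <- tibble(statistic = rep(NA_real_, nrow(counts)),
                p = NA_real_, low_count = NA)
  for (i in seq_len(nrow(counts))) {
    m <- matrix(counts[i, ], nrow = 2L, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      stop_spliceops("2x2 table has a zero margin (untestable)",
                     "spliceops_zero_margin")
    }
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    out$statistic[i] <- unname(ct$statistic)
    out$p[i] <- ct$p.value
    out$low_count[i] <- any(expected < 5)
  }
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over features — restricted to
#' features with positive counts in every sample — of the ratio of the
#' sample's count to the feature's geometric mean across samples. Samples
#' that are exact scalar multiples of one another recover those scalars up to
#' a common normalisation.
#'
#' @param counts Feature-by-sample matrix or data frame of non-negative
#'   counts (features as rows).
#' @param fallback With no all-positive feature, `"error"` (default) aborts;
#'   `"positive"` uses, per feature, the geometric mean over its positive
#'   entries and takes medians over each sample's positive counts
#'   (pseudo-reference fallback).
#' @return Named numeric vector of positive per-sample factors.
#' @export
estimate_size_factors <- function(counts, fallback = c("error", "positive")) {
  fallback <- match.arg(fallback)
  m <- as.matrix(counts)
  if (ncol(m) == 1L) return(stats::setNames(1, colnames(m)))
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    if (fallback == "error") {
      stop_spliceops(
        paste0("no feature has positive counts in every sample; ",
               "consider fallback = \"positive\" (pseudo-reference)"),
        "spliceops_normalization_error")
    }
    log_gm <- apply(m, 1L, function(r) mean(log(r[r > 0])))
    sf <- apply(m, 2L, function(col) {
      ok <- col > 0 & is.finite(log_gm)
      exp(stats::median(log(col[ok]) - log_gm[ok]))
    })
  } else {
    mp <- m[all_pos, , drop = FALSE]
    log_gm <- rowMeans(log(mp))
    sf <- apply(mp, 2L, function(col) exp(stats::median(log(col) - log_gm)))
  }
  stats::setNames(sf, colnames(m))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of p_(j) * m / j, capped
#' at 1, returned in the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order and length.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop_spliceops("p-values must lie in [0, 1]", "spliceops_domain_error")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Simplified negative-binomial differential count test
#'
#' Two-condition test on a features-by-samples count matrix following the
#' classical count-model decomposition of the per-feature variance into a raw
#' (biological) variance term plus shot noise: Var = mu + alpha * mu^2.
#' Counts are normalised by median-of-ratios size factors. The dispersion
#' alpha is estimated per feature by method of moments across replicates and
#' shrunk toward the mean dispersion of features with similar expression
#' (bins of the normalised mean holding at least `min_bin` features where
#' possible). Without replicates in either condition, alpha is pooled across
#' conditions from the cross-condition estimate — a documented limitation: a
#' real biological difference then inflates the null variance.
#'
#' The p-value conditions on the feature's total count: with condition sums
#' KA + KB = K fixed, the probability of every split (a, K - a) is computed
#' from the two conditions' NB laws; the two-sided p doubles the smaller tail
#' of that conditional split distribution, with a mid-p correction (half
#' weight on the observed split) to offset the discreteness that otherwise
#' makes exact conditional tests conservative. Features with zero total get
#' status `zero` and p = 1.
#'
#' @param counts Feature-by-sample matrix/data frame of non-negative integer
#'   counts, with feature ids as row names.
#' @param condition Factor/character vector, one label per column; exactly
#'   two levels.
#' @param size_factors Optional precomputed factors (default: estimated).
#' @param min_bin Minimum features per dispersion bin (default 20).
#' @param sf_fallback Passed to [estimate_size_factors()].
#' @return An object of class `spliceops_nbdiff`: a tibble with `feature_id`,
#'   `base_mean_a`, `base_mean_b`, `log2_fc`, `statistic` (the dispersion
#'   used), `p`, `q`, `status`; `tidy()` returns it, `glance()` summarises,
#'   `autoplot()` draws an MA plot.
#' @export
diff_counts <- function(counts, condition, size_factors = NULL,
                        min_bin = 20L, sf_fallback = "error") {
  m <- as.matrix(counts)
  if (any(m < 0)) {
    stop_spliceops("counts must be non-negative", "spliceops_domain_error")
  }
  condition <- as.character(condition)
  lev <- unique(condition)
  if (length(condition) != ncol(m) || length(lev) != 2L) {
    stop_spliceops("exactly two conditions, one label per sample, required",
                   "spliceops_design_error")
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  sf <- size_factors %||% estimate_size_factors(m, fallback = sf_fallback)
  q <- sweep(m, 2L, sf, "/")                       # normalised counts
  ia <- condition == lev[1L]; ib <- condition == lev[2L]
  mu <- rowMeans(q)
  alpha <- pool_dispersions(q, ia, ib, min_bin = min_bin)

  base_a <- rowMeans(q[, ia, drop = FALSE])
  base_b <- rowMeans(q[, ib, drop = FALSE])
  res <- tibble(
    feature_id = rownames(m),
    base_mean_a = base_a, base_mean_b = base_b,
    log2_fc = log2((base_b + 0.5) / (base_a + 0.5)),
    statistic = alpha, p = NA_real_, status = "tested")
  for (i in seq_len(nrow(m))) {
    ka <- sum(m[i, ia]); kb <- sum(m[i, ib])
    if (ka + kb == 0) {
      res$p[i] <- 1; res$status[i] <- "zero"; next
    }
    res$p[i] <- nb_exact_p(ka, kb, mu_hat = mu[i], alpha = alpha[i],
                           sf_a = sf[ia], sf_b = sf[ib])
  }
  res$q <- bh_adjust(res$p)
  res <- res |>
    select("feature_id", "base_mean_a", "base_mean_b", "log2_fc",
           "statistic", "p", "q", "status")
  class(res) <- c("spliceops_nbdiff", class(res))
  res
}

# Method-of-moments dispersions with binned pooling by expression level.
pool_dispersions <- function(q, ia, ib, min_bin = 20L) {
  mu <- rowMeans(q)
  has_reps <- sum(ia) > 1L || sum(ib) > 1L
  raw <- if (has_reps) {
    # within-condition moments, averaged over conditions that have replicates
    per_cond <- function(idx) {
      if (sum(idx) < 2L) return(rep(NA_real_, nrow(q)))
      mus <- rowMeans(q[, idx, drop = FALSE])
      vars <- apply(q[, idx, drop = FALSE], 1L, stats::var)
      ifelse(mus > 0, (vars - mus) / mus^2, NA_real_)
    }
    rowMeans(cbind(per_cond(ia), per_cond(ib)), na.rm = TRUE)
  } else {
    # no replicates anywhere: pool across conditions (blind estimate)
    vars <- apply(q, 1L, stats::var)
    ifelse(mu > 0, (vars - mu) / mu^2, NA_real_)
  }
  raw[!is.finite(raw)] <- NA_real_
  # the trend is taken over unfloored estimates: flooring each feature at 0
  # first would bias the trend upward when the true dispersion is ~0
  # shrink toward the trend over expression bins (>= min_bin features each)
  ok <- mu > 0
  n_ok <- sum(ok)
  if (n_ok == 0L) return(rep(0, nrow(q)))
  n_bins <- max(1L, min(floor(n_ok / min_bin), 20L))
  br <- unique(stats::quantile(mu[ok], probs = seq(0, 1, length.out =
                                                     n_bins + 1L)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  trend <- tapply(raw, bin, mean, na.rm = TRUE)
  trend[!is.finite(trend)] <- mean(raw, na.rm = TRUE)
  fitted <- pmax(as.numeric(trend[bin]), 0)
  fitted[!is.finite(fitted)] <- 0
  # conservative pooling: never let a noisy per-feature estimate fall below
  # the trend of similarly expressed features
  alpha <- ifelse(is.na(raw), fitted, pmax(raw, fitted))
  pmax(alpha, 0)
}

# Conditional two-sided NB p-value for one feature: doubled smaller tail of
# the split distribution given the total, with a mid-p correction for
# discreteness. Under the null both conditions share normalised mean mu_hat;
# the sum over condition c has mean mu_hat * sum(sf_c) and variance
# sum(sf_j * mu_hat + alpha * (sf_j * mu_hat)^2).
nb_exact_p <- function(ka, kb, mu_hat, alpha, sf_a, sf_b,
                       max_exact = 100000L) {
  k <- ka + kb
  pa <- nb_sum_params(mu_hat, alpha, sf_a)
  pb <- nb_sum_params(mu_hat, alpha, sf_b)
  if (k > max_exact) {
    # marginal-tail fallback for very deep features
    p1 <- stats::pnbinom(ka - 1, mu = pa$mu, size = pa$size) +
      0.5 * stats::dnbinom(ka, mu = pa$mu, size = pa$size)
    return(min(1, 2 * min(p1, 1 - p1)))
  }
  a <- 0:k
  lp <- stats::dnbinom(a, mu = pa$mu, size = pa$size, log = TRUE) +
    stats::dnbinom(k - a, mu = pb$mu, size = pb$size, log = TRUE)
  pr <- exp(lp - logsumexp(lp))
  lo <- sum(pr[a < ka]) + 0.5 * pr[ka + 1L]
  hi <- sum(pr[a > ka]) + 0.5 * pr[ka + 1L]
  min(1, 2 * min(lo, hi))
}

nb_sum_params <- function(mu_hat, alpha, sf) {
  mu <- mu_hat * sum(sf)
  v <- sum(sf * mu_hat + alpha * (sf * mu_hat)^2)
  size <- if (v > mu) mu^2 / (v - mu) else 1e8   # Poisson limit
  list(mu = mu, size = size)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  mx <- max(x)
  if (!is.finite(mx)) return(-Inf)
  mx + log(sum(exp(x - mx)))
}

#' @exportS3Method generics::tidy
tidy.spliceops_nbdiff <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.spliceops_nbdiff <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_tested = sum(x$status == "tested"),
         n_zero = sum(x$status == "zero"),
         n_sig_q05 = sum(x$q < 0.05, na.rm = TRUE),
         median_dispersion = stats::median(x$statistic, na.rm = TRUE))
}
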