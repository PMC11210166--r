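#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_j w_j (r_j - \hat\theta_{IVW,fixed})^2} over the per-variant
#' Wald ratios, compared to a chi-square with k - 1 degrees of freedom
#' (upper tail). The fixed-effect IVW center is used regardless of the
#' reporting model (standard definition). A small p-value flags
#' heterogeneity — in MR, potential horizontal pleiotropy — and motivates the
#' random-effects model.
#'
#' @param x a `harmonized_set` or pair table with at least 2 variants.
#' @return List (`q_test`): `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(x) {
  wr <- wald_ratio(x)
  k <- nrow(wr)
  if (k < 2) stop_mr("cochran_q needs >= 2 instruments; got %d", k)
  beta <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  q <- sum(wr$weight * (wr$ratio - beta)^2)
  structure(list(q = q, df = k - 1L,
                 pvalue = stats::pchisq(q, df = k - 1, lower.tail = FALSE)),
            class = "q_test")
}

#' @export
print.q_test <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.4g\n", x$q, x$df, x$pvalue))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' A view over [mr_egger()]'s intercept: the average pleiotropic effect, its
#' standard error and a two-sided p-value.
#'
#' @inheritParams mr_egger
#' @return List: `intercept`, `se`, `pvalue`.
#' @export
egger_intercept_test <- function(x, ci = c("normal", "t")) {
  e <- mr_egger(x, ci = ci)
  list(intercept = e$extra$intercept, se = e$extra$intercept_se,
       pvalue = e$extra$intercept_pvalue)
}

# Leave-one-out IVW slopes through the origin, vectorized: slope_(-j) from
# the weighted sums minus variant j's contribution.
loo_slopes <- function(bx, by, w) {
  s_xy <- sum(w * bx * by)
  s_xx <- sum(w * bx^2)
  (s_xy - w * bx * by) / (s_xx - w * bx^2)
}

presso_rss <- function(bx, by, w) {
  slopes <- loo_slopes(bx, by, w)
  resid <- by - slopes * bx
  list(rss = sum(w * resid^2), resid2 = w * resid^2, slopes = slopes)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based sensitivity analysis with three procedures: (a) a global
#' test for horizontal pleiotropy, comparing the observed leave-one-out
#' weighted residual sum of squares against its parametric null distribution;
#' (b) a per-variant outlier test on each observed squared residual
#' (Bonferroni-adjusted across variants); and (c) a distortion test for the
#' difference between the causal estimate before and after removing flagged
#' outliers, referenced to the distribution obtained by removing random
#' variant subsets of the same size.
#'
#' For each variant j the expected outcome effect is taken from the IVW fit
#' excluding j; null datasets redraw every `beta_x` from
#' `N(beta_x, se_x^2)` and every `beta_y` from `N(slope_(-j) * beta_x,
#' se_y^2)`, and the statistic is recomputed identically. The global p-value
#' is `(1 + #[RSS_sim >= RSS_obs]) / (n_sim + 1)`, bounded below by
#' `1/(n_sim+1)`.
#'
#' @param x a `harmonized_set` or pair table with at least 4 variants
#'   (leave-one-out fits need 3 remaining).
#' @param n_sim number of null simulations (default 1000; fewer than 100
#'   draws a warning).
#' @param seed integer seed (required; same seed and inputs give a
#'   bit-identical result).
#' @param outlier_alpha significance level for the Bonferroni-adjusted
#'   per-variant outlier test (default 0.05).
#' @return A `presso_result`: `rss_obs`, `global_pvalue`, `n_sim`,
#'   `outlier_pvalues` (adjusted, with the adjustment flagged), `outliers`,
#'   `beta_raw`, and — only when outliers are flagged — `beta_corrected` and
#'   `distortion_pvalue`.
#' @export
mr_presso <- function(x, n_sim = 1000, seed, outlier_alpha = 0.05) {
  if (missing(seed) || is.null(seed)) {
    stop_mr("mr_presso: a seed is required for the null simulations")
  }
  p <- as_mr_pairs(x)
  k <- nrow(p)
  if (k < 4) stop_mr("mr_presso needs >= 4 instruments; got %d", k)
  if (n_sim < 100) warning("mr_presso: n_sim < 100 gives a very coarse p-value")
  w <- 1 / p$se_y^2
  obs <- presso_rss(p$beta_x, p$beta_y, w)

  res <- with_seed(seed, {
    exceed_global <- 0L
    exceed_resid <- numeric(k)
    for (s in seq_len(n_sim)) {
      bx <- stats::rnorm(k, p$beta_x, p$se_x)
      by <- stats::rnorm(k, obs$slopes * p$beta_x, p$se_y)
      sim <- presso_rss(bx, by, w)
      exceed_global <- exceed_global + (sim$rss >= obs$rss)
      exceed_resid <- exceed_resid + (sim$resid2 >= obs$resid2)
    }
    list(global = exceed_global, resid = exceed_resid)
  })
  global_pvalue <- (1 + res$global) / (n_sim + 1)
  p_raw <- (1 + res$resid) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * k)
  outliers <- p$snp[p_adj < outlier_alpha]

  beta_raw <- mr_ivw(p, model = "fixed")$beta
  beta_corrected <- NULL
  distortion_pvalue <- NULL
  if (length(outliers) > 0 && length(outliers) < k - 1) {
    keep <- !p$snp %in% outliers
    beta_corrected <- mr_ivw(p[keep, , drop = FALSE], model = "fixed")$beta
    d_obs <- beta_raw - beta_corrected
    d_sim <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(s) {
        drop_idx <- sample.int(k, length(outliers))
        beta_raw - mr_ivw(p[-drop_idx, , drop = FALSE], model = "fixed")$beta
      }, numeric(1))
    })
    distortion_pvalue <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }

  structure(list(rss_obs = obs$rss, global_pvalue = global_pvalue,
                 n_sim = n_sim,
                 outlier_pvalues = stats::setNames(p_adj, p$snp),
                 outlier_adjustment = "bonferroni",
                 outliers = outliers, distortion_pvalue = distortion_pvalue,
                 beta_raw = beta_raw, beta_corrected = beta_corrected,
                 seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g (%d sims)\n",
              x$rss_obs, x$global_pvalue, x$n_sim))
  if (length(x$outliers)) {
    cat(sprintf("  outliers: %s\n  beta %0.4g -> %0.4g (distortion p = %.3g)\n",
                paste(x$outliers, collapse = ", "), x$beta_raw,
                x$beta_corrected, x$distortion_pvalue))
  } else cat("  no outliers flagged\n")
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW causal effect excluding each variant in turn; a row
#' whose estimate moves materially, or whose interval conclusion flips,
#' flags a single dominant instrument. The final row (`snp = "(full set)"`)
#' is the all-variant estimate.
#'
#' @param x a `harmonized_set` or pair table with at least 2 variants.
#' @param model IVW model for every fit (match the main analysis).
#' @return A data frame with `nsnp + 1` rows: excluded `snp`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`; attribute `sign_consistency` gives the
#'   fraction of leave-one-out rows whose interval agrees with the full-set
#'   conclusion about excluding zero.
#' @export
leave_one_out <- function(x, model = c("fixed", "random")) {
  model <- match.arg(model)
  p <- as_mr_pairs(x)
  k <- nrow(p)
  if (k < 2) stop_mr("leave_one_out needs >= 2 instruments; got %d", k)
  one <- function(est, label) {
    data.frame(snp = label, beta = est$beta, se = est$se, ci_low = est$ci_low,
               ci_high = est$ci_high, pvalue = est$pvalue,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(k), function(i) {
    one(mr_ivw(p[-i, , drop = FALSE], model = model), p$snp[i])
  })
  full <- mr_ivw(p, model = model)
  out <- rbind(do.call(rbind, rows), one(full, "(full set)"))
  rownames(out) <- NULL
  full_excl0 <- full$ci_low > 0 || full$ci_high < 0
  loo_excl0 <- out$ci_low[seq_len(k)] > 0 | out$ci_high[seq_len(k)] < 0
  attr(out, "sign_consistency") <- mean(loo_excl0 == full_excl0)
  out
}

#' Data tables behind the standard MR figures
#'
#' Emits the numbers the usual forest, funnel and scatter plots are drawn
#' from; rendering is left to the caller.
#'
#' @param x a `harmonized_set` or pair table.
#' @param estimates optional list of `mr_estimate` summary rows to append to
#'   the forest table; defaults to fixed/random IVW plus MR-Egger when
#'   enough variants are available.
#' @param seed seed forwarded to the weighted median if it is computed here.
#' @return List of data frames: `forest` (per-variant ratio with 95% CI plus
#'   summary rows), `funnel` (ratio vs precision `1/se_ratio`), `scatter`
#'   (`beta_x`, `beta_y`, `se_x`, `se_y`) with fitted slopes/intercepts as
#'   attribute `fits`.
#' @export
funnel_and_forest_data <- function(x, estimates = NULL, seed = 1L) {
  p <- as_mr_pairs(x)
  wr <- wald_ratio(p)
  z <- stats::qnorm(0.975)
  forest <- data.frame(label = wr$snp, type = "snp", beta = wr$ratio,
                       ci_low = wr$ratio - z * wr$se_ratio,
                       ci_high = wr$ratio + z * wr$se_ratio,
                       stringsAsFactors = FALSE)
  if (is.null(estimates)) {
    estimates <- list(mr_ivw(p, "fixed"))
    if (nrow(p) >= 2) estimates <- c(estimates, list(mr_ivw(p, "random")))
    if (nrow(p) >= 3) {
      # degenerate geometries (e.g. constant beta_x) have no Egger fit
      more <- tryCatch(list(mr_egger(p), mr_weighted_median(p, seed = seed)),
                       error = function(e) list())
      estimates <- c(estimates, more)
    }
  }
  for (e in estimates) {
    forest <- rbind(forest, data.frame(label = e$method, type = "summary",
                                       beta = e$beta, ci_low = e$ci_low,
                                       ci_high = e$ci_high,
                                       stringsAsFactors = FALSE))
  }
  funnel <- data.frame(snp = wr$snp, ratio = wr$ratio,
                       precision = 1 / wr$se_ratio, stringsAsFactors = FALSE)
  scatter <- p[, c("snp", "beta_x", "se_x", "beta_y", "se_y")]
  fits <- data.frame(
    method = vapply(estimates, `[[`, character(1), "method"),
    slope = vapply(estimates, `[[`, numeric(1), "beta"),
    intercept = vapply(estimates,
                       function(e) e$extra$intercept %||% 0, numeric(1)),
    stringsAsFactors = FALSE)
  attr(scatter, "fits") <- fits
  list(forest = forest, funnel = funnel, scatter = scatter)
}
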