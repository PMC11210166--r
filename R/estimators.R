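#' @rdname mr_ivw
#' @export
as_mr_pairs <- function(x) {
  if (inherits(x, "harmonized_set")) x <- x$pairs
  x <- as.data.frame(x)
  needed <- c("beta_x", "se_x", "beta_y", "se_y")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop_mr("not a harmonized pair table; missing: %s",
            paste(missing_cols, collapse = ", "))
  }
  if (!"snp" %in% names(x)) x$snp <- sprintf("snp_%d", seq_len(nrow(x)))
  x
}

new_mr_estimate <- function(method, beta, se, nsnp, pvalue = NULL,
                            ci_mult = stats::qnorm(0.975), extra = list()) {
  est <- structure(list(
    method = method, beta = beta, se = se,
    ci_low = beta - ci_mult * se, ci_high = beta + ci_mult * se,
    pvalue = pvalue %||% 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE),
    nsnp = nsnp, extra = extra), class = "mr_estimate")
  to_odds_ratio(est)
}

#' Report a causal estimate on the odds-ratio scale
#'
#' Exponentiates the log-scale point estimate and confidence bounds. Both
#' scales are kept on the object and printed with explicit labels; published
#' MR tables sometimes print an OR next to log-scale confidence bounds, an
#' ambiguity this report avoids.
#'
#' @param estimate an `mr_estimate`.
#' @return The estimate with `or_point`, `or_ci_low`, `or_ci_high` filled.
#' @export
to_odds_ratio <- function(estimate) {
  estimate$or_point <- exp(estimate$beta)
  estimate$or_ci_low <- exp(estimate$ci_low)
  estimate$or_ci_high <- exp(estimate$ci_high)
  estimate
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s (%d SNPs)\n  log scale: beta %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n  OR  scale: %.4g, 95%% CI [%.4g, %.4g]\n",
    x$method, x$nsnp, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue,
    x$or_point, x$or_ci_low, x$or_ci_high))
  invisible(x)
}

#' Per-variant Wald ratios
#'
#' The single-instrument causal estimate `beta_y / beta_x` with first-order
#' delta-method standard error `se_y / |beta_x|` (exposure-side uncertainty
#' ignored, the convention under which IVW is a weighted mean of ratios with
#' weights `1/se_ratio^2`).
#'
#' @param x a `harmonized_set` or pair table.
#' @return Data frame: `snp`, `ratio`, `se_ratio`, `weight`.
#' @export
wald_ratio <- function(x) {
  p <- as_mr_pairs(x)
  zero <- !is.na(p$beta_x) & p$beta_x == 0
  if (any(zero)) {
    stop_mr("wald_ratio undefined for beta_x = 0: %s",
            paste(p$snp[zero], collapse = ", "))
  }
  data.frame(snp = p$snp, ratio = p$beta_y / p$beta_x,
             se_ratio = p$se_y / abs(p$beta_x),
             weight = p$beta_x^2 / p$se_y^2, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal estimate
#'
#' The main estimator: an inverse-variance-weighted meta-analysis of the
#' per-variant Wald ratios, \eqn{\hat\theta = \sum w_j r_j / \sum w_j} with
#' \eqn{w_j = 1/se(r_j)^2}. The fixed-effect standard error is
#' \eqn{1/\sqrt{\sum w_j}}; the multiplicative random-effects model inflates
#' it by \eqn{\sqrt{\max(1, Q/(k-1))}} where Q is Cochran's heterogeneity
#' statistic. Algebraically identical to weighted least squares of `beta_y`
#' on `beta_x` through the origin with weights `1/se_y^2`.
#'
#' @param x a `harmonized_set` or pair table.
#' @param model `"fixed"` or `"random"` (multiplicative).
#' @return An `mr_estimate`; `extra` carries Q, its df and the variance
#'   inflation factor.
#' @export
mr_ivw <- function(x, model = c("fixed", "random")) {
  model <- match.arg(model)
  wr <- wald_ratio(x)
  k <- nrow(wr)
  if (k < 1) stop_mr("mr_ivw: no instruments")
  w <- wr$weight
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (wr$ratio - beta)^2)
  scale <- if (k >= 2) sqrt(max(1, q / (k - 1))) else 1
  se <- if (model == "random") se_fixed * scale else se_fixed
  new_mr_estimate(paste0("ivw_", model), beta, se, k,
                  extra = list(q = q, df = k - 1, scale = scale,
                               se_fixed = se_fixed))
}

# Orient pairs so beta_x >= 0 (flip both betas of a pair together; the Wald
# ratio, and hence every estimator, is unchanged).
orient_pairs <- function(p) {
  flip <- p$beta_x < 0
  p$beta_x[flip] <- -p$beta_x[flip]
  p$beta_y[flip] <- -p$beta_y[flip]
  p
}

#' MR-Egger regression
#'
#' Weighted least squares of the (orientation-aligned) outcome effects on the
#' exposure effects with a free intercept and weights `1/se_y^2`. The slope
#' is the causal estimate, consistent under the InSiDE assumption; the
#' intercept estimates the average directional pleiotropic effect and its
#' test is the standard directional-pleiotropy diagnostic. Standard errors
#' are the fixed-effect WLS errors inflated by the residual standard
#' deviation when it exceeds 1 (multiplicative overdispersion, truncated at
#' 1), matching the convention of the common MR toolchain.
#'
#' @param x a `harmonized_set` or pair table with at least 3 variants.
#' @param ci `"normal"` (default, 1.96-type intervals and normal p-values) or
#'   `"t"` (t with k - 2 df).
#' @return An `mr_estimate` for the slope; `extra` carries `intercept`,
#'   `intercept_se`, `intercept_pvalue` and the residual scale.
#' @export
mr_egger <- function(x, ci = c("normal", "t")) {
  ci <- match.arg(ci)
  p <- orient_pairs(as_mr_pairs(x))
  k <- nrow(p)
  if (k < 3) {
    stop_mr("mr_egger needs >= 3 instruments (slope plus pleiotropy intercept); got %d", k)
  }
  w <- 1 / p$se_y^2
  X <- cbind(intercept = 1, slope = p$beta_x)
  xtwx <- crossprod(X, X * w)
  coefs <- drop(solve(xtwx, crossprod(X, p$beta_y * w)))
  resid <- p$beta_y - drop(X %*% coefs)
  sigma2 <- sum(w * resid^2) / (k - 2)
  se_fixed <- sqrt(diag(solve(xtwx)))
  infl <- max(1, sqrt(sigma2))
  se <- se_fixed * infl

  if (ci == "t") {
    mult <- stats::qt(0.975, df = k - 2)
    pfun <- function(est, s) 2 * stats::pt(abs(est / s), df = k - 2,
                                           lower.tail = FALSE)
  } else {
    mult <- stats::qnorm(0.975)
    pfun <- function(est, s) 2 * stats::pnorm(abs(est / s), lower.tail = FALSE)
  }
  new_mr_estimate("egger_slope", coefs[["slope"]], se[["slope"]], k,
                  pvalue = pfun(coefs[["slope"]], se[["slope"]]),
                  ci_mult = mult,
                  extra = list(intercept = coefs[["intercept"]],
                               intercept_se = se[["intercept"]],
                               intercept_pvalue = pfun(coefs[["intercept"]],
                                                       se[["intercept"]]),
                               residual_scale = infl, ci = ci))
}

# Interpolated weighted median of `values` under nonnegative `weights`:
# order values, form percentiles (cumsum(w) - w/2)/sum(w), and linearly
# interpolate the value at percentile 0.5.
weighted_median_point <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord] / sum(weights)
  pctl <- cumsum(w) - w / 2
  if (0.5 <= pctl[1]) return(v[1])
  if (0.5 >= pctl[length(pctl)]) return(v[length(v)])
  stats::approx(pctl, v, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The inverse-variance weighted median of the per-variant Wald ratios:
#' consistent when instruments carrying at least half of the total weight are
#' valid, at the cost of wider intervals than IVW. The point estimate
#' interpolates the ratio at cumulative weight 0.5; the standard error comes
#' from a seeded parametric bootstrap that redraws each variant's exposure
#' and outcome betas from their sampling distributions.
#'
#' @param x a `harmonized_set` or pair table with at least 3 variants.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed (required: the bootstrap must be reproducible).
#' @return An `mr_estimate`; `extra` records `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(x, n_boot = 1000, seed) {
  if (missing(seed) || is.null(seed)) {
    stop_mr("mr_weighted_median: a seed is required for the bootstrap SE")
  }
  p <- as_mr_pairs(x)
  k <- nrow(p)
  if (k < 3) stop_mr("mr_weighted_median needs >= 3 instruments; got %d", k)
  wr <- wald_ratio(p)
  beta <- weighted_median_point(wr$ratio, wr$weight)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, p$beta_x, p$se_x)
      by <- stats::rnorm(k, p$beta_y, p$se_y)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / p$se_y[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  new_mr_estimate("weighted_median", beta, se, k,
                  extra = list(n_boot = n_boot, seed = seed))
}

#' Serialize estimates to a flat results table
#'
#' @param estimates a list of `mr_estimate` objects.
#' @return Data frame with one row per estimate: method, nsnp, both scales,
#'   and flattened method-specific extras.
#' @export
mr_estimates_table <- function(estimates) {
  rows <- lapply(estimates, function(e) {
    data.frame(method = e$method, nsnp = e$nsnp, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               or_point = e$or_point, or_ci_low = e$or_ci_low,
               or_ci_high = e$or_ci_high,
               egger_intercept = e$extra$intercept %||% NA_real_,
               egger_intercept_pvalue = e$extra$intercept_pvalue %||% NA_real_,
               q = e$extra$q %||% NA_real_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
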