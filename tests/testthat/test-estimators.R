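test_that("wald ratios follow the delta-method definition", {
  p <- make_pairs(beta_x = 0.01, beta_y = 0.02, se_y = 0.005)
  wr <- wald_ratio(p)
  expect_equal(wr$ratio, 2.0)
  expect_equal(wr$se_ratio, 0.5)
  expect_equal(wr$weight, 1 / 0.5^2)

  expect_equal(wald_ratio(make_pairs(0.01, 0))$ratio, 0)
  # joint sign flip leaves the ratio unchanged
  expect_equal(wald_ratio(make_pairs(-0.01, -0.02))$ratio, 2.0)

  expect_error(wald_ratio(make_pairs(c(0.01, 0), c(0.1, 0.1),
                                     snp = c("ok", "bad"))), "bad")
})

test_that("IVW matches hand-computed weighted means and degenerate cases", {
  # single SNP: equals its Wald ratio exactly
  p1 <- make_pairs(0.02, 0.05, se_y = 0.004)
  e1 <- mr_ivw(p1, "fixed")
  expect_equal(e1$beta, 2.5)
  expect_equal(e1$se, 0.004 / 0.02)
  expect_equal(mr_ivw(p1, "random")$se, e1$se)  # no Q with one SNP

  # two ratios 1 and 3 with unit SEs -> beta 2, se 1/sqrt(2)
  p2 <- make_pairs(c(1, 1), c(1, 3), se_y = 1)
  e2 <- mr_ivw(p2, "fixed")
  expect_equal(e2$beta, 2.0)
  expect_equal(e2$se, 1 / sqrt(2))
  expect_equal(e2$ci_low, 2 - qnorm(0.975) / sqrt(2))

  expect_error(mr_ivw(make_pairs(numeric(0), numeric(0))), "no instruments")
})

test_that("IVW fixed equals origin-constrained WLS on random sets", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(3:30, 1)
    p <- make_pairs(rnorm(k, 0, 0.1), rnorm(k, 0, 0.1),
                    se_y = runif(k, 0.005, 0.05))
    got <- mr_ivw(p, "fixed")$beta
    fit <- lm(beta_y ~ 0 + beta_x, data = p, weights = 1 / p$se_y^2)
    expect_equal(got, unname(coef(fit)[1]), tolerance = 1e-10)
  }
})

test_that("random-effects SE inflates exactly when Q exceeds its df", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(2:25, 1)
    p <- make_pairs(rnorm(k, 0.05, 0.02), rnorm(k, 0.01, 0.02),
                    se_y = runif(k, 0.005, 0.05))
    ef <- mr_ivw(p, "fixed"); er <- mr_ivw(p, "random")
    expect_gte(er$se, ef$se)
    q <- cochran_q(p)
    if (q$q <= k - 1) expect_equal(er$se, ef$se)
    else expect_equal(er$se, ef$se * sqrt(q$q / (k - 1)))
  }
})

test_that("Egger regression recovers an exact line and its identities", {
  p <- make_pairs(c(1, 2, 3), c(1.1, 2.1, 3.1), se_y = 1)
  e <- mr_egger(p)
  expect_equal(e$beta, 1.0, tolerance = 1e-12)
  expect_equal(e$extra$intercept, 0.1, tolerance = 1e-12)
  expect_equal(e$extra$residual_scale, 1)  # zero residual, truncated at 1

  # with all outcome effects zero, slope and intercept are zero
  e0 <- mr_egger(make_pairs(c(0.5, 1, 2), c(0, 0, 0)))
  expect_equal(e0$beta, 0)
  expect_equal(e0$extra$intercept, 0)

  expect_error(mr_egger(make_pairs(c(1, 2), c(1, 2))), ">= 3")

  # forcing the intercept to zero gives the IVW fixed estimate:
  # check via the algebraic identity sum(w*x*y)/sum(w*x^2)
  set.seed(7)
  k <- 12
  p <- make_pairs(rnorm(k, 0.05, 0.03), rnorm(k, 0.02, 0.03),
                  se_y = runif(k, 0.005, 0.05))
  w <- 1 / p$se_y^2
  through_origin <- sum(w * p$beta_x * p$beta_y) / sum(w * p$beta_x^2)
  expect_equal(mr_ivw(p, "fixed")$beta, through_origin, tolerance = 1e-12)

  # orientation: flipping any pair's joint signs changes nothing
  p2 <- p; flip <- c(1, 4, 9)
  p2$beta_x[flip] <- -p2$beta_x[flip]; p2$beta_y[flip] <- -p2$beta_y[flip]
  expect_equal(mr_egger(p2)$beta, mr_egger(p)$beta)
  expect_equal(mr_egger(p2)$extra$intercept, mr_egger(p)$extra$intercept)

  # t-based intervals are at least as wide
  et <- mr_egger(p, ci = "t")
  expect_gte(et$ci_high - et$ci_low, mr_egger(p)$ci_high - mr_egger(p)$ci_low)
})

test_that("weighted median interpolates the cumulative-weight rule", {
  # equal weights on (1, 2, 9): simple median
  p <- make_pairs(c(0.1, 0.1, 0.1), c(0.1, 0.2, 0.9), se_y = 0.1)
  e <- mr_weighted_median(p, n_boot = 50, seed = 1)
  expect_equal(e$beta, 2.0)

  # weights (0.9, 0.05, 0.05) via se_y: ratio pulled toward 1; the
  # interpolation formula gives 1 + (0.5 - 0.45)/(0.925 - 0.45) = 1.105263...
  se_y <- 0.1 / sqrt(c(0.9, 0.05, 0.05))
  p <- make_pairs(c(0.1, 0.1, 0.1), c(0.1, 0.2, 0.9), se_y = se_y)
  e <- mr_weighted_median(p, n_boot = 50, seed = 1)
  expect_equal(e$beta, 1 + 0.05 / 0.475, tolerance = 1e-12)

  # equal weights, odd nsnp -> simple median (property)
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(c(3, 5, 7, 9), 1)
    ratios <- rnorm(k)
    p <- make_pairs(rep(0.1, k), ratios * 0.1, se_y = 0.1)
    e <- mr_weighted_median(p, n_boot = 10, seed = 1)
    expect_equal(e$beta, median(ratios), tolerance = 1e-12)
  }

  # same seed -> identical SE; different seed -> (almost surely) different
  p <- make_pairs(rnorm(5, 0.1, 0.02), rnorm(5, 0.02, 0.02), se_y = 0.02)
  e1 <- mr_weighted_median(p, n_boot = 200, seed = 42)
  e2 <- mr_weighted_median(p, n_boot = 200, seed = 42)
  expect_identical(e1$se, e2$se)
  expect_error(mr_weighted_median(p, n_boot = 10), "seed")
})

test_that("odds-ratio reporting exponentiates the log scale", {
  e <- mr_ivw(make_pairs(0.1, 0), "fixed")
  expect_equal(to_odds_ratio(e)$or_point, 1.0)

  # published internal-consistency checks: CI midpoints on the log scale
  mk <- function(lo, hi) {
    est <- structure(list(method = "ivw_random", beta = mean(c(lo, hi)),
                          se = (hi - lo) / (2 * qnorm(0.975)),
                          ci_low = lo, ci_high = hi, pvalue = NA, nsnp = 23,
                          extra = list()), class = "mr_estimate")
    to_odds_ratio(est)
  }
  expect_equal(mk(0.098, 0.281)$or_point, 1.209, tolerance = 5e-4)
  expect_equal(mk(-0.0002, 0.002)$or_point, 1.001, tolerance = 5e-4)
})

test_that("estimators are invariant to input row order", {
  set.seed(3)
  k <- 15
  p <- make_pairs(rnorm(k, 0.05, 0.02), rnorm(k, 0.02, 0.02),
                  se_y = runif(k, 0.01, 0.05))
  perm <- sample(k)
  expect_equal(mr_ivw(p[perm, ], "random")$beta, mr_ivw(p, "random")$beta)
  expect_equal(mr_egger(p[perm, ])$beta, mr_egger(p)$beta)
  expect_equal(mr_weighted_median(p[perm, ], n_boot = 10, seed = 1)$beta,
               mr_weighted_median(p, n_boot = 10, seed = 1)$beta)
})

test_that("estimates serialize to a labeled two-scale table", {
  p <- make_pairs(rnorm(6, 0.08, 0.01), rnorm(6, 0.02, 0.01), se_y = 0.01)
  tbl <- mr_estimates_table(list(mr_ivw(p, "fixed"), mr_egger(p)))
  expect_equal(tbl$method, c("ivw_fixed", "egger_slope"))
  expect_equal(tbl$or_point, exp(tbl$beta))
  expect_true(is.na(tbl$egger_intercept[1]) && !is.na(tbl$egger_intercept[2]))
})
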