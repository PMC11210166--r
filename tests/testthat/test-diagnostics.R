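test_that("Cochran's Q matches hand arithmetic", {
  # identical ratios -> Q = 0, p = 1
  p <- make_pairs(c(0.1, 0.2, 0.4), c(0.2, 0.4, 0.8), se_y = 0.01)
  q <- cochran_q(p)
  expect_equal(q$q, 0, tolerance = 1e-20)
  expect_equal(q$pvalue, 1)

  # ratios 1 and 3, unit SEs: Q = 2 on 1 df, p = P(chi2_1 > 2) = 0.1573
  q2 <- cochran_q(make_pairs(c(1, 1), c(1, 3), se_y = 1))
  expect_equal(q2$q, 2.0)
  expect_equal(q2$df, 1L)
  expect_equal(q2$pvalue, 0.157, tolerance = 1e-2)

  expect_error(cochran_q(make_pairs(1, 1)), ">= 2")

  # multiplicative-model identity: Q > k-1 => Q = (k-1) * (se_r/se_f)^2
  set.seed(8)
  for (i in 1:10) {
    k <- sample(3:20, 1)
    p <- make_pairs(rnorm(k, 0.05, 0.02), rnorm(k, 0.02, 0.03),
                    se_y = runif(k, 0.005, 0.03))
    q <- cochran_q(p)
    if (q$q > k - 1) {
      rat <- mr_ivw(p, "random")$se / mr_ivw(p, "fixed")$se
      expect_equal(q$q, (k - 1) * rat^2, tolerance = 1e-10)
    }
  }
})

test_that("Egger intercept test mirrors the regression intercept", {
  # exact proportionality -> intercept 0, p ~ 1
  p <- make_pairs(c(1, 2, 3, 4), 0.5 * c(1, 2, 3, 4), se_y = 0.1)
  it <- egger_intercept_test(p)
  expect_equal(it$intercept, 0, tolerance = 1e-12)
  expect_equal(it$pvalue, 1, tolerance = 1e-6)

  it2 <- egger_intercept_test(make_pairs(c(1, 2, 3), c(1.1, 2.1, 3.1), se_y = 1))
  expect_equal(it2$intercept, 0.1, tolerance = 1e-12)

  # seeded directional-pleiotropy scenario: detected in >= 80% of replicates
  hits <- vapply(1:200, function(r) {
    sim <- simulate_two_sample(sim_params(seed = 5000 + r,
                                          pleiotropy_mode = "directional"))
    hs <- harmonize(sim$exposure, sim$outcome)
    egger_intercept_test(hs)$pvalue < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("MR-PRESSO is deterministic and validates its inputs", {
  sim <- simulate_two_sample(sim_params(seed = 31))
  hs <- harmonize(sim$exposure, sim$outcome)
  r1 <- mr_presso(hs, n_sim = 200, seed = 5)
  r2 <- mr_presso(hs, n_sim = 200, seed = 5)
  expect_identical(r1, r2)
  expect_gte(r1$global_pvalue, 1 / 201)
  expect_true(all(r1$outliers %in% hs$pairs$snp))
  expect_null(r1$beta_corrected)  # no outliers in a clean set

  expect_error(mr_presso(make_pairs(1:3 / 10, 1:3 / 10), n_sim = 200, seed = 1),
               ">= 4")
  expect_warning(mr_presso(hs, n_sim = 50, seed = 1), "n_sim")
  expect_error(mr_presso(hs, n_sim = 200), "seed")
})

test_that("MR-PRESSO flags a constructed gross outlier and corrects", {
  sim <- simulate_two_sample(sim_params(seed = 31))
  p <- harmonize(sim$exposure, sim$outcome)$pairs
  i <- 3
  p$beta_y[i] <- p$beta_y[i] + 10 * p$se_y[i]
  res <- mr_presso(p, n_sim = 1000, seed = 8)
  expect_true(p$snp[i] %in% res$outliers)
  expect_lt(res$global_pvalue, 0.05)
  expect_false(is.null(res$beta_corrected))
  expect_false(is.null(res$distortion_pvalue))
  # corrected estimate equals IVW on the cleaned set
  clean <- mr_ivw(p[!p$snp %in% res$outliers, ], "fixed")$beta
  expect_equal(res$beta_corrected, clean)
  # removing the flagged SNP never increases the remaining RSS
  w <- 1 / p$se_y^2
  rss_all <- mrpipe:::presso_rss(p$beta_x, p$beta_y, w)$rss
  keep <- !p$snp %in% res$outliers
  rss_rest <- mrpipe:::presso_rss(p$beta_x[keep], p$beta_y[keep], w[keep])$rss
  expect_lte(rss_rest, rss_all)
})

test_that("leave-one-out excludes exactly one variant per row", {
  # nsnp = 2: each row is the other SNP's Wald ratio
  p <- make_pairs(c(0.1, 0.2), c(0.15, 0.1), se_y = 0.02)
  loo <- leave_one_out(p)
  expect_equal(nrow(loo), 3)
  wr <- wald_ratio(p)
  expect_equal(loo$beta[1], wr$ratio[2])
  expect_equal(loo$beta[2], wr$ratio[1])
  # full-set row equals the plain IVW fit
  expect_equal(loo$beta[3], mr_ivw(p, "fixed")$beta)

  expect_error(leave_one_out(make_pairs(0.1, 0.1)), ">= 2")

  # poisoning: row i never uses SNP i's statistics
  set.seed(12)
  k <- 8
  p <- make_pairs(rnorm(k, 0.08, 0.02), rnorm(k, 0.03, 0.02), se_y = 0.02)
  base <- leave_one_out(p)
  for (i in c(2, 5)) {
    poisoned <- p
    poisoned$beta_x[i] <- NaN; poisoned$beta_y[i] <- NaN
    loo_p <- suppressWarnings(leave_one_out(poisoned))
    expect_equal(loo_p$beta[i], base$beta[i])
    expect_equal(loo_p$se[i], base$se[i])
  }

  # synthetic clean set: every leave-one-out estimate inside the full CI
  sim <- simulate_two_sample(sim_params(seed = 17))
  hs <- harmonize(sim$exposure, sim$outcome)
  loo <- leave_one_out(hs)
  full <- loo[nrow(loo), ]
  rows <- loo[-nrow(loo), ]
  expect_true(all(rows$beta >= full$ci_low & rows$beta <= full$ci_high))
  expect_equal(attr(loo, "sign_consistency"), 1)
})

test_that("plot-data tables carry the figures' numbers", {
  p1 <- make_pairs(0.1, 0.2, se_y = 0.02)
  fd1 <- funnel_and_forest_data(p1)
  expect_equal(sum(fd1$forest$type == "snp"), 1)
  expect_gte(sum(fd1$forest$type == "summary"), 1)

  set.seed(5)
  k <- 9
  p <- make_pairs(rnorm(k, 0.1, 0.02), rnorm(k, 0.02, 0.02), se_y = 0.02)
  fd <- funnel_and_forest_data(p, seed = 3)
  expect_equal(nrow(fd$funnel), k)
  expect_equal(fd$funnel$precision, 1 / wald_ratio(p)$se_ratio)
  # scatter slope column equals the estimator betas exactly
  fits <- attr(fd$scatter, "fits")
  expect_equal(fits$slope[fits$method == "ivw_fixed"],
               mr_ivw(p, "fixed")$beta)
  expect_equal(fits$slope[fits$method == "egger_slope"], mr_egger(p)$beta)
  expect_equal(fits$intercept[fits$method == "egger_slope"],
               mr_egger(p)$extra$intercept)

  # symmetric construction: funnel ratios symmetric about the IVW center
  ps <- make_pairs(rep(0.1, 4), c(0.18, 0.22, 0.16, 0.24), se_y = 0.02)
  fds <- funnel_and_forest_data(ps)
  center <- mr_ivw(ps, "fixed")$beta
  expect_equal(sort(fds$funnel$ratio - center), sort(center - fds$funnel$ratio))
})
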