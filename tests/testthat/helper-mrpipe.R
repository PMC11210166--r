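# Shared fixtures and independent oracles for the test suite.

# Quick record builder with sensible filler defaults.
make_records <- function(snp, ea = "A", nea = "G", eaf = 0.3, beta = 0.1,
                         se = 0.02, pvalue = NULL, chrom = NULL, pos = NULL) {
  k <- length(snp)
  recycle <- function(x) rep_len(x, k)
  beta <- recycle(beta); se <- recycle(se)
  if (is.null(pvalue)) {
    pvalue <- pmax(2 * pnorm(abs(beta / se), lower.tail = FALSE),
                   .Machine$double.xmin)
  }
  summary_stats(snp, recycle(ea), recycle(nea), recycle(eaf), beta, se,
                recycle(pvalue), chrom = chrom, pos = pos)
}

# Direct harmonized-pair table (bypasses allele bookkeeping) for estimators.
make_pairs <- function(beta_x, beta_y, se_x = 0.01, se_y = 0.01,
                       snp = NULL) {
  k <- length(beta_x)
  data.frame(snp = snp %||% sprintf("rs%03d", seq_len(k)),
             effect_allele = rep_len("A", k), other_allele = rep_len("G", k),
             beta_x = beta_x, se_x = rep_len(se_x, k), eaf_x = rep_len(0.3, k),
             beta_y = beta_y, se_y = rep_len(se_y, k), eaf_y = rep_len(0.3, k),
             pvalue_x = rep_len(1e-8, k), action = rep_len("unchanged", k),
             stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force oracle: the greedy clumping definition applied literally and
# independently of the package implementation. `ld_mat` is a symmetric
# matrix with rsID dimnames; no positional window.
clump_oracle <- function(records, ld_mat, r2_threshold) {
  df <- as.data.frame(records)
  df <- df[order(df$pvalue, df$snp), ]
  kept <- character(0)
  for (i in seq_len(nrow(df))) {
    id <- df$snp[i]
    conflict <- FALSE
    for (j in kept) {
      if (ld_mat[id, j] >= r2_threshold) conflict <- TRUE
    }
    if (!conflict) kept <- c(kept, id)
  }
  kept
}

# Random symmetric LD matrix over the given ids.
random_ld_matrix <- function(ids, p_high = 0.4) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) {
      m[i, j] <- m[j, i] <- if (runif(1) < p_high) runif(1, 0.001, 1)
        else runif(1, 0, 0.0009)
    }
  }
  diag(m) <- 1
  m
}

# Swap allele coding of chosen rows: EA<->NEA, beta -> -beta, eaf -> 1-eaf.
# A pure relabeling; no estimator should notice.
relabel_records <- function(records, idx) {
  df <- as.data.frame(records)
  ea <- df$effect_allele[idx]
  df$effect_allele[idx] <- df$other_allele[idx]
  df$other_allele[idx] <- ea
  df$beta[idx] <- -df$beta[idx]
  df$eaf[idx] <- 1 - df$eaf[idx]
  as_summary_stats(df)
}

# F column printed alongside the packaged instrument tables (recomputed by
# the package, stored only here for comparison).
printed_f_bph <- c(22.691, 31.483, 23.477, 35.868, 22.062, 22.709, 25.665,
                   30.630, 26.996, 79.461, 24.196, 22.914, 45.128, 21.741,
                   79.023, 45.140, 38.054, 26.037, 39.014, 21.639, 28.956,
                   51.983, 26.377)
printed_f_prostatitis <- c(23.853, 22.081, 22.440, 21.674, 30.004, 24.970,
                           21.058, 21.204, 24.861, 21.364)
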