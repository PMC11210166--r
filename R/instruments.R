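#' Instrument sets with filter provenance
#'
#' An `instrument_set` bundles the surviving `summary_stats` records with an
#' ordered provenance log: one row per applied filter with the number of
#' records entering, removed and leaving, so counts telescope from raw input
#' to the estimation set.
#'
#' @param records a `summary_stats` data frame.
#' @param provenance data frame with columns `step`, `n_in`, `removed`,
#'   `n_out`, `detail`.
#' @return An `instrument_set`.
#' @export
instrument_set <- function(records, provenance = NULL) {
  records <- as_summary_stats(as.data.frame(records))
  if (is.null(provenance)) {
    provenance <- data.frame(step = "input", n_in = nrow(records), removed = 0L,
                             n_out = nrow(records), detail = "",
                             stringsAsFactors = FALSE)
  }
  structure(list(records = records, k = nrow(records), provenance = provenance),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %d instrument(s)\n", x$k))
  print(x$provenance, row.names = FALSE)
  invisible(x)
}

as_records <- function(x) {
  if (inherits(x, "instrument_set")) x$records
  else as_summary_stats(as.data.frame(x))
}

as_provenance <- function(x) {
  if (inherits(x, "instrument_set")) x$provenance else NULL
}

add_step <- function(prov, records_in, step, removed, detail = "") {
  n_in <- nrow(records_in)
  row <- data.frame(step = step, n_in = n_in, removed = as.integer(removed),
                    n_out = n_in - as.integer(removed), detail = detail,
                    stringsAsFactors = FALSE)
  if (is.null(prov)) {
    prov <- data.frame(step = "input", n_in = n_in, removed = 0L, n_out = n_in,
                       detail = "", stringsAsFactors = FALSE)
  }
  rbind(prov, row)
}

#' Select instruments by association p-value
#'
#' Keeps exactly the records with `pvalue < p_threshold`. The default
#' threshold is the one used for both exposures in the source analysis
#' (5e-6); note this is laxer than the conventional genome-wide 5e-8 and is
#' treated as a plain parameter.
#'
#' @param x `summary_stats` or `instrument_set`.
#' @param p_threshold two-sided p-value cutoff in (0, 1).
#' @return An `instrument_set`.
#' @export
select_instruments <- function(x, p_threshold = 5e-6) {
  stopifnot(is.numeric(p_threshold), p_threshold > 0, p_threshold <= 1)
  records <- as_records(x)
  keep <- records$pvalue < p_threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  prov <- add_step(as_provenance(x), records, "select_pvalue", sum(!keep),
                   sprintf("p < %g", p_threshold))
  if (nrow(out) == 0) {
    stop_mr("no instruments survive p < %g (started with %d)", p_threshold,
            nrow(records), class = "mrpipe_no_instruments")
  }
  instrument_set(out, prov)
}

#' Build a pairwise LD r-squared lookup
#'
#' Accepts a symmetric matrix with rsID dimnames, a 3-column long table
#' (`snp_a`, `snp_b`, `r2`), or a function of two rsIDs; returns a vectorized
#' lookup function returning `NA` for unknown pairs.
#'
#' @param ld matrix, data frame or function.
#' @return `function(snp_a, snp_b) -> r2`.
#' @export
ld_lookup <- function(ld) {
  if (is.function(ld)) return(ld)
  if (is.matrix(ld)) {
    stopifnot(!is.null(rownames(ld)), !is.null(colnames(ld)))
    return(function(a, b) {
      ifelse(a %in% rownames(ld) & b %in% colnames(ld),
             mapply(function(x, y) ld[x, y], a, b), NA_real_)
    })
  }
  if (is.data.frame(ld)) {
    stopifnot(ncol(ld) >= 3)
    key <- c(paste(ld[[1]], ld[[2]], sep = "\r"),
             paste(ld[[2]], ld[[1]], sep = "\r"))
    val <- rep(as.numeric(ld[[3]]), 2)
    return(function(a, b) {
      out <- val[match(paste(a, b, sep = "\r"), key)]
      out[a == b] <- 1
      out
    })
  }
  stop_mr("ld must be a function, matrix or 3-column data frame")
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken lexicographically by
#' rsID, making the result invariant to input row order), then accepts each
#' variant unless its r-squared with an already-accepted variant inside the
#' clumping window is at or above `r2_threshold`. Output rows are in
#' acceptance order.
#'
#' Two variants are "in window" when both carry coordinates, share a
#' chromosome and are within `window_bp`; variants without coordinates are
#' always in window (pure r-squared rule).
#'
#' @param x `summary_stats` or `instrument_set`.
#' @param ld anything accepted by [ld_lookup()].
#' @param r2_threshold pairwise r-squared cutoff (default 0.001).
#' @param window_bp clumping window in base pairs (default 10 Mb); `Inf`
#'   disables the positional restriction.
#' @param missing_ld `"permissive"` treats a missing r-squared for an
#'   in-window pair as 0 with a warning; `"strict"` errors.
#' @return An `instrument_set`.
#' @export
clump <- function(x, ld, r2_threshold = 0.001, window_bp = 1e7,
                  missing_ld = c("permissive", "strict")) {
  missing_ld <- match.arg(missing_ld)
  lookup <- ld_lookup(ld)
  records <- as_records(x)
  ord <- order(records$pvalue, records$snp)
  sorted <- records[ord, , drop = FALSE]

  has_coord <- if (all(c("chrom", "pos") %in% names(sorted)))
    !is.na(sorted$chrom) & !is.na(sorted$pos) else rep(FALSE, nrow(sorted))

  accepted <- integer(0)
  n_missing <- 0L
  for (i in seq_len(nrow(sorted))) {
    in_window <- if (length(accepted) == 0) logical(0)
    else if (is.finite(window_bp)) {
      both <- has_coord[accepted] & has_coord[i]
      (!both) | (sorted$chrom[accepted] == sorted$chrom[i] &
                   abs(sorted$pos[accepted] - sorted$pos[i]) <= window_bp)
    } else rep(TRUE, length(accepted))
    rivals <- accepted[in_window]
    ok <- TRUE
    if (length(rivals) > 0) {
      r2 <- lookup(rep(sorted$snp[i], length(rivals)), sorted$snp[rivals])
      if (anyNA(r2)) {
        if (missing_ld == "strict") {
          stop_mr("missing LD r2 for pair(s) involving %s", sorted$snp[i])
        }
        n_missing <- n_missing + sum(is.na(r2))
        r2[is.na(r2)] <- 0
      }
      ok <- all(r2 < r2_threshold)
    }
    if (ok) accepted <- c(accepted, i)
  }
  if (n_missing > 0) {
    warning(sprintf("%d missing LD value(s) treated as r2 = 0", n_missing))
  }
  out <- sorted[accepted, , drop = FALSE]
  rownames(out) <- NULL
  prov <- add_step(as_provenance(x), records, "clump",
                   nrow(records) - nrow(out),
                   sprintf("r2 < %g, window %s bp", r2_threshold,
                           format(window_bp)))
  instrument_set(out, prov)
}

#' Screen instruments against a local trait-annotation table
#'
#' Offline stand-in for a genotype-phenotype database query: removes any
#' instrument annotated with a trait matching a blocklisted pattern
#' (case-insensitive substring match). An empty annotation table or blocklist
#' leaves the set unchanged.
#'
#' @param x `summary_stats` or `instrument_set`.
#' @param annotations data frame whose first two columns are rsID and
#'   associated trait.
#' @param blocklist character vector of trait substrings to exclude.
#' @return An `instrument_set`; the provenance detail lists removed
#'   (rsID, trait) pairs.
#' @export
screen_confounders <- function(x, annotations, blocklist) {
  records <- as_records(x)
  removed_pairs <- character(0)
  drop_ids <- character(0)
  if (!is.null(annotations) && nrow(annotations) > 0 && length(blocklist) > 0) {
    ann_snp <- as.character(annotations[[1]])
    ann_trait <- as.character(annotations[[2]])
    hit <- rep(FALSE, length(ann_trait))
    for (pat in blocklist) {
      hit <- hit | grepl(tolower(pat), tolower(ann_trait), fixed = TRUE)
    }
    hit <- hit & ann_snp %in% records$snp
    drop_ids <- unique(ann_snp[hit])
    removed_pairs <- sprintf("%s:%s", ann_snp[hit], ann_trait[hit])
  }
  keep <- !records$snp %in% drop_ids
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  prov <- add_step(as_provenance(x), records, "screen_confounders", sum(!keep),
                   paste(removed_pairs, collapse = "; "))
  instrument_set(out, prov)
}

#' Instrument-strength metrics (R-squared and F)
#'
#' Computes, per variant, the proportion of exposure variance explained
#' \deqn{R^2 = 2\,(1 - MAF)\,MAF\,\left(\beta / (SE\sqrt{N})\right)^2}
#' with MAF = min(EAF, 1 - EAF), and three F-statistic conventions:
#' `f_paper` uses \eqn{F = \frac{N-k-1}{k}\frac{R^2}{1-R^2}} with the
#' supplied instrument count `k`; `f_persnp` is the same with k = 1; and
#' `f_from_p` is \eqn{z^2} for the standard-normal two-sided quantile of the
#' p-value, computed through the upper-tail path so it survives p ~ 1e-19.
#' `f_from_p` reproduces published per-variant F columns (which the
#' R-squared route, evaluated on rounded table entries, does not) and is the
#' default convention for filtering and reporting.
#'
#' @param x `summary_stats` or `instrument_set`.
#' @param n study sample size (scalar; a per-row `n` column overrides it).
#' @param k instrument count for `f_paper`; defaults to the number of rows.
#' @return Data frame: `snp`, `r2_paper`, `f_paper`, `f_persnp`, `f_from_p`.
#' @export
instrument_strength <- function(x, n, k = NULL) {
  records <- as_records(x)
  if (is.null(k)) k <- nrow(records)
  n_row <- if ("n" %in% names(records) && any(!is.na(records$n)))
    ifelse(is.na(records$n), n, records$n) else rep(n, nrow(records))
  if (any(n_row <= k + 1)) {
    stop_mr("instrument_strength: need n > k + 1 (n = %s, k = %d)",
            paste(unique(n_row[n_row <= k + 1]), collapse = ","), k)
  }
  maf <- pmin(records$eaf, 1 - records$eaf)
  r2 <- 2 * (1 - maf) * maf * (records$beta / (records$se * sqrt(n_row)))^2
  f_of <- function(kk) ((n_row - kk - 1) / kk) * r2 / (1 - r2)
  z <- stats::qnorm(records$pvalue / 2, lower.tail = FALSE)
  data.frame(snp = records$snp, r2_paper = r2, f_paper = f_of(k),
             f_persnp = f_of(1), f_from_p = z^2, stringsAsFactors = FALSE)
}

#' Summarize instrument strength across a set
#'
#' Reports the minimum and maximum per-variant F (using the `f_from_p`
#' convention) and how many instruments clear the conventional
#' weak-instrument bar F > 10.
#'
#' @inheritParams instrument_strength
#' @return List with `f_min`, `f_max`, `n_strong`, `k`.
#' @export
strength_summary <- function(x, n) {
  records <- as_records(x)
  if (nrow(records) == 0) stop_mr("strength_summary: empty instrument set")
  st <- instrument_strength(records, n = n)
  list(f_min = min(st$f_from_p), f_max = max(st$f_from_p),
       n_strong = sum(st$f_from_p > 10), k = nrow(records))
}
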