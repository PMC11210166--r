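#' Harmonize exposure and outcome summary statistics
#'
#' Aligns both studies to a shared effect allele per variant so the Wald
#' ratio \eqn{\beta_Y/\beta_X} is meaningful. Only variants present in both
#' studies are considered; the rest are reported in `dropped`. For each
#' shared variant:
#' \itemize{
#'   \item identical allele pair: kept unchanged;
#'   \item swapped alleles (EA and NEA exchanged): outcome beta sign is
#'     flipped and `eaf_y := 1 - eaf_y`;
#'   \item complementary-strand match: outcome alleles are relabelled to the
#'     exposure strand, then the swap rule applies;
#'   \item palindromic variants (A/T or C/G), whose strand cannot be read
#'     from the alleles: orientation is inferred from allele frequency when
#'     both frequencies sit outside the ambiguity window
#'     \eqn{[0.5 - w, 0.5 + w]}, otherwise the variant is dropped;
#'   \item irreconcilable allele sets are dropped as incompatible.
#' }
#'
#' @param exposure,outcome `summary_stats` or `instrument_set`; rsIDs must be
#'   unique within each study.
#' @param palindromic_eaf_window half-width \eqn{w} of the frequency
#'   ambiguity window (default 0.08, i.e. drop when either EAF falls in
#'   \[0.42, 0.58\]). A palindromic variant with a missing EAF on either side
#'   is dropped (conservative).
#' @param exposure_meta,outcome_meta optional `study_meta` rows carried along
#'   for downstream reporting.
#' @return A `harmonized_set`: `pairs` (retained variants with `beta_x`,
#'   `se_x`, `eaf_x`, `beta_y`, `se_y`, `eaf_y`, shared alleles and the
#'   action taken), `dropped` (excluded variants with reasons), and the study
#'   metadata. Every input exposure variant appears in exactly one of the
#'   two tables.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08,
                      exposure_meta = NULL, outcome_meta = NULL) {
  ex <- as_records(exposure)
  out <- as_records(outcome)
  for (side in list(c("exposure", "ex"), c("outcome", "out"))) {
    ids <- get(side[2])$snp
    if (anyDuplicated(ids)) {
      stop_mr("duplicate snp id(s) in %s study: %s", side[1],
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
  }
  w <- palindromic_eaf_window

  pairs <- list()
  dropped <- list()
  drop <- function(id, action, reason) {
    dropped[[length(dropped) + 1]] <<- data.frame(
      snp = id, action = action, reason = reason, stringsAsFactors = FALSE)
  }

  oy <- out[match(ex$snp, out$snp), , drop = FALSE]
  for (i in seq_len(nrow(ex))) {
    id <- ex$snp[i]
    if (is.na(oy$snp[i])) {
      drop(id, "dropped_incompatible", "absent from outcome study")
      next
    }
    ea_x <- ex$effect_allele[i]; nea_x <- ex$other_allele[i]
    ea_y <- oy$effect_allele[i]; nea_y <- oy$other_allele[i]
    beta_y <- oy$beta[i]; eaf_y <- oy$eaf[i]
    action <- NULL

    if (is_palindromic(ea_x, nea_x)) {
      if (!setequal(c(ea_y, nea_y), c(ea_x, nea_x))) {
        drop(id, "dropped_incompatible", "allele sets differ")
        next
      }
      eaf_x <- ex$eaf[i]
      ambiguous <- is.na(eaf_x) || is.na(eaf_y) ||
        abs(eaf_x - 0.5) <= w || abs(eaf_y - 0.5) <= w
      if (ambiguous) {
        drop(id, "dropped_palindromic",
             sprintf("palindromic with EAF in [%.2f, %.2f] or missing",
                     0.5 - w, 0.5 + w))
        next
      }
      # Alleles cannot resolve strand; align labels, then let frequency decide.
      flip <- ea_y != ea_x
      if (flip) { beta_y <- -beta_y; eaf_y <- 1 - eaf_y }
      if ((eaf_x - 0.5) * (eaf_y - 0.5) < 0) {
        beta_y <- -beta_y; eaf_y <- 1 - eaf_y; flip <- !flip
      }
      action <- if (flip) "outcome_beta_flipped" else "unchanged"
    } else {
      flipped_strand <- FALSE
      if (!setequal(c(ea_y, nea_y), c(ea_x, nea_x))) {
        ea_c <- complement_allele(ea_y); nea_c <- complement_allele(nea_y)
        if (setequal(c(ea_c, nea_c), c(ea_x, nea_x))) {
          ea_y <- ea_c; nea_y <- nea_c; flipped_strand <- TRUE
        } else {
          drop(id, "dropped_incompatible", "allele sets differ")
          next
        }
      }
      flipped_beta <- ea_y != ea_x
      if (flipped_beta) { beta_y <- -beta_y; eaf_y <- 1 - eaf_y }
      action <- if (flipped_strand && flipped_beta) "strand_flipped_and_beta_flipped"
        else if (flipped_strand) "strand_flipped"
        else if (flipped_beta) "outcome_beta_flipped"
        else "unchanged"
    }

    pairs[[length(pairs) + 1]] <- data.frame(
      snp = id, effect_allele = ea_x, other_allele = nea_x,
      beta_x = ex$beta[i], se_x = ex$se[i], eaf_x = ex$eaf[i],
      beta_y = beta_y, se_y = oy$se[i], eaf_y = eaf_y,
      pvalue_x = ex$pvalue[i], action = action, stringsAsFactors = FALSE)
  }

  pairs <- if (length(pairs)) do.call(rbind, pairs)
    else data.frame(snp = character(0), effect_allele = character(0),
                    other_allele = character(0), beta_x = numeric(0),
                    se_x = numeric(0), eaf_x = numeric(0), beta_y = numeric(0),
                    se_y = numeric(0), eaf_y = numeric(0),
                    pvalue_x = numeric(0), action = character(0),
                    stringsAsFactors = FALSE)
  dropped <- if (length(dropped)) do.call(rbind, dropped)
    else data.frame(snp = character(0), action = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  structure(list(pairs = pairs, dropped = dropped,
                 exposure_meta = exposure_meta, outcome_meta = outcome_meta,
                 palindromic_eaf_window = w),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %d retained pair(s), %d dropped\n",
              nrow(x$pairs), nrow(x$dropped)))
  if (nrow(x$pairs)) print(table(x$pairs$action))
  invisible(x)
}

#' Harmonization report
#'
#' One row per input exposure variant (retained or dropped) with the action
#' taken and, for exclusions, the reason.
#'
#' @param hs a `harmonized_set`.
#' @param path optional file; when given, the report is written as TSV.
#' @return The report data frame (invisibly when `path` is given).
#' @export
harmonization_report <- function(hs, path = NULL) {
  kept <- if (nrow(hs$pairs))
    data.frame(snp = hs$pairs$snp, action = hs$pairs$action, reason = "",
               stringsAsFactors = FALSE)
    else data.frame(snp = character(0), action = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  rep <- rbind(kept, hs$dropped)
  if (!is.null(path)) {
    utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}

#' Re-express one side of a harmonized set as summary statistics
#'
#' Used to verify the involution property (harmonizing an already-harmonized
#' set changes nothing) and to feed harmonized pairs back through the
#' pipeline. P-values are recomputed from the Wald z-score.
#'
#' @param hs a `harmonized_set`.
#' @param side `"exposure"` or `"outcome"`.
#' @return A `summary_stats` data frame.
#' @export
harmonized_side <- function(hs, side = c("exposure", "outcome")) {
  side <- match.arg(side)
  p <- hs$pairs
  b <- if (side == "exposure") p$beta_x else p$beta_y
  s <- if (side == "exposure") p$se_x else p$se_y
  eaf <- if (side == "exposure") p$eaf_x else p$eaf_y
  pv <- if (side == "exposure") p$pvalue_x
    else 2 * stats::pnorm(abs(b / s), lower.tail = FALSE)
  summary_stats(p$snp, p$effect_allele, p$other_allele, eaf, b, s,
                pmin(pmax(pv, .Machine$double.xmin), 1))
}
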