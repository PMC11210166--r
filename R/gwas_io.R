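#' GWAS summary-statistic tables
#'
#' A `summary_stats` object is a data frame with one row per variant and the
#' canonical columns `snp`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `pvalue`, plus optional `chrom`/`pos` (1-based) and a per-row `n`
#' override. Alleles are single uppercase bases; `se > 0`; `0 < pvalue <= 1`;
#' `0 <= eaf <= 1`.
#'
#' @param snp character rsIDs (nonempty).
#' @param effect_allele,other_allele single-base alleles (A/C/G/T), distinct
#'   within a row.
#' @param eaf effect-allele frequency in \[0, 1\].
#' @param beta additive per-allele effect (log-odds or linear scale).
#' @param se standard error of `beta`, strictly positive.
#' @param pvalue two-sided p-value in (0, 1\]; exact zeros are clamped to the
#'   smallest positive double with a warning.
#' @param chrom,pos optional genomic coordinates (1-based).
#' @param n optional per-row sample size override.
#' @return A `summary_stats` data frame.
#' @export
summary_stats <- function(snp, effect_allele, other_allele, eaf, beta, se,
                          pvalue, chrom = NULL, pos = NULL, n = NULL) {
  df <- data.frame(
    snp = as.character(snp),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    eaf = as.numeric(eaf),
    beta = as.numeric(beta),
    se = as.numeric(se),
    pvalue = as.numeric(pvalue),
    stringsAsFactors = FALSE
  )
  if (!is.null(chrom)) df$chrom <- as.character(chrom)
  if (!is.null(pos)) df$pos <- as.numeric(pos)
  if (!is.null(n)) df$n <- as.numeric(n)
  as_summary_stats(df)
}

#' Coerce a data frame to `summary_stats`, enforcing invariants
#'
#' Zero p-values are clamped to the smallest positive double (warning). Rows
#' violating any invariant are rejected: they are removed from the result and
#' reported in a single warning naming each offending row and the rule it
#' broke. Row order of surviving rows is preserved.
#'
#' @param df data frame with the canonical columns (see [summary_stats()]).
#' @return A validated `summary_stats` data frame.
#' @export
as_summary_stats <- function(df) {
  required <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se",
                "pvalue")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_mr("missing mandatory column(s): %s",
            paste(missing_cols, collapse = ", "),
            class = "mrpipe_config_error")
  }
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)

  zero_p <- which(!is.na(df$pvalue) & df$pvalue == 0)
  if (length(zero_p) > 0) {
    warning(sprintf("%d zero p-value(s) clamped to %.3e (rows %s)",
                    length(zero_p), .Machine$double.xmin,
                    paste(zero_p, collapse = ", ")))
    df$pvalue[zero_p] <- .Machine$double.xmin
  }

  bad <- summary_stats_violations(df)
  if (any(bad != "")) {
    idx <- which(bad != "")
    warning(sprintf(
      "rejected %d row(s) violating summary-stat invariants:\n%s",
      length(idx),
      paste(sprintf("  row %d (%s): %s", idx,
                    ifelse(is.na(df$snp[idx]), "<NA>", df$snp[idx]),
                    bad[idx]),
            collapse = "\n")))
    df <- df[bad == "", , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("summary_stats", "data.frame")
  df
}

# One message per row; "" means the row is valid.
summary_stats_violations <- function(df) {
  msg <- character(nrow(df))
  add <- function(cond, text) {
    cond[is.na(cond)] <- TRUE
    msg[cond] <<- ifelse(msg[cond] == "", text, paste(msg[cond], text, sep = "; "))
  }
  add(is.na(df$snp) | !nzchar(df$snp), "empty snp id")
  add(!df$effect_allele %in% c("A", "C", "G", "T"), "effect_allele not in A/C/G/T")
  add(!df$other_allele %in% c("A", "C", "G", "T"), "other_allele not in A/C/G/T")
  add(df$effect_allele == df$other_allele, "effect_allele == other_allele")
  add(!is.finite(df$eaf) | df$eaf < 0 | df$eaf > 1, "eaf outside [0,1]")
  add(!is.finite(df$beta), "non-numeric beta")
  add(!is.finite(df$se) | df$se <= 0, "se not > 0")
  add(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1, "pvalue outside (0,1]")
  msg
}

# Canonical on-disk headers -> internal field names.
default_dialect <- c(snp = "SNP", effect_allele = "EA", other_allele = "NEA",
                     eaf = "EAF", beta = "BETA", se = "SE", pvalue = "P",
                     chrom = "CHR", pos = "POS", n = "N")

#' Read GWAS summary statistics from delimited text
#'
#' The canonical format is tab-separated with a header row and columns
#' `SNP/EA/NEA/EAF/BETA/SE/P` (optionally `CHR`, `POS`, `N`). Other layouts
#' are accommodated with a `dialect` map. Rows whose numeric fields do not
#' parse, or which violate the record invariants, are rejected with
#' row-numbered diagnostics (a warning), never silently dropped. Row order is
#' preserved.
#'
#' @param source path to a delimited text file (or a connection).
#' @param dialect named character vector mapping canonical field names
#'   (`snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`,
#'   `chrom`, `pos`, `n`) to the column names used in the file. Defaults to
#'   the canonical headers.
#' @param sep field separator; tab by default.
#' @return A `summary_stats` data frame.
#' @export
read_summary_stats <- function(source, dialect = NULL, sep = "\t") {
  map <- default_dialect
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  raw <- utils::read.table(source, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  required <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se",
                "pvalue")
  missing_cols <- required[!map[required] %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop_mr("missing mandatory column(s): %s (looked for: %s)",
            paste(missing_cols, collapse = ", "),
            paste(map[missing_cols], collapse = ", "),
            class = "mrpipe_config_error")
  }
  present <- names(map)[map %in% names(raw)]
  df <- stats::setNames(raw[, map[present], drop = FALSE], present)

  numeric_fields <- intersect(c("eaf", "beta", "se", "pvalue", "pos", "n"),
                              names(df))
  parse_fail <- rep(FALSE, nrow(df))
  for (f in numeric_fields) {
    vals <- suppressWarnings(as.numeric(df[[f]]))
    parse_fail <- parse_fail | (is.na(vals) & !is.na(df[[f]]) & nzchar(df[[f]]))
    df[[f]] <- vals
  }
  if (any(parse_fail)) {
    warning(sprintf("rejected %d row(s) with unparseable numeric fields: rows %s",
                    sum(parse_fail),
                    paste(which(parse_fail), collapse = ", ")))
    df <- df[!parse_fail, , drop = FALSE]
    rownames(df) <- NULL
  }
  as_summary_stats(df)
}

#' Write GWAS summary statistics as canonical TSV
#'
#' Numeric fields are written with full double precision so that
#' `read_summary_stats(write_summary_stats(x))` reproduces `x`
#' field-for-field.
#'
#' @param x a `summary_stats` data frame.
#' @param sink output file path (or connection).
#' @return `sink`, invisibly.
#' @export
write_summary_stats <- function(x, sink) {
  x <- as_summary_stats(as.data.frame(x))
  present <- intersect(names(default_dialect), names(x))
  out <- x[, present, drop = FALSE]
  for (f in intersect(c("eaf", "beta", "se", "pvalue", "pos", "n"), present)) {
    out[[f]] <- format(out[[f]], digits = 17, trim = TRUE, scientific = NA)
  }
  names(out) <- default_dialect[present]
  utils::write.table(out, sink, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sink)
}

#' Study-level metadata
#'
#' One row per GWAS cohort: trait label, total sample size `n`, ancestry,
#' consortium, year and source. Sample size lives here (one N per cohort)
#' rather than per-variant; a per-row `n` column in the summary statistics
#' overrides it when present.
#'
#' @param trait_label free-text phenotype name.
#' @param n total participants (> 0).
#' @param population ancestry label.
#' @param year study year.
#' @param consortium,source free text.
#' @return A `study_meta` data frame.
#' @export
study_meta <- function(trait_label, n, population = NA_character_,
                       year = NA_integer_, consortium = NA_character_,
                       source = NA_character_) {
  n <- as.numeric(n)
  if (any(!is.finite(n) | n <= 0)) stop_mr("study_meta: n must be > 0")
  df <- data.frame(trait_label = as.character(trait_label), n = n,
                   population = as.character(population),
                   consortium = as.character(consortium),
                   year = as.integer(year), source = as.character(source),
                   stringsAsFactors = FALSE)
  class(df) <- c("study_meta", "data.frame")
  df
}

#' Load a packaged fixture table
#'
#' Three fixtures ship with the package: the 23 benign-prostatic-hyperplasia
#' (BPH) instruments, the 10 prostatitis instruments (both as published
#' association tables: SNP, alleles, EAF, beta, SE, p; the F column is always
#' recomputed, never stored), and the cohort metadata table with sample sizes
#' N = 463 010 (BPH, prostate cancer) and N = 74 658 (prostatitis).
#'
#' @param name one of `"bph_instruments"`, `"prostatitis_instruments"`,
#'   `"study_meta"`.
#' @return A `summary_stats` or `study_meta` data frame.
#' @export
load_fixture <- function(name) {
  files <- c(bph_instruments = "bph_instruments.tsv",
             prostatitis_instruments = "prostatitis_instruments.tsv",
             study_meta = "study_meta.tsv")
  if (length(name) != 1 || !name %in% names(files)) {
    stop_mr("unknown fixture '%s'; expected one of: %s",
            paste(name, collapse = ","), paste(names(files), collapse = ", "),
            class = "mrpipe_lookup_error")
  }
  path <- system.file("extdata", files[[name]], package = "mrpipe",
                      mustWork = TRUE)
  if (name == "study_meta") {
    raw <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
    return(study_meta(raw$trait_label, raw$n, raw$population, raw$year,
                      raw$consortium, raw$source))
  }
  read_summary_stats(path)
}
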