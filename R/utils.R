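#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# DNA complement for allele strings (vectorized, single-base alleles only).
complement_allele <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

is_palindromic <- function(ea, nea) {
  toupper(ea) == complement_allele(nea)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mr <- function(fmt, ..., class = "mrpipe_error") {
  stop(structure(
    class = unique(c(class, "mrpipe_error", "error", "condition")),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
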