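# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_if_not_scalar <- function(x, name, lower = -Inf, upper = Inf,
                               open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("`%s` = %s is outside the allowed range %s%s, %s%s", name,
                 format(x), if (open_lower) "(" else "[", format(lower),
                 format(upper), if (open_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype matrix (n_samples x n_sites) from a haplotype matrix whose rows
# 2i-1, 2i belong to sample i
haps_to_genotypes <- function(haps) {
  n <- nrow(haps) / 2L
  haps[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
}

# rows of a haplotype matrix belonging to the given sample indices
hap_rows <- function(sample_idx) {
  as.vector(rbind(2L * sample_idx - 1L, 2L * sample_idx))
}
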