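# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed from a master seed and a counter.
# Multiplier kept small so master * mult stays below 2^53 and the double
# arithmetic is exact.
derive_seed <- function(master, counter) {
  master <- as.double(master) %% 2147483647
  as.integer((master * 48271 + as.double(counter)) %% 2147483647)
}

# Evaluate `expr` under a local RNG seeded with `seed` when non-NULL,
# otherwise use the ambient RNG state.
with_seed_or_ambient <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Coerce a locus / region given as list(chrom, start, end), a 1-row data
# frame, or c(chrom, start, end) into a canonical list.
as_region <- function(region) {
  if (is.null(region)) return(NULL)
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1)
    region <- as.list(region)
  }
  if (is.list(region)) {
    out <- list(
      chrom = as.character(region$chrom),
      start = as.numeric(region$start),
      end = as.numeric(region$end)
    )
  } else if (length(region) == 3) {
    out <- list(
      chrom = as.character(region[[1]]),
      start = as.numeric(region[[2]]),
      end = as.numeric(region[[3]])
    )
  } else {
    abort("`region` must be list(chrom, start, end) or a length-3 vector.")
  }
  if (anyNA(c(out$start, out$end)) || out$start > out$end) {
    abort("Region start must be <= end and numeric.")
  }
  out
}

# Simple stderr log line used by loaders and the pipeline.
log_msg <- function(...) {
  inform(paste0(...))
}
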