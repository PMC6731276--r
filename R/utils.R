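#' @keywords internal
"_PACKAGE"

## Deterministic sub-seed derivation: every repeated/nested stochastic step
## (permutation batches, scan runs, per-sample enrichment, null-model draws)
## draws its seed from the caller's master seed through this map, so results
## are reproducible regardless of evaluation order. Kept strictly below 2^31.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483647) + 1
  o <- as.double(offset) %% 2147483647
  as.integer((s * 48271 + o * 8191 + 12345) %% 2147483647)
}

## stop()/warning() wrappers with a consistent condition prefix
pc_stop <- function(...) stop(..., call. = FALSE)
pc_warn <- function(...) warning(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == floor(x)

## row-wise mean/variance without apply() overhead
row_means <- function(x) rowMeans(x)
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  rowSums((x - rowMeans(x))^2) / (n - 1)
}
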