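# Internal helpers: seeded evaluation, derived sub-seeds, sample moments.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# The caller's RNG state is restored on exit, so seeded simulation calls
# do not perturb the session stream (NULL seed = use the current stream).
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation so that one master seed drives several
# independent draws; kept below 2^31 - 1.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647 +
               7919 * offset) %% 2147483647L
}

# Adjusted Fisher-Pearson skewness (the SAS/Excel G1 form).
sampleSkewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- sd(x)
  if (s < .Machine$double.eps^0.5) return(NA_real_)
  z <- (x - mean(x)) / s
  n / ((n - 1) * (n - 2)) * sum(z^3)
}

# Excess kurtosis with small-sample adjustment (SAS form; Gaussian -> 0).
sampleKurtosis <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) return(NA_real_)
  s <- sd(x)
  if (s < .Machine$double.eps^0.5) return(NA_real_)
  z <- (x - mean(x)) / s
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

# Haldane map function and its RIL-adjusted expansion.
haldaneR <- function(d_cM) 0.5 * (1 - exp(-0.02 * d_cM))
rilAdjust <- function(r) 2 * r / (1 + 2 * r)

chromNumber <- function(chrom) {
  n <- suppressWarnings(as.integer(gsub("[^0-9]", "", chrom)))
  ifelse(is.na(n), match(chrom, unique(chrom)), n)
}
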