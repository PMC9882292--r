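#' Derive a reproducible child seed from a master seed
#'
#' Counter-based derivation: replicate `k` of a run with master seed `seed`
#' gets its own RNG stream seed, so any single replicate can be reproduced
#' in isolation. All arithmetic stays below 2^31 - 1.
#'
#' @param seed master seed (integer)
#' @param k counter (replicate index, >= 0)
#' @return an integer seed
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k), length(k) == 1)
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m)
  as.integer(1 + (s * 48271 + as.double(k) * 1000003) %% (m - 1))
}

# Exact two-sample Kolmogorov-Smirnov statistic: sup |F1 - F2| over the
# combined support, both ECDFs right-continuous.
ks_statistic <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ks_sorted(x, sort(y))
}

# Same statistic with y pre-sorted; O(n log n + n log m). The sup is
# attained at a jump of either ECDF. Between consecutive unique x values
# F_x is constant, so |F_x - F_y| over that gap is extremal either at the
# left x jump (right-continuous values) or just below the right x jump
# (both left limits); evaluating both at the unique x values covers every
# y jump as well, exactly, ties included.
ks_sorted <- function(x, sy) {
  u <- sort(unique(x))
  n <- length(x); m <- length(sy)
  sx <- sort(x)
  fx <- findInterval(u, sx) / n
  fx_minus <- findInterval(u, sx, left.open = TRUE) / n
  fy <- findInterval(u, sy) / m
  fy_minus <- findInterval(u, sy, left.open = TRUE) / m
  max(abs(fx - fy), abs(fx_minus - fy_minus))
}

# Right-continuous ECDF evaluated at q, from a sample.
ecdf_at <- function(sample, q) {
  findInterval(q, sort(sample)) / length(sample)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vp_log <- function(..., level = "INFO") {
  message(sprintf("[vesselprox %s] %s", level, paste0(...)))
}

utils::globalVariables(c("distance", "genotype", "sample", "kind",
                         "mean_distance_um", "area_fraction",
                         "perimeter_area_ratio"))
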