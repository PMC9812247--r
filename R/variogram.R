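#' Empirical semivariogram of a spatial profile
#'
#' `gamma(h) = 0.5 * mean[(v_i - v_j)^2]` over unit pairs whose separation
#' falls in the lag bin around `h`. The variogram is the spatial-
#' autocorrelation fingerprint that surrogate maps must preserve: it rises
#' with distance for an autocorrelated field and plateaus at the sill (the
#' field variance).
#'
#' @param values numeric vector (one per unit) or a [spatial_profile()].
#' @param distance_matrix symmetric mm distance matrix (computed from the
#'   profile coordinates if `values` is a profile).
#' @param n_lags number of lag bins; bin edges are quantiles of the pairwise
#'   distances (equal-count bins), so every reported lag rests on a similar
#'   number of pairs and no lag estimate is dominated by one or two pairs.
#' @param max_frac fraction of the maximum pairwise distance covered by the
#'   bins; pairs farther apart are ignored. The default cutoff of one third
#'   of the maximum distance is the common geostatistics convention: distant
#'   pairs are few, mutually dependent, and uninformative about the
#'   autocorrelation structure that matters locally.
#' @return data frame of class `variogram` with columns `lag` (bin center,
#'   mm), `gamma`, `n_pairs`; empty bins are dropped.
#' @export
compute_variogram <- function(values, distance_matrix = NULL, n_lags = 10,
                              max_frac = 1/3) {
  if (inherits(values, "spatial_profile")) {
    distance_matrix <- distance_matrix %||% profile_distances(values)
    values <- values$value
  }
  stopifnot(is.numeric(values), is.matrix(distance_matrix))
  n <- length(values)
  if (n < 3) stop_imtx("need at least 3 units")
  if (nrow(distance_matrix) != n) stop_imtx("distance matrix size mismatch")
  pairs <- variogram_pairs(distance_matrix, n_lags, max_frac)
  sq <- (values[pairs$i] - values[pairs$j])^2
  gamma <- 0.5 * as.numeric(tapply(sq, pairs$bin, mean))
  structure(data.frame(lag = pairs$lag,
                       gamma = gamma,
                       n_pairs = pairs$n_pairs),
            class = c("variogram", "data.frame"))
}

# shared pair/bin bookkeeping for compute_variogram and generate_surrogates:
# equal-count bins with the mean pair distance as the reported lag
variogram_pairs <- function(distance_matrix, n_lags, max_frac) {
  n <- nrow(distance_matrix)
  ut <- upper.tri(distance_matrix)
  d <- distance_matrix[ut]
  maxd <- max(d)
  if (maxd <= 0) stop_imtx("degenerate geometry: all units co-located")
  lmax <- max_frac * maxd
  keep <- d > 0 & d <= lmax
  idx <- which(ut, arr.ind = TRUE)
  dk <- d[keep]
  breaks <- unique(quantile(dk, probs = seq(0, 1, length.out = n_lags + 1)))
  bin <- findInterval(dk, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  # renumber to consecutive nonempty bins and take the pair-mean lag
  ub <- sort(unique(bin))
  bin <- match(bin, ub)
  lag <- as.numeric(tapply(dk, bin, mean))
  list(i = idx[keep, 1], j = idx[keep, 2], bin = bin,
       lag = lag, n_pairs = as.integer(table(bin)))
}
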