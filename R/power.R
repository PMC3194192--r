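#' Convert fold coverage to a per-position read-start rate
#'
#' Fold coverage `c` (sequenced bases per genome base) relates to the
#' read-start rate as `lambda = c / S` for read length `S`. Power
#' formulas use the per-position rate throughout.
#'
#' @param coverage Fold coverage.
#' @param S Read length (bp), default 35.
#' @return Read starts per position.
#' @export
coverage_to_rate <- function(coverage, S = 35) coverage / S

#' Theoretical power of depth-only CNV detection
#'
#' Under a simple Poisson model, the read count in a copy-neutral region
#' of size `delta` has mean `mu0 = delta * lambda / S`; a 1-copy loss
#' halves it and a 1-copy gain multiplies it by 1.5. The test is
#' one-sided with an exact discrete critical value: the most extreme
#' count in the alternative's direction whose null tail probability is
#' at most `alpha`. Power is the alternative's tail beyond (and
#' including) that critical value.
#'
#' @param delta Region (CNV) size in bp.
#' @param lam Read starts per position.
#' @param S Read length (bp).
#' @param alpha Type I error cutoff.
#' @param direction `"loss"` (1-copy loss, lower tail) or `"gain"`
#'   (1-copy gain, upper tail).
#' @return Power in `[0, 1]` (0 when `mu0 = 0`, e.g. `delta = 0`).
#' @export
depth_power <- function(delta, lam, S = 35, alpha = 1e-5,
                        direction = c("loss", "gain")) {
  direction <- match.arg(direction)
  mu0 <- delta * lam / S
  if (mu0 <= 0) return(0)
  if (direction == "loss") {
    k <- stats::qpois(alpha, mu0)
    while (k >= 0 && stats::ppois(k, mu0) > alpha) k <- k - 1
    if (k < 0) return(0)
    stats::ppois(k, 0.5 * mu0)
  } else {
    k <- stats::qpois(1 - alpha, mu0)
    while (stats::ppois(k - 1, mu0, lower.tail = FALSE) > alpha) k <- k + 1
    stats::ppois(k - 1, 1.5 * mu0, lower.tail = FALSE)
  }
}

#' Power of deletion detection from a single mate pair
#'
#' A pair whose insert contains a deletion of size `delta` maps with an
#' outer-distance drawn from the null insert distribution translated by
#' `delta`. The test rejects when the distance exceeds `Q`, the
#' `(1 - alpha)` quantile of the null distribution; power is
#' `1 - CDF_shifted(Q)`.
#'
#' @param delta Deletion size (bp).
#' @param insert An `insert_model`.
#' @param alpha Type I error cutoff.
#' @return Power in `[0, 1]`. At `delta = 0` this is the achieved size
#'   of the discrete test (at most `alpha`, within one pmf cell of it).
#' @export
single_pair_power <- function(delta, insert, alpha = 1e-5) {
  cdf <- cumsum(insert$pmf)
  Q <- match(TRUE, cdf >= 1 - alpha)
  if (is.na(Q)) Q <- insert$dist_cutoff
  # shifted variable is X + delta with X ~ null pmf, so the shifted CDF
  # at Q is the null CDF at Q - delta
  x <- round(Q - delta)
  if (x < 1) return(1)
  if (x >= insert$dist_cutoff) return(0)
  1 - cdf[x]
}

#' Power of deletion detection from multiple spanning pairs
#'
#' Aggregating `m` spanning pairs, none of which need be an individual
#' outlier, the mean outer-distance has standard error `sigma / sqrt(m)`
#' under a Gaussian approximation of the null. The expected number of
#' inserts spanning a point is `(lambda / 2) * D` (pair-start rate times
#' insert span); for a heterozygous deletion only the carrier
#' haplotype's pairs are shifted, halving `m`. Power of the one-sided
#' Z test is `1 - Phi(z_{1-alpha} - Z)` with noncentrality
#' `Z = delta * sqrt(m) / sigma`.
#'
#' @param delta Deletion size (bp).
#' @param lam Read starts per position (see [coverage_to_rate()]).
#' @param D Insert mean outer-distance (bp).
#' @param sigma Insert standard deviation (bp).
#' @param alpha Type I error cutoff.
#' @param zygosity `"het"` (default; halves the spanning-pair count) or
#'   `"hom"`.
#' @param m Optional explicit spanning-pair count, overriding the
#'   expected value (kept continuous; no flooring).
#' @return Power in `[0, 1]`; exactly `alpha` at `delta = 0`.
#' @export
multi_pair_power <- function(delta, lam, D, sigma, alpha = 1e-5,
                             zygosity = c("het", "hom"), m = NULL) {
  zygosity <- match.arg(zygosity)
  if (is.null(m)) {
    m <- lam / 2 * D
    if (zygosity == "het") m <- m / 2
  }
  Z <- delta * sqrt(m) / sigma
  stats::pnorm(Z - stats::qnorm(1 - alpha))
}

#' Expected number of deletion-spanning inserts
#' @inheritParams multi_pair_power
#' @return Expected (continuous) spanning-pair count.
#' @export
expected_spanning_pairs <- function(lam, D, zygosity = c("het", "hom")) {
  zygosity <- match.arg(zygosity)
  m <- lam / 2 * D
  if (zygosity == "het") m / 2 else m
}

#' Power heatmap over deletion size and coverage
#'
#' One power value per (size, coverage) cell. Modes: `depth` (1-copy
#' loss from depth only), `pair200` (mate-pair power, insert library
#' mean 200 sd 20), `pair1500` (library mean 1500 sd 200). Presets:
#' 35 bp reads, `alpha = 1e-5`. The conventional axes span deletion
#' sizes 50 bp to 256 kbp and coverages 0.1 to 5 fold.
#'
#' @param delta_range Deletion sizes (bp), the rows.
#' @param coverage_range Fold coverages, the columns.
#' @param mode One of `"depth"`, `"pair200"`, `"pair1500"`.
#' @param S Read length (bp).
#' @param alpha Type I error cutoff.
#' @param zygosity Zygosity convention for the pair modes.
#' @return Numeric matrix, `length(delta_range)` rows x
#'   `length(coverage_range)` columns, dimnames set to the ranges.
#' @export
power_heatmap <- function(delta_range, coverage_range,
                          mode = c("depth", "pair200", "pair1500"),
                          S = 35, alpha = 1e-5, zygosity = "hom") {
  mode <- match.arg(mode)
  stopifnot(length(delta_range) > 0, length(coverage_range) > 0)
  lib <- switch(mode, depth = NULL, pair200 = c(200, 20),
                pair1500 = c(1500, 200))
  out <- matrix(NA_real_, length(delta_range), length(coverage_range),
                dimnames = list(delta_range, coverage_range))
  for (i in seq_along(delta_range)) {
    for (j in seq_along(coverage_range)) {
      lam <- coverage_to_rate(coverage_range[j], S)
      out[i, j] <- if (mode == "depth") {
        depth_power(delta_range[i], lam, S = S, alpha = alpha,
                    direction = "loss")
      } else {
        multi_pair_power(delta_range[i], lam, D = lib[1], sigma = lib[2],
                         alpha = alpha, zygosity = zygosity)
      }
    }
  }
  out
}
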