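#' Histone exchange score
#'
#' `E = log2(myc + eps) - log2(HA + eps)` per region. The pseudocount
#' (default 0.05) damps the noise of regions with low read counts. High E
#' marks short-residence (rapidly exchanged) chromatin; the non-cleavable
#' sensor control is expected to center E at 0.
#'
#' @param myc,ha Non-negative normalized coverage vectors.
#' @param eps Pseudocount (default 0.05).
#' @return Exchange score in log2 units, vectorized.
#' @export
exchange_score <- function(myc, ha, eps = 0.05) {
  stopifnot(eps > 0, all(myc >= 0), all(ha >= 0))
  log2(myc + eps) - log2(ha + eps)
}

#' Histone-mark enrichment over input
#'
#' `log2(mark + 1) - log2(input + 1)`; the unit pseudocount keeps the score
#' finite at zero coverage.
#'
#' @param mark,input Non-negative coverage vectors.
#' @return Enrichment in log2 units.
#' @export
enrichment_score <- function(mark, input) {
  stopifnot(all(mark >= 0), all(input >= 0))
  log2(mark + 1) - log2(input + 1)
}

#' Normalize scores to a control region set
#'
#' Subtracts the mean score of a control set (typically the same regions
#' shifted 20 kb) from every value; the subtracted constant is attached so
#' raw values can be reconstructed exactly.
#'
#' @param values Per-region scores.
#' @param control_values Scores over the control set (non-empty).
#' @return `values - mean(control_values)`, with the subtracted mean in
#'   `attr(, "control_mean")`.
#' @export
normalize_to_control <- function(values, control_values) {
  if (length(control_values) == 0) stop("control set is empty")
  cm <- mean(control_values)
  out <- values - cm
  attr(out, "control_mean") <- cm
  out
}

#' Turnover thresholds for promoter stratification
#'
#' @param occupancy_min Minimum `log2(HA + eps)` for a promoter to count as
#'   occupied (default 1).
#' @param high_exchange_min Exchange score above which an occupied promoter is
#'   high-turnover (default 1.55).
#' @param low_exchange_max Exchange score below which it is low-turnover
#'   (default -0.45).
#' @return A named list.
#' @export
turnover_thresholds <- function(occupancy_min = 1, high_exchange_min = 1.55,
                                low_exchange_max = -0.45) {
  stopifnot(high_exchange_min > low_exchange_max)
  list(occupancy_min = occupancy_min,
       high_exchange_min = high_exchange_min,
       low_exchange_max = low_exchange_max)
}

#' Classify regions into high / low turnover
#'
#' Occupied regions (`log2(HA + eps) > occupancy_min`) are high-turnover when
#' their exchange score exceeds `high_exchange_min` and low-turnover when it
#' falls below `low_exchange_max`; everything else is unclassified. The two
#' classes are disjoint by construction.
#'
#' @param myc,ha Normalized coverage vectors.
#' @param thresholds From [turnover_thresholds()].
#' @param eps Pseudocount (default 0.05).
#' @return Factor with levels `high`, `low`, `unclassified`.
#' @export
classify_turnover <- function(myc, ha, thresholds = turnover_thresholds(),
                              eps = 0.05) {
  occ <- log2(ha + eps)
  e <- exchange_score(myc, ha, eps)
  lab <- rep("unclassified", length(e))
  occupied <- occ > thresholds$occupancy_min
  lab[occupied & e > thresholds$high_exchange_min] <- "high"
  lab[occupied & e < thresholds$low_exchange_max] <- "low"
  factor(lab, levels = c("high", "low", "unclassified"))
}

#' PRC2 binding score
#'
#' Raw read sum of the SUZ12, EZH2 and JARID2 components, used as the
#' ranking/binning key for bivalent promoters. The `log2(x + 1)` transform is
#' for displaying or correlating individual components, not for the sum.
#'
#' @param suz12,ezh2,jarid2 Non-negative read counts.
#' @return Numeric score (the raw sum).
#' @export
prc2_score <- function(suz12, ezh2, jarid2) {
  stopifnot(all(suz12 >= 0), all(ezh2 >= 0), all(jarid2 >= 0))
  suz12 + ezh2 + jarid2
}

#' Classify the dynamics mode from myc/HA trends
#'
#' Given per-bin trends (signed slopes) of mean log2 myc and log2 HA against
#' a covariate: joint increase is `incorporation` (new deposition adds both
#' tags), an HA drop with flat myc is `eviction`, diverging trends (myc
#' rising relative to HA) is `exchange_shift`, and anything else `stable`.
#'
#' @param trend_myc,trend_ha Signed slopes.
#' @param tol Dead-band below which a slope counts as flat (default 0.1 log2
#'   units).
#' @return One of `"incorporation"`, `"eviction"`, `"exchange_shift"`,
#'   `"stable"`.
#' @export
classify_dynamics_mode <- function(trend_myc, trend_ha, tol = 0.1) {
  if (trend_myc > tol && trend_ha > tol) return("incorporation")
  if (trend_ha < -tol && abs(trend_myc) <= tol) return("eviction")
  if ((trend_myc - trend_ha) > tol) return("exchange_shift")
  "stable"
}

#' Pooled exchange of binned mean coverage
#'
#' `log2(mean_myc + eps) - log2(mean_ha + eps)` per bin: the means are taken
#' across regions first and the log-ratio second. This mean-then-log
#' estimator is used for the CTCF nucleosome bins and is deliberately
#' distinct from averaging per-region exchange scores.
#'
#' @param mean_myc,mean_ha Per-bin mean coverage.
#' @param eps Pseudocount (default 0.05).
#' @return Per-bin exchange in log2 units.
#' @export
pooled_bin_exchange <- function(mean_myc, mean_ha, eps = 0.05) {
  exchange_score(mean_myc, mean_ha, eps)
}

#' Build an exchange track over a region set
#'
#' Convenience wrapper: shifted-point counting of the myc and HA channels
#' over `regions`, depth normalization against the 5 kb tiling, and the
#' exchange score.
#'
#' @param myc_frags,ha_frags Fragment `GRanges` (already length-filtered).
#' @param regions Region `GRanges`.
#' @param genome `Seqinfo` for the depth-normalization tiling.
#' @param shift_bp 5' shift (default 80).
#' @param depth_target Target tiling mean (default 0.4).
#' @param eps Pseudocount (default 0.05).
#' @return Data frame with `myc`, `ha` (normalized per-kb coverage) and
#'   `exchange`, one row per region.
#' @export
exchange_track <- function(myc_frags, ha_frags, regions, genome,
                           shift_bp = 80, depth_target = 0.4, eps = 0.05) {
  p_myc <- shift_five_prime(myc_frags, shift_bp)
  p_ha <- shift_five_prime(ha_frags, shift_bp)
  myc <- count_in_regions(p_myc, regions) *
    depth_factor(p_myc, genome, depth_target)
  ha <- count_in_regions(p_ha, regions) *
    depth_factor(p_ha, genome, depth_target)
  data.frame(myc = myc, ha = ha, exchange = exchange_score(myc, ha, eps))
}
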