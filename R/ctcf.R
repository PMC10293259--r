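#' Nucleosome bin layout around CTCF motifs
#'
#' The analyzed window covers the two nucleosomes on either side of the motif
#' center (4 x `nuc_bp`, default 720 bp) divided into `n_bins` bins (default
#' 31, ~23 bp each); the division remainder is absorbed by the central bin so
#' the layout stays mirror-symmetric, which makes strand-flip antisymmetry
#' exact. `n_bins` must be odd when the remainder is nonzero.
#'
#' @param nuc_bp Nucleosome span in bp (default 180).
#' @param n_bins Number of bins covering the window (default 31).
#' @return List with `nuc_bp`, `n_bins`, `span`, `half`, bin `widths` and
#'   cumulative `breaks`.
#' @export
nucleosome_layout <- function(nuc_bp = 180, n_bins = 31) {
  stopifnot(n_bins >= 4, nuc_bp > 0)
  span <- 4L * as.integer(nuc_bp)
  base <- span %/% n_bins
  rem <- span - base * n_bins
  if (rem > 0 && n_bins %% 2 == 0)
    stop("n_bins must be odd when the window is not evenly divisible")
  widths <- rep(base, n_bins)
  widths[(n_bins + 1) %/% 2] <- base + rem
  list(nuc_bp = nuc_bp, n_bins = n_bins, span = span, half = span %/% 2L,
       widths = widths, breaks = c(0, cumsum(widths)))
}

#' Strand-aware exchange around CTCF motifs
#'
#' Bins myc and HA points over the four nucleosomes around each motif center
#' (coordinates mirrored for minus-strand motifs so column 1 is always the
#' motif-upstream side), computes the pooled per-bin exchange (mean coverage
#' across motifs first, log-ratio second) and per-motif per-nucleosome-zone
#' exchange for asymmetry scoring. Motifs inside genes should be excluded by
#' the caller (e.g. with [overlap_flags()] against the gene set).
#'
#' @param myc_points,ha_points Width-1 `GRanges`.
#' @param motifs Stranded motif `GRanges`.
#' @param layout From [nucleosome_layout()].
#' @param eps Pseudocount (default 0.05).
#' @return List: `bins` (data frame with per-bin pooled `mean_myc`, `mean_ha`,
#'   `exchange`), `zone_exchange` (motifs x 4 matrix, zones -2, -1, +1, +2;
#'   `NA` rows where a zone has no coverage in either channel), and the raw
#'   per-zone density matrices `zone_myc`, `zone_ha`.
#' @export
nucleosome_bin_exchange <- function(myc_points, ha_points, motifs,
                                    layout = nucleosome_layout(), eps = 0.05) {
  center <- (GenomicRanges::start(motifs) + GenomicRanges::end(motifs)) %/% 2L
  w0 <- center - layout$half
  minus <- as.character(GenomicRanges::strand(motifs)) == "-"
  chrom <- GenomicRanges::seqnames(motifs)

  orient <- function(mat) {
    mat[minus, ] <- mat[minus, rev(seq_len(ncol(mat))), drop = FALSE]
    mat
  }
  count <- function(points, breaks) {
    orient(.window_count_matrix(points, chrom, w0, layout$span,
                                length(breaks) - 1L, breaks))
  }

  m_myc <- count(myc_points, layout$breaks)
  m_ha <- count(ha_points, layout$breaks)
  dens <- function(mat, widths) sweep(mat, 2, widths / 1000, `/`)
  bins <- data.frame(
    bin = seq_len(layout$n_bins),
    mean_myc = colMeans(dens(m_myc, layout$widths)),
    mean_ha = colMeans(dens(m_ha, layout$widths)))
  bins$exchange <- pooled_bin_exchange(bins$mean_myc, bins$mean_ha, eps)

  zone_breaks <- seq(0, layout$span, by = layout$nuc_bp)
  z_myc <- count(myc_points, zone_breaks)
  z_ha <- count(ha_points, zone_breaks)
  zd_myc <- dens(z_myc, rep(layout$nuc_bp, 4))
  zd_ha <- dens(z_ha, rep(layout$nuc_bp, 4))
  zone_e <- log2(zd_myc + eps) - log2(zd_ha + eps)
  uncovered <- (z_myc + z_ha) == 0
  zone_e[rowSums(uncovered) > 0, ] <- NA_real_
  colnames(zone_e) <- colnames(zd_myc) <- colnames(zd_ha) <-
    c("m2", "m1", "p1", "p2")
  list(bins = bins, zone_exchange = zone_e,
       zone_myc = zd_myc, zone_ha = zd_ha)
}

#' Per-motif exchange asymmetry score
#'
#' `A = mean(E over nucleosomes +1, +2) - mean(E over -1, -2)`, in
#' motif-orientation-corrected log2 units. Flipping every motif strand
#' negates every A exactly (the zone layout is mirror-symmetric).
#'
#' @param zone_exchange Motifs x 4 matrix with columns `m2, m1, p1, p2`
#'   (from [nucleosome_bin_exchange()]).
#' @return Numeric vector of asymmetry scores (NA where zones lack coverage).
#' @export
asymmetry_score <- function(zone_exchange) {
  rowMeans(zone_exchange[, c("p1", "p2"), drop = FALSE]) -
    rowMeans(zone_exchange[, c("m2", "m1"), drop = FALSE])
}

#' Top-vs-bottom asymmetry-decile contrast
#'
#' Mean of `values` over the motifs with the highest decile of asymmetry
#' scores minus the mean over the bottom decile (the bottom decile serves as
#' the control set). `values` may be a per-motif vector or a motifs x bins
#' matrix (e.g. a mark-enrichment profile), in which case the contrast is
#' per column.
#'
#' @param values Per-motif vector or matrix.
#' @param asymmetry Per-motif asymmetry scores.
#' @param fraction Decile fraction (default 0.1); each group has
#'   `ceiling(fraction * n)` motifs.
#' @return Contrast (scalar or per-column vector) with `n_top`, `n_bottom`,
#'   `top_idx`, `bottom_idx` attributes.
#' @export
decile_contrast <- function(values, asymmetry, fraction = 0.1) {
  ok <- which(!is.na(asymmetry))
  if (length(ok) < 20) stop("need at least 20 motifs with defined asymmetry")
  k <- ceiling(fraction * length(ok))
  top <- ok[order(asymmetry[ok], decreasing = TRUE, method = "radix")[seq_len(k)]]
  bottom <- ok[order(asymmetry[ok], method = "radix")[seq_len(k)]]
  vm <- as.matrix(values)
  out <- colMeans(vm[top, , drop = FALSE]) -
    colMeans(vm[bottom, , drop = FALSE])
  if (ncol(vm) == 1) out <- unname(out[1])
  attr(out, "n_top") <- length(top)
  attr(out, "n_bottom") <- length(bottom)
  attr(out, "top_idx") <- top
  attr(out, "bottom_idx") <- bottom
  out
}

#' Partition motifs into occupied and unoccupied sets
#'
#' A motif is occupied when it overlaps (>= 1 bp) any ChIP-seq peak.
#' The partition is exhaustive and disjoint.
#'
#' @param motifs Motif `GRanges`.
#' @param chip_peaks Peak `GRanges` on the same genome.
#' @return List with `occupied` and `unoccupied` `GRanges`.
#' @export
partition_by_occupancy <- function(motifs, chip_peaks) {
  occ <- overlap_flags(motifs, chip_peaks)
  list(occupied = motifs[occ], unoccupied = motifs[!occ])
}
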