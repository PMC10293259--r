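#' Shift regions by a fixed offset
#'
#' Translates every interval by `offset_bp`, the construction used for
#' shifted-control regions (e.g. 20 kb downstream of an analyzed region set).
#' The default is a strand-ignorant literal translation; `strand_aware = TRUE`
#' shifts minus-strand regions in the opposite direction. Shifted intervals
#' that leave chromosome bounds are dropped (not clipped), so a control set
#' may be smaller than its target set; downstream statistics use means, which
#' tolerates that.
#'
#' @param regions A `GRanges` with `seqinfo` set (or pass `genome`).
#' @param offset_bp Signed shift in bp.
#' @param genome Optional `Seqinfo` overriding `seqinfo(regions)`.
#' @param strand_aware Shift against strand for `-` regions. Default `FALSE`.
#' @return Shifted `GRanges`; the number of dropped intervals is in
#'   `metadata()$n_dropped`.
#' @export
shift_regions <- function(regions, offset_bp, genome = NULL,
                          strand_aware = FALSE) {
  if (is.null(genome)) genome <- GenomeInfoDb::seqinfo(regions)
  lens <- GenomeInfoDb::seqlengths(genome)
  if (any(is.na(lens)))
    stop("genome lengths required to bound-check shifted regions")
  off <- rep(as.integer(offset_bp), length(regions))
  if (strand_aware) {
    neg <- as.character(GenomicRanges::strand(regions)) == "-"
    off[neg] <- -off[neg]
  }
  # shift() warns on transient out-of-bound ranges; we drop them ourselves
  shifted <- suppressWarnings(GenomicRanges::shift(regions, off))
  lens_per <- lens[as.character(GenomicRanges::seqnames(shifted))]
  ok <- GenomicRanges::start(shifted) >= 1L &
    GenomicRanges::end(shifted) <= lens_per
  out <- shifted[ok]
  S4Vectors::metadata(out)$n_dropped <- sum(!ok)
  out
}

#' Flag regions overlapping another region set
#'
#' @param regions Query `GRanges`.
#' @param other Subject `GRanges` on the same genome.
#' @param min_overlap_bp Minimum overlap in bp to count (default 1).
#' @return Logical vector, one flag per query region.
#' @export
overlap_flags <- function(regions, other, min_overlap_bp = 1L) {
  GenomicRanges::countOverlaps(regions, other,
                               minoverlap = min_overlap_bp,
                               ignore.strand = TRUE) > 0L
}
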