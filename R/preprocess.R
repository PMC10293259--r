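#' Filter fragments by maximum length
#'
#' Drops fragments longer than `max_bp` (the printed rule is "> 300 bp
#' filtered out", so a 300 bp fragment survives).
#'
#' @param frags Fragment `GRanges`.
#' @param max_bp Maximum retained fragment length (default 300).
#' @return Filtered `GRanges`; `metadata()$n_removed` records the drop count.
#' @export
filter_fragments <- function(frags, max_bp = 300) {
  stopifnot(max_bp > 0)
  keep <- GenomicRanges::width(frags) <= max_bp
  out <- frags[keep]
  S4Vectors::metadata(out)$n_removed <- sum(!keep)
  out
}

#' ATAC minimum-length filter
#'
#' Discards sub-nucleosomal fragments shorter than `min_bp` ("< 120 bp
#' discarded", so a 120 bp fragment survives). Intended for the ATAC channel.
#'
#' @param frags Fragment `GRanges`.
#' @param min_bp Minimum retained length (default 120).
#' @return Filtered `GRanges` with `metadata()$n_removed`.
#' @export
atac_filter <- function(frags, min_bp = 120) {
  keep <- GenomicRanges::width(frags) >= min_bp
  out <- frags[keep]
  if (length(out) == 0 && length(frags) > 0)
    warning("ATAC filter removed every fragment")
  S4Vectors::metadata(out)$n_removed <- sum(!keep)
  out
}

#' Shift fragment 5' ends toward their midpoints
#'
#' Moves each fragment's 5' end `shift_bp` toward 3' (strand-aware), the
#' standard approximation of the fragment midpoint when `shift_bp` is half
#' the mean fragment length (80 bp for a 160 bp library). Unstranded
#' fragments are treated as `+`. Points are clipped to chromosome bounds
#' when `seqinfo` is available.
#'
#' @param frags Fragment `GRanges`.
#' @param shift_bp Non-negative shift (default 80).
#' @return Width-1 `GRanges` of points, one per fragment.
#' @export
shift_five_prime <- function(frags, shift_bp = 80) {
  stopifnot(shift_bp >= 0)
  s <- as.character(GenomicRanges::strand(frags))
  pos <- ifelse(s == "-",
                GenomicRanges::end(frags) - shift_bp,
                GenomicRanges::start(frags) + shift_bp)
  lens <- GenomeInfoDb::seqlengths(frags)
  if (!all(is.na(lens))) {
    per <- lens[as.character(GenomicRanges::seqnames(frags))]
    pos <- pmax(1, pmin(pos, per))
  } else {
    pos <- pmax(1, pos)
  }
  GenomicRanges::GRanges(GenomicRanges::seqnames(frags),
                         IRanges::IRanges(pos, width = 1L),
                         strand = GenomicRanges::strand(frags),
                         seqinfo = GenomeInfoDb::seqinfo(frags))
}

#' Count points in regions (mean coverage per kb)
#'
#' Per region: number of points inside, divided by the region length in bp,
#' times 1000. The per-kb unit is a convention only — every downstream
#' statistic is a ratio or pseudocounted log difference, so a common rescaling
#' cancels after depth normalization.
#'
#' @param points Width-1 `GRanges` (from [shift_five_prime()]).
#' @param regions Region `GRanges`.
#' @return Numeric vector, one value per region.
#' @export
count_in_regions <- function(points, regions) {
  n <- GenomicRanges::countOverlaps(regions, points, ignore.strand = TRUE)
  n / GenomicRanges::width(regions) * 1000
}

#' Per-sample depth factor against the 5 kb genome tiling
#'
#' The normalization universe is the genome-wide 5 kb tiling: the factor is
#' `target / mean(count per kb over all tiles)`, so that after scaling every
#' sample's tiling mean equals `target` (default 0.4).
#'
#' @param points Width-1 `GRanges` for the sample.
#' @param genome A `Seqinfo`.
#' @param target Target mean normalized depth (default 0.4).
#' @param tile_width Tiling width in bp (default 5000).
#' @return A single scaling factor.
#' @export
depth_factor <- function(points, genome, target = 0.4, tile_width = 5000) {
  tiles <- tile_genome(genome, tile_width)
  m <- mean(count_in_regions(points, tiles))
  if (m == 0) stop("cannot normalize a sample with zero coverage")
  target / m
}

#' Apply depth factors to a count table
#'
#' @param table Numeric matrix or data frame of counts (regions x samples).
#' @param factors Per-sample factors, recycled across columns; typically from
#'   [depth_factor()].
#' @return Scaled table with the factors in `attr(, "depth_factors")`.
#' @export
normalize_depth <- function(table, factors) {
  tab <- as.matrix(table)
  stopifnot(length(factors) %in% c(1L, ncol(tab)))
  out <- sweep(tab, 2, rep_len(factors, ncol(tab)), `*`)
  attr(out, "depth_factors") <- rep_len(factors, ncol(tab))
  out
}

#' Pool replicate fragment collections with optional depth matching
#'
#' When `match_depth = TRUE`, collections with more fragments are randomly
#' down-sampled (seeded) to the size of the smallest collection before
#' concatenation, so a deeper replicate cannot dominate the pool.
#'
#' @param collections List of fragment `GRanges` (same channel).
#' @param match_depth Down-sample to the minimum size first. Default `TRUE`.
#' @param seed Integer seed for the subsampling.
#' @return Pooled fragment `GRanges`.
#' @export
pool_replicates <- function(collections, match_depth = TRUE, seed = 1) {
  stopifnot(length(collections) >= 2)
  if (match_depth) {
    n_min <- min(vapply(collections, length, integer(1)))
    collections <- .with_seed(seed, lapply(collections, function(gr) {
      if (length(gr) > n_min) gr[sort(sample(length(gr), n_min))] else gr
    }))
  }
  out <- do.call(c, lapply(collections, GenomicRanges::granges))
  mq <- unlist(lapply(collections, function(gr)
    gr$mapq %||% rep(NA_integer_, length(gr))))
  S4Vectors::mcols(out)$mapq <- mq
  S4Vectors::metadata(out) <- S4Vectors::metadata(collections[[1]])
  out
}
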