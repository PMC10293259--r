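#' Read aligned paired-end fragments
#'
#' Imports one fragment per properly paired template from a BAM/SAM file
#' (via [GenomicAlignments::readGAlignmentPairs()] with a mapping-quality
#' filter, the standard Bioconductor route) or from the package's fragment-BED
#' dialect (6 columns: chrom, start, end, name, mapq, strand — mapping quality
#' sits in the BED score slot so the simulator needs no BAM writer).
#'
#' @param path Path to `.bam`, `.sam` or a fragment-BED file.
#' @param min_mapq Minimum mapping quality retained (default 10); records
#'   below it are excluded.
#' @param sample Sample name stored in the collection's metadata.
#' @param channel One of `"myc"`, `"HA"`, `"mark"`, `"input"`, `"ATAC"`.
#' @param genome Optional `Seqinfo` to attach and validate against.
#' @return A `GRanges` of fragments with a `mapq` column; `metadata()` carries
#'   `sample`, `channel` and `n_skipped` (records dropped by pairing/MQ).
#' @export
read_fragments <- function(path, min_mapq = 10, sample = NA_character_,
                           channel = c("myc", "HA", "mark", "input", "ATAC"),
                           genome = NULL) {
  channel <- match.arg(channel)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bam", "sam")) {
    gr <- .read_fragments_bam(path, min_mapq)
  } else {
    gr <- .read_fragments_bed(path, min_mapq)
  }
  if (!is.null(genome)) gr <- .apply_genome(gr, genome, oob = "drop")
  fragment_collection(gr, sample = sample, channel = channel,
                      n_skipped = S4Vectors::metadata(gr)$n_skipped %||% 0L)
}

.read_fragments_bam <- function(path, min_mapq) {
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  n_total <- Rsamtools::countBam(path)$records
  param <- Rsamtools::ScanBamParam(
    what = "mapq",
    mapqFilter = min_mapq,
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  pairs <- GenomicAlignments::readGAlignmentPairs(path, param = param)
  gr <- GenomicRanges::granges(pairs, on.discordant.seqnames = "drop")
  S4Vectors::mcols(gr)$mapq <-
    S4Vectors::mcols(GenomicAlignments::first(pairs))$mapq
  S4Vectors::metadata(gr)$n_skipped <- n_total - 2L * length(gr)
  gr
}

.read_fragments_bed <- function(path, min_mapq) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "name", "mapq", "strand"),
                           stringsAsFactors = FALSE)
  if (any(tab$end <= tab$start))
    stop("fragment-BED contains records with end <= start")
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start + 1L, tab$end),
                               strand = tab$strand,
                               mapq = as.integer(tab$mapq))
  keep <- gr$mapq >= min_mapq
  out <- gr[keep]
  S4Vectors::metadata(out)$n_skipped <- sum(!keep)
  out
}

#' Tag a fragment GRanges with sample/channel metadata
#'
#' @param gr Fragment `GRanges` (must have positive widths).
#' @param sample Sample name.
#' @param channel Channel label.
#' @param n_skipped Count of records dropped on import.
#' @return The same `GRanges` with metadata set.
#' @export
fragment_collection <- function(gr, sample = NA_character_, channel = "myc",
                                n_skipped = 0L) {
  stopifnot(all(GenomicRanges::width(gr) >= 1L))
  S4Vectors::metadata(gr)$sample <- sample
  S4Vectors::metadata(gr)$channel <- channel
  S4Vectors::metadata(gr)$n_skipped <- n_skipped
  gr
}

#' Write fragments in the fragment-BED dialect
#'
#' @param frags Fragment `GRanges` with a `mapq` column.
#' @param path Output path.
#' @export
write_fragments <- function(frags, path) {
  mapq <- frags$mapq %||% rep(60L, length(frags))
  strand <- as.character(GenomicRanges::strand(frags))
  strand[strand == "*"] <- "+"
  lines <- sprintf("%s\t%d\t%d\tf%d\t%d\t%s",
                   as.character(GenomicRanges::seqnames(frags)),
                   GenomicRanges::start(frags) - 1L,
                   GenomicRanges::end(frags),
                   seq_along(frags), as.integer(mapq), strand)
  writeLines(lines, path)
  invisible(path)
}
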