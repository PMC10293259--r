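#' Read a chromosome-sizes table
#'
#' Reads a two-column TSV (`name<TAB>length`) into a [GenomeInfoDb::Seqinfo]
#' object, the package's genome representation. All intervals elsewhere are
#' validated against these bounds.
#'
#' @param path Path to a chrom.sizes TSV (no header).
#' @return A `Seqinfo` object.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  make_genome(tab$chrom, tab$length)
}

#' Construct a genome from names and lengths
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Positive integer lengths (bp), one per chromosome.
#' @return A `Seqinfo` object.
#' @export
make_genome <- function(chrom_names, chrom_lengths) {
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(chrom_lengths <= 0) || any(!is.finite(chrom_lengths)))
    stop("chromosome lengths must be positive and finite")
  GenomeInfoDb::Seqinfo(seqnames = as.character(chrom_names),
                        seqlengths = as.integer(chrom_lengths))
}

#' Write a chromosome-sizes table
#' @param genome A `Seqinfo` object.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  tab <- data.frame(chrom = GenomeInfoDb::seqnames(genome),
                    length = GenomeInfoDb::seqlengths(genome))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Attach genome bounds to a GRanges and validate / resolve out-of-bounds
# records. `oob` controls intervals exceeding [0, length); `unknown_chrom`
# controls records on chromosomes absent from the genome.
.apply_genome <- function(gr, genome,
                          oob = c("error", "drop", "clip"),
                          unknown_chrom = c("error", "drop")) {
  oob <- match.arg(oob)
  unknown_chrom <- match.arg(unknown_chrom)
  known <- as.character(GenomicRanges::seqnames(gr)) %in%
    GenomeInfoDb::seqnames(genome)
  if (!all(known)) {
    if (unknown_chrom == "error")
      stop("unknown chromosome(s): ",
           paste(unique(as.character(GenomicRanges::seqnames(gr))[!known]),
                 collapse = ", "))
    gr <- gr[known]
  }
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
  lens <- GenomeInfoDb::seqlengths(genome)[as.character(GenomicRanges::seqnames(gr))]
  bad <- GenomicRanges::start(gr) < 1L | GenomicRanges::end(gr) > lens
  if (any(bad)) {
    if (oob == "error")
      stop(sum(bad), " interval(s) out of chromosome bounds")
    if (oob == "drop") gr <- gr[!bad]
    else {
      GenomicRanges::start(gr) <- pmax(GenomicRanges::start(gr), 1L)
      GenomicRanges::end(gr) <- pmin(
        GenomicRanges::end(gr),
        GenomeInfoDb::seqlengths(genome)[as.character(GenomicRanges::seqnames(gr))])
    }
  }
  GenomeInfoDb::seqinfo(gr) <- genome
  gr
}
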