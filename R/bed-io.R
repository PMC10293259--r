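#' Read a BED file into a region set
#'
#' Imports BED3/BED6/BED12 via [rtracklayer::import()] and validates the
#' intervals against a genome. Regions are returned as a [GenomicRanges::GRanges]
#' (1-based closed, the Bioconductor convention; BED's 0-based half-open
#' coordinates are converted on import and restored by [write_bed()], so
#' adjacent BED intervals `[a,b)`, `[b,c)` never overlap in memory either).
#'
#' @param path Path to a BED file.
#' @param genome Optional `Seqinfo`; when given, intervals are validated
#'   against chromosome bounds.
#' @param oob How to treat out-of-bounds intervals: `"error"` (default),
#'   `"drop"` or `"clip"`.
#' @param unknown_chrom `"error"` (default) or `"drop"` records whose
#'   chromosome is absent from `genome`.
#' @param sorted Sort by (chrom, start) before returning. Default keeps file
#'   order.
#' @return A `GRanges` with any name/score columns preserved.
#' @export
read_bed <- function(path, genome = NULL,
                     oob = c("error", "drop", "clip"),
                     unknown_chrom = c("error", "drop"),
                     sorted = FALSE) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) .diagnose_bed(path, conditionMessage(e)))
  if (!is.null(genome))
    gr <- .apply_genome(gr, genome, oob = match.arg(oob),
                        unknown_chrom = match.arg(unknown_chrom))
  if (sorted) gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  gr
}

# Re-scan a BED file that rtracklayer rejected and point at the offending
# line; falls back to the original importer message.
.diagnose_bed <- function(path, msg) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("BED parse error at line %d: fewer than 3 fields", i))
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("BED parse error at line %d: non-numeric coordinates", i))
    if (s >= e)
      stop(sprintf("BED parse error at line %d: start (%s) >= end (%s)",
                   i, f[2], f[3]))
  }
  stop("BED import failed: ", msg)
}

#' Write a region set as BED6
#'
#' Deterministic formatter (one `sprintf` per line) so that
#' `write_bed(read_bed(f))` round-trips canonical BED6 files byte-identically.
#'
#' @param regions A `GRanges`; `name` and `score` metadata columns are used
#'   when present.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  m <- S4Vectors::mcols(regions)
  name <- if ("name" %in% names(m)) as.character(m$name) else rep(".", length(regions))
  name[is.na(name)] <- "."
  score <- if ("score" %in% names(m)) m$score else rep(0, length(regions))
  score[is.na(score)] <- 0
  score <- ifelse(score == round(score),
                  sprintf("%d", as.integer(round(score))),
                  sprintf("%g", score))
  strand <- as.character(GenomicRanges::strand(regions))
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   as.character(GenomicRanges::seqnames(regions)),
                   GenomicRanges::start(regions) - 1L,
                   GenomicRanges::end(regions),
                   name, score, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene table
#'
#' Reads the TSV gene dialect (`gene_id, chrom, start, end, strand,
#' expression`; header required; BED-style 0-based half-open coordinates) into
#' a stranded `GRanges` with `gene_id` and `expression` columns. One record
#' per gene (longest transcript) is assumed. Transcripts shorter than
#' `min_length_bp` are discarded so that TSSs and TESs stay unambiguous.
#'
#' @param path Path to the gene-table TSV.
#' @param genome Optional `Seqinfo` for bounds validation.
#' @param min_length_bp Minimum gene length kept (default 2000).
#' @return A stranded `GRanges` with `gene_id` and `expression`.
#' @export
read_gene_table <- function(path, genome = NULL, min_length_bp = 2000) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand", "expression")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start + 1L, tab$end),
                               strand = tab$strand,
                               gene_id = tab$gene_id,
                               expression = tab$expression)
  gr <- gr[GenomicRanges::width(gr) >= min_length_bp]
  if (!is.null(genome)) gr <- .apply_genome(gr, genome)
  gr
}

#' Write a gene table
#' @param genes Stranded `GRanges` with `gene_id` and `expression` columns.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  tab <- data.frame(gene_id = genes$gene_id,
                    chrom = as.character(GenomicRanges::seqnames(genes)),
                    start = GenomicRanges::start(genes) - 1L,
                    end = GenomicRanges::end(genes),
                    strand = as.character(GenomicRanges::strand(genes)),
                    expression = genes$expression)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Promoter regions upstream of TSSs
#'
#' Promoters are the `width_bp` (default 1 kb) immediately upstream of each
#' TSS, strand-aware.
#'
#' @param genes Stranded `GRanges`.
#' @param width_bp Promoter width in bp.
#' @return A `GRanges` of promoters, same order and metadata as `genes`.
#' @export
gene_promoters <- function(genes, width_bp = 1000) {
  GenomicRanges::trim(
    GenomicRanges::promoters(genes, upstream = width_bp, downstream = 0))
}
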