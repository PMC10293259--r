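#' Tile a genome into fixed-width windows
#'
#' Non-overlapping consecutive windows per chromosome. The final partial
#' window is kept if it is at least half the tile width (`partial = "half"`,
#' the default), always (`"all"`), or never (`"none"`). With `"all"` the
#' tiling covers each chromosome exactly, without gap or overlap.
#'
#' @param genome A `Seqinfo`.
#' @param width Tile width in bp (default 5000).
#' @param partial Final-partial-window rule.
#' @return A `GRanges` of tiles.
#' @export
tile_genome <- function(genome, width = 5000,
                        partial = c("half", "all", "none")) {
  partial <- match.arg(partial)
  stopifnot(width > 0)
  tiles <- GenomicRanges::tileGenome(GenomeInfoDb::seqlengths(genome),
                                     tilewidth = width,
                                     cut.last.tile.in.chrom = TRUE)
  GenomeInfoDb::seqinfo(tiles) <- genome
  if (partial == "all") return(tiles)
  w <- GenomicRanges::width(tiles)
  thr <- if (partial == "half") ceiling(width / 2) else width
  tiles[w >= thr]
}

#' Metaprofile matrix around anchor centers
#'
#' Per anchor, point density is binned over `[center - flank_bp,
#' center + flank_bp)` into `2 * flank_bp / bin_bp` columns. With
#' `strand_aware = TRUE`, rows of minus-strand anchors are reversed so that
#' column 1 is always the anchor's 5' side. Values are counts per bin scaled
#' to per-kb density.
#'
#' @param points Width-1 `GRanges`.
#' @param anchors Anchor `GRanges` (stranded if `strand_aware`).
#' @param flank_bp Half-window (default 1000).
#' @param bin_bp Bin width; must divide `2 * flank_bp` (default 50).
#' @param strand_aware Reverse minus-strand rows. Default `FALSE`.
#' @return Matrix (anchors x bins) with `bin_bp` and `flank_bp` attributes.
#' @export
anchored_matrix <- function(points, anchors, flank_bp = 1000, bin_bp = 50,
                            strand_aware = FALSE) {
  ncol <- (2 * flank_bp) / bin_bp
  if (ncol != round(ncol)) stop("bin_bp must divide 2 * flank_bp")
  center <- (GenomicRanges::start(anchors) + GenomicRanges::end(anchors)) %/% 2L
  w0 <- center - flank_bp
  mat <- .window_count_matrix(points, GenomicRanges::seqnames(anchors),
                              w0, 2 * flank_bp, as.integer(ncol),
                              breaks = seq(0, 2 * flank_bp, by = bin_bp))
  mat <- mat / bin_bp * 1000
  if (strand_aware) {
    neg <- as.character(GenomicRanges::strand(anchors)) == "-"
    mat[neg, ] <- mat[neg, rev(seq_len(ncol(mat))), drop = FALSE]
  }
  attr(mat, "bin_bp") <- bin_bp
  attr(mat, "flank_bp") <- flank_bp
  mat
}

# Count points into per-anchor windows starting at w0 (1-based), width win_w,
# with bin boundaries `breaks` (relative, half-open). Returns a count matrix.
.window_count_matrix <- function(points, chrom, w0, win_w, n_bins, breaks) {
  windows <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(w0, width = win_w))
  pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(points),
                                IRanges::ranges(points))
  hits <- GenomicRanges::findOverlaps(windows, pts, ignore.strand = TRUE)
  n <- length(windows)
  mat <- matrix(0, nrow = n, ncol = n_bins)
  if (length(hits)) {
    rel <- GenomicRanges::start(pts)[S4Vectors::subjectHits(hits)] -
      w0[S4Vectors::queryHits(hits)]
    col <- findInterval(rel, breaks, left.open = FALSE, rightmost.closed = FALSE)
    ok <- col >= 1 & col <= n_bins
    idx <- (S4Vectors::queryHits(hits)[ok] - 1L) * n_bins + col[ok]
    counts <- tabulate(idx, nbins = n * n_bins)
    mat <- matrix(counts, nrow = n, ncol = n_bins, byrow = TRUE)
  }
  mat
}

# Shared engine for scaled-body matrices: fixed-width flank bins plus a body
# rescaled to body_bins columns, strand-oriented so column 1 is the 5'-most
# flank bin.
.scaled_matrix <- function(points, regions, flank_bp, flank_bins, body_bins) {
  if (any(GenomicRanges::width(regions) < body_bins))
    stop("every region must be at least body_bins bp long")
  n <- length(regions)
  n_col <- 2L * flank_bins + body_bins
  pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(points),
                                IRanges::ranges(points))
  s <- GenomicRanges::start(regions)
  e <- GenomicRanges::end(regions)
  minus <- as.character(GenomicRanges::strand(regions)) == "-"
  fbw <- if (flank_bins > 0) flank_bp / flank_bins else 1
  w <- GenomicRanges::width(regions)

  mat <- matrix(0, nrow = n, ncol = n_col)

  add_hits <- function(win_start, win_w, col_of_rel) {
    win <- GenomicRanges::GRanges(GenomicRanges::seqnames(regions),
                                  IRanges::IRanges(pmax(1L, win_start),
                                                   win_start + win_w - 1L))
    hits <- GenomicRanges::findOverlaps(win, pts, ignore.strand = TRUE)
    if (!length(hits)) return()
    q <- S4Vectors::queryHits(hits)
    rel <- GenomicRanges::start(pts)[S4Vectors::subjectHits(hits)] -
      win_start[q]
    keep <- rel >= 0 & rel < win_w[q]
    q <- q[keep]; rel <- rel[keep]
    col <- col_of_rel(rel, q)
    idx <- (q - 1L) * n_col + col
    counts <- tabulate(idx, nbins = n * n_col)
    mat <<- mat + matrix(counts, nrow = n, ncol = n_col, byrow = TRUE)
  }

  if (flank_bins > 0) {
    # upstream flank (5' of the region): left of + regions, right of - ones
    up_start <- ifelse(minus, e + 1L, s - flank_bp)
    add_hits(up_start, rep(flank_bp, n), function(rel, q) {
      b <- ifelse(minus[q], (flank_bp - 1 - rel) %/% fbw, rel %/% fbw)
      as.integer(b) + 1L
    })
    dn_start <- ifelse(minus, s - flank_bp, e + 1L)
    add_hits(dn_start, rep(flank_bp, n), function(rel, q) {
      b <- ifelse(minus[q], (flank_bp - 1 - rel) %/% fbw, rel %/% fbw)
      flank_bins + body_bins + as.integer(b) + 1L
    })
  }
  # scaled body: relative position measured from the strand's 5' end so
  # minus-strand binning is the exact mirror of plus-strand binning
  add_hits(s, w, function(rel, q) {
    rel5 <- ifelse(minus[q], w[q] - 1 - rel, rel)
    b <- floor(rel5 * body_bins / w[q])
    b <- pmin(b, body_bins - 1)
    flank_bins + as.integer(b) + 1L
  })

  # per-kb density: flank bins have fixed width, body bins w/body_bins
  if (flank_bins > 0) {
    fcols <- c(seq_len(flank_bins), flank_bins + body_bins + seq_len(flank_bins))
    mat[, fcols] <- mat[, fcols] / fbw * 1000
  }
  bcols <- flank_bins + seq_len(body_bins)
  mat[, bcols] <- mat[, bcols] / (w / body_bins) * 1000
  attr(mat, "flank_bins") <- flank_bins
  attr(mat, "body_bins") <- body_bins
  attr(mat, "flank_bp") <- flank_bp
  mat
}

#' Scaled-gene metaprofile matrix
#'
#' Each gene is extended `flank_bp` (default 5 kb) upstream of the TSS and
#' downstream of the TES; each flank is divided into `flank_bins` fixed-width
#' segments (default 10 x 500 bp) and the gene body into `body_bins`
#' length-scaled segments (default 100), giving 120 columns. Rows are
#' strand-oriented: column 1 is the 5'-most upstream bin.
#'
#' @param points Width-1 `GRanges`.
#' @param genes Stranded `GRanges`, each at least `body_bins` bp long.
#' @param flank_bp,flank_bins,body_bins Layout parameters.
#' @return Matrix (genes x `2 * flank_bins + body_bins`), per-kb density.
#' @export
scaled_gene_matrix <- function(points, genes, flank_bp = 5000,
                               flank_bins = 10, body_bins = 100) {
  .scaled_matrix(points, genes, flank_bp, flank_bins, body_bins)
}

#' Bin regions by a covariate into equal-count quantile bins
#'
#' Regions are optionally pre-filtered (`filter >= filter_min`, e.g. dropping
#' low-MNase-coverage regions), ranked by the covariate, and split into
#' `n_bins` equal-count bins; when the count does not divide evenly the
#' remainder is spread one-per-bin over the leading bins (10 regions in 3
#' bins gives sizes 4, 3, 3). Ties keep their original order.
#'
#' @param covariate Per-region ranking value.
#' @param n_bins Number of bins.
#' @param values Optional data frame of per-region columns to average per bin.
#' @param filter,filter_min Optional per-region filter value and threshold.
#' @param decreasing Rank descending instead of ascending. Default `FALSE`.
#' @return List with `assignment` (bin index per region, `NA` when filtered
#'   out) and `summary` (per-bin `n`, `mean_covariate`, and a `mean_` column
#'   per value column).
#' @export
bin_by_covariate <- function(covariate, n_bins, values = NULL,
                             filter = NULL, filter_min = NULL,
                             decreasing = FALSE) {
  n_all <- length(covariate)
  keep <- rep(TRUE, n_all)
  if (!is.null(filter)) {
    stopifnot(!is.null(filter_min), length(filter) == n_all)
    keep <- filter >= filter_min
  }
  idx <- which(keep)
  n <- length(idx)
  stopifnot(n_bins >= 1, n_bins <= n)
  ord <- idx[order(covariate[idx], decreasing = decreasing, method = "radix")]
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bin_sorted <- rep.int(seq_len(n_bins), sizes)
  assignment <- rep(NA_integer_, n_all)
  assignment[ord] <- bin_sorted
  summary <- data.frame(bin = seq_len(n_bins), n = sizes)
  summary$mean_covariate <- as.numeric(
    tapply(covariate[ord], bin_sorted, mean))
  if (!is.null(values)) {
    values <- as.data.frame(values)
    for (cn in names(values))
      summary[[paste0("mean_", cn)]] <-
        as.numeric(tapply(values[[cn]][ord], bin_sorted, mean))
  }
  list(assignment = assignment, summary = summary)
}

#' Smooth a trend with LOESS
#'
#' Locally weighted regression (span 0.5, degree 2) used for display
#' trendlines; quantitative statistics elsewhere use exact binned means.
#'
#' @param x,y Numeric vectors (at least 10 points).
#' @param span LOESS span (default 0.5).
#' @return Fitted trend at the input `x`, in input order.
#' @export
smooth_trend <- function(x, y, span = 0.5) {
  stopifnot(length(x) >= 10, length(x) == length(y))
  fit <- stats::loess(y ~ x, span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, newdata = data.frame(x = x)))
}

#' Select the top fraction of regions by a score
#'
#' Keeps the highest `ceiling(fraction * n)` regions; ties are broken by
#' original order (stable sort).
#'
#' @param regions A `GRanges` (or any subsettable object).
#' @param score Per-region score.
#' @param fraction Fraction in `(0, 1]`.
#' @return The selected subset, in original order.
#' @export
top_fraction <- function(regions, score, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(score)
  k <- ceiling(fraction * n)
  sel <- order(score, decreasing = TRUE, method = "radix")[seq_len(k)]
  regions[sort(sel)]
}

#' Select heterochromatin proxy regions
#'
#' Filters peaks to a length window (inclusive; default 150-2000 bp) and then
#' keeps the `top_n` by read density (e.g. MNase coverage), so only
#' well-covered constitutive-heterochromatin peaks are analyzed.
#'
#' @param peaks Peak `GRanges`.
#' @param density Per-peak read density.
#' @param len_min,len_max Inclusive length bounds.
#' @param top_n Number of densest peaks kept (default 2000).
#' @return The selected `GRanges`, in original order.
#' @export
select_heterochromatin_regions <- function(peaks, density, len_min = 150,
                                           len_max = 2000, top_n = 2000) {
  w <- GenomicRanges::width(peaks)
  ok <- w >= len_min & w <= len_max
  peaks <- peaks[ok]
  density <- density[ok]
  if (length(peaks) == 0) return(peaks)
  k <- min(top_n, length(peaks))
  sel <- order(density, decreasing = TRUE, method = "radix")[seq_len(k)]
  peaks[sort(sel)]
}
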