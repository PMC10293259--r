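test_that("genome tiling follows the partial-window rule", {
  g10 <- tiny_genome(c(chr1 = 10000))
  expect_length(tile_genome(g10, 5000), 2)
  # 12.6 kb: the 2.6 kb tail is >= half of 5 kb, so kept
  g126 <- tiny_genome(c(chr1 = 12600))
  t3 <- tile_genome(g126, 5000, partial = "half")
  expect_length(t3, 3)
  expect_equal(width(t3)[3], 2600)
  expect_length(tile_genome(g126, 5000, partial = "none"), 2)
  # with partials kept the tiling partitions the chromosome exactly
  g2 <- tiny_genome(c(chr1 = 12600, chr2 = 7100))
  all_t <- tile_genome(g2, 5000, partial = "all")
  expect_equal(sum(width(all_t)), 12600 + 7100)
  expect_true(all(width(GenomicRanges::reduce(all_t)) ==
                    c(12600, 7100)))
})

test_that("anchored matrices have the right shape and strand involution", {
  g <- tiny_genome(c(chr1 = 1e5))
  pts <- random_points(5000, g, seed = 41)
  anchors <- GRanges("chr1", IRanges(seq(5000, 90000, by = 5000), width = 1),
                     strand = "+", seqinfo = g)
  m <- anchored_matrix(pts, anchors, flank_bp = 1000, bin_bp = 50)
  expect_equal(dim(m), c(length(anchors), 40))
  # strand-aware on all-minus anchors equals the column-reversed matrix
  neg <- anchors
  strand(neg) <- "-"
  m_neg <- anchored_matrix(pts, neg, flank_bp = 1000, bin_bp = 50,
                           strand_aware = TRUE)
  expect_equal(m_neg, m[, 40:1],
               ignore_attr = TRUE)
  # involution: reversing twice restores the original
  m_again <- anchored_matrix(pts, anchors, flank_bp = 1000, bin_bp = 50,
                             strand_aware = TRUE)
  expect_equal(m_again, m, ignore_attr = TRUE)
  expect_error(anchored_matrix(pts, anchors, flank_bp = 1000, bin_bp = 33))
})

test_that("symmetric deposition yields a mirror-symmetric metaprofile", {
  g <- tiny_genome(c(chr1 = 2e6))
  set.seed(42)
  centers <- seq(20000, 1980000, by = 20000)
  # symmetric signal: points at center +- Normal(0, 200)
  off <- round(rnorm(40000, 0, 200))
  pos <- sample(centers, 40000, replace = TRUE) + off
  pts <- GRanges("chr1", IRanges(pos, width = 1), seqinfo = g)
  anchors <- GRanges("chr1", IRanges(centers, width = 1), seqinfo = g)
  prof <- colMeans(anchored_matrix(pts, anchors, flank_bp = 1000,
                                   bin_bp = 100))
  expect_gt(cor(prof, rev(prof)), 0.98)
})

test_that("scaled-gene matrix is 120 columns and mirror-consistent", {
  g <- tiny_genome(c(chr1 = 1e6))
  pts <- random_points(30000, g, seed = 43)
  genes <- GRanges("chr1", IRanges(c(100000, 300000, 500000),
                                   width = c(20000, 8000, 3000)),
                   strand = c("+", "-", "+"), seqinfo = g)
  m <- scaled_gene_matrix(pts, genes)
  expect_equal(ncol(m), 120)
  expect_equal(nrow(m), 3)
  # a minus-strand gene equals the plus-strand computation on the mirrored
  # point layout
  gene_m <- GRanges("chr1", IRanges(300000, width = 8000), strand = "-",
                    seqinfo = g)
  gene_p <- GRanges("chr1", IRanges(300000, width = 8000), strand = "+",
                    seqinfo = g)
  L <- 1e6 + 1  # mirror position p -> L - p
  mirrored <- GRanges("chr1", IRanges(L - start(pts), width = 1), seqinfo = g)
  gene_p_mirror <- GRanges("chr1",
                           IRanges(L - end(gene_m), L - start(gene_m)),
                           strand = "+", seqinfo = g)
  m_minus <- scaled_gene_matrix(pts, gene_m)
  m_mirror <- scaled_gene_matrix(mirrored, gene_p_mirror)
  expect_equal(m_minus, m_mirror, ignore_attr = TRUE)
  # uniform coverage: flat rows within noise
  dense <- random_points(2e5, g, seed = 44)
  flat <- scaled_gene_matrix(dense, genes[1])
  expect_lt(sd(flat[1, ]) / mean(flat[1, ]), 0.25)
  expect_error(scaled_gene_matrix(pts, GRanges("chr1", IRanges(1, 50),
                                               seqinfo = g)))
})

test_that("covariate binning is equal-count with the leading-remainder rule", {
  b <- bin_by_covariate(runif(100), 4)
  expect_equal(b$summary$n, rep(25, 4))
  set.seed(45)
  x <- rnorm(10)
  b3 <- bin_by_covariate(x, 3)
  expect_equal(b3$summary$n, c(4, 3, 3))
  expect_equal(sum(b3$summary$n), 10)
  # bin means non-decreasing in the covariate
  expect_true(all(diff(b3$summary$mean_covariate) >= 0))
  # assignment is a partition of the kept regions
  expect_equal(sort(table(b3$assignment)), sort(c(`1` = 4, `2` = 3, `3` = 3)),
               ignore_attr = TRUE)
  # filtering drops regions before binning and keeps sizes consistent
  filt <- bin_by_covariate(x, 3, filter = seq_along(x), filter_min = 3)
  expect_equal(sum(filt$summary$n), 8)
  expect_equal(sum(is.na(filt$assignment)), 2)
  # per-bin means of attached values
  v <- data.frame(y = x * 2)
  bv <- bin_by_covariate(x, 2, values = v)
  expect_equal(bv$summary$mean_y,
               as.numeric(tapply(v$y[order(x)], rep(1:2, each = 5), mean)))
})

test_that("LOESS trend is exact on clean input and tracks noisy slopes", {
  x <- seq_len(50)
  expect_lt(max(abs(smooth_trend(x, x) - x)), 1e-6)
  expect_lt(max(abs(smooth_trend(x, rep(2, 50)) - 2)), 1e-9)
  set.seed(46)
  n <- 200
  xn <- runif(n, 0, 10)
  yn <- 3 * xn + rnorm(n, 0, 1)
  tr <- smooth_trend(xn, yn)
  slope <- coef(lm(tr ~ xn))[2]
  expect_lt(abs(slope - 3) / 3, 0.1)
  expect_error(smooth_trend(1:5, 1:5))
})

test_that("top-fraction selection matches sort-and-slice with stable ties", {
  r <- GRanges("chr1", IRanges(seq(1, by = 100, length.out = 200), width = 50))
  sc <- rep(c(5, 3, 5, 1), 50)
  expect_length(top_fraction(r, sc, 1), 200)
  expect_length(top_fraction(r, sc, 0.01), 2)
  got <- top_fraction(r, sc, 0.25)
  ord <- order(sc, decreasing = TRUE)          # stable for ties
  oracle <- sort(ord[1:50])
  expect_equal(start(got), start(r)[oracle])
  # ties broken by original order: first tied 5s selected first
  first_two <- top_fraction(r, sc, 2 / 200)
  expect_equal(start(first_two), start(r)[c(1, 3)])
})

test_that("heterochromatin peak selection applies inclusive length bounds", {
  w <- c(100, 150, 149, 500, 2000, 2001, 1000)
  peaks <- GRanges("chr1", IRanges(seq(1, by = 5000, length.out = 7),
                                   width = w))
  dens <- c(9, 1, 9, 5, 3, 9, 4)
  sel <- select_heterochromatin_regions(peaks, dens, top_n = 2000)
  expect_equal(width(sel), c(150, 500, 2000, 1000))  # 100,149,2001 excluded
  top2 <- select_heterochromatin_regions(peaks, dens, top_n = 2)
  expect_equal(sort(width(top2)), c(500, 1000))      # densest eligible two
  none <- select_heterochromatin_regions(
    GRanges("chr1", IRanges(1, 100)), 1)
  expect_length(none, 0)
})
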