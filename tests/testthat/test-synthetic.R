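test_that("steady-state uncleaved fraction matches the closed form and a race oracle", {
  expect_equal(steady_state_uncleaved(2, 2), 0.5)
  expect_equal(steady_state_uncleaved(7, 0), 1)
  expect_equal(steady_state_uncleaved(3, 1), 0.75)
  # independent oracle: simulate the eviction-vs-cleavage exponential race
  set.seed(101)
  n <- 1e5
  race <- mean(rexp(n, 3) < rexp(n, 1))
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(race - steady_state_uncleaved(3, 1)), 3 * se)
  # monotonicity
  lam <- c(0.1, 0.5, 1, 5, 20)
  expect_true(all(diff(steady_state_uncleaved(lam, 1)) > 0))
  expect_true(all(diff(steady_state_uncleaved(1, lam)) < 0))
  expect_error(steady_state_uncleaved(0, 1))
  expect_error(steady_state_uncleaved(1, -1))
})

test_that("genome fixture is deterministic, counted and base-partitioning", {
  fix1 <- build_genome_fixture(n_genes = 40, n_ctcf = 30, n_repeats = 15,
                               n_enhancers = 20, n_hetero = 3,
                               chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                               seed = 5)
  fix2 <- build_genome_fixture(n_genes = 40, n_ctcf = 30, n_repeats = 15,
                               n_enhancers = 20, n_hetero = 3,
                               chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                               seed = 5)
  expect_identical(fix1$loci, fix2$loci)
  expect_identical(fix1$genes, fix2$genes)
  expect_length(fix1$genes, 40)
  expect_length(fix1$ctcf, 30)
  # CTCF motifs half + and half -
  expect_equal(sum(strand(fix1$ctcf) == "+"), 15)
  # every base covered by exactly one locus
  cov <- GenomicRanges::coverage(fix1$loci)
  expect_true(all(vapply(cov, function(v)
    all(S4Vectors::runValue(v) == 1L), logical(1))))
  # no-repeat request leaves the rest intact
  fix0 <- build_genome_fixture(n_genes = 40, n_ctcf = 30, n_repeats = 0,
                               n_enhancers = 20, n_hetero = 3,
                               chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                               seed = 5)
  expect_length(fix0$repeats, 0)
  expect_length(fix0$genes, 40)
})

test_that("fixture round-trips through its on-disk form", {
  fix <- build_genome_fixture(n_genes = 20, n_ctcf = 10, n_repeats = 5,
                              n_enhancers = 10, n_hetero = 2,
                              chrom_lengths = c(chr1 = 2e6), seed = 2)
  dir <- withr::local_tempdir()
  write_fixture(fix, dir)
  g <- read_chrom_sizes(file.path(dir, "genome.chrom.sizes"))
  expect_equal(GenomeInfoDb::seqlengths(g), GenomeInfoDb::seqlengths(fix$genome))
  genes <- read_gene_table(file.path(dir, "genes.tsv"), g)
  expect_equal(length(genes), length(fix$genes))
  expect_equal(start(genes), start(fix$genes))
  truth <- read.table(file.path(dir, "locus_truth.tsv"), header = TRUE,
                      sep = "\t")
  expect_equal(nrow(truth), length(fix$loci))
  expect_equal(sum(truth$class == "gene_body"), length(fix$genes))
})

test_that("simulated channels are deterministic and kinetically ordered", {
  u <- uniform_loci(2, width = 5000, gap = 5000, occupancy = 0.5,
                    lambda = c(10, 1))
  ch1 <- simulate_channels(u, depth = 2e4, kappa = 1, seed = 3)
  ch2 <- simulate_channels(u, depth = 2e4, kappa = 1, seed = 3)
  expect_identical(ch1$myc, ch2$myc)
  expect_identical(ch1$HA, ch2$HA)
  # lambda_A = 10 * lambda_B at equal occupancy: myc/HA ratio larger at A
  m <- count_in_regions(shift_five_prime(ch1$myc), u$loci)
  h <- count_in_regions(shift_five_prime(ch1$HA), u$loci)
  expect_gt(m[1] / h[1], m[2] / h[2])
})

test_that("per-locus count ratios converge to the uncleaved fraction", {
  # estimator consistency at high depth: ratio -> f within 3 MC SE
  n <- 50
  u <- uniform_loci(n, width = 1000, gap = 1000, occupancy = 0.5,
                    lambda = rep(c(0.25, 1, 4, 9, 19), each = 10))
  kappa <- 1
  depth <- n * 400
  cc <- simulate_region_counts(u, depth = depth, kappa = kappa, seed = 9)[[1]]
  f_true <- steady_state_uncleaved(u$loci$lambda, kappa)
  # myc channel is depth-matched to HA, so the ratio estimates f / mean(f)
  scale <- sum(u$loci$occupancy * GenomicRanges::width(u$loci) * f_true) /
    sum(u$loci$occupancy * GenomicRanges::width(u$loci))
  est <- cc$myc / pmax(cc$ha, 1) * scale
  se <- sqrt(f_true^2 * (1 / pmax(cc$myc, 1) + 1 / pmax(cc$ha, 1)))
  expect_true(mean(abs(est - f_true) < 3 * pmax(se, 1e-3)) > 0.95)
})

test_that("non-cleavable control centers exchange at zero", {
  u <- uniform_loci(200, width = 1000, gap = 1000, occupancy = 0.5,
                    lambda = exp(seq(log(0.05), log(20), length.out = 200)))
  cc <- simulate_region_counts(u, depth = 200 * 200, kappa = 0, seed = 4)[[1]]
  e <- exchange_score(cc$myc, cc$ha)
  expect_lt(abs(mean(e)), 0.05)
})

test_that("optional channels behave: input tracks width, ATAC has short fragments", {
  fix <- build_genome_fixture(n_genes = 30, n_ctcf = 10, n_repeats = 5,
                              n_enhancers = 20, n_hetero = 2,
                              chrom_lengths = c(chr1 = 2e6), seed = 8)
  ch <- simulate_channels(fix, depth = 5e4,
                          channels = c("input", "mark", "ATAC"), seed = 8)
  expect_named(ch, c("input", "mark", "ATAC"))
  # ATAC: sub-120 bp component present, and concentrated at open classes
  w <- width(ch$ATAC)
  expect_gt(mean(w < 120), 0.1)
  open <- fix$loci[fix$loci$class %in%
                     c("promoter", "enhancer_active", "enhancer_primed")]
  dens_open <- sum(countOverlaps(open, ch$ATAC)) / sum(width(open))
  closed <- fix$loci[fix$loci$class == "background"]
  dens_closed <- sum(countOverlaps(closed, ch$ATAC)) / sum(width(closed))
  expect_gt(dens_open, dens_closed * 2)
  # mark channel enriched at its weighted classes
  enh <- fix$loci[fix$loci$class == "enhancer_active"]
  dens_enh <- sum(countOverlaps(enh, ch$mark)) / sum(width(enh))
  dens_bg <- sum(countOverlaps(closed, ch$mark)) / sum(width(closed))
  expect_gt(dens_enh, dens_bg * 2)
})
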