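# Shared in-code fixtures: tiny genomes, fragment builders, and a SAM writer
# so BAM import can be tested from plain text.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

tiny_genome <- function(lengths = c(chr1 = 1e6, chr2 = 1e6)) {
  exchseq::make_genome(names(lengths), lengths)
}

# Build a fragment GRanges from BED-style (0-based half-open) coordinates.
frags_bed0 <- function(chrom, start0, end0, strand = "+", mapq = 60,
                       genome = NULL) {
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand,
                mapq = as.integer(rep_len(mapq, length(start0))))
  if (!is.null(genome)) GenomeInfoDb::seqinfo(gr) <- genome
  gr
}

# Write a minimal paired-end SAM file: one template per row of `templates`
# (chrom, start0, end0, mapq). Both mates get the template's MAPQ, proper-pair
# flags, and a full-match CIGAR of read_len.
write_test_sam <- function(path, templates, chrom_lengths = c(chr1 = 1e6),
                           read_len = 50) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)))
  seq1 <- paste(rep("A", read_len), collapse = "")
  for (i in seq_len(nrow(templates))) {
    t <- templates[i, ]
    pos1 <- t$start0 + 1L                     # SAM is 1-based
    pos2 <- t$end0 - read_len + 1L
    tlen <- t$end0 - t$start0
    qn <- sprintf("tmpl%03d", i)
    lines <- c(lines,
      sprintf("%s\t99\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t*", qn, t$chrom,
              pos1, t$mapq, read_len, pos2, tlen, seq1),
      sprintf("%s\t147\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t*", qn, t$chrom,
              pos2, t$mapq, read_len, pos1, -tlen, seq1))
  }
  writeLines(lines, path)
  path
}

# Uniformly scattered width-1 points on a genome (seeded).
random_points <- function(n, genome, seed = 1) {
  lens <- GenomeInfoDb::seqlengths(genome)
  set.seed(seed)
  chr <- sample(names(lens), n, replace = TRUE, prob = as.numeric(lens))
  pos <- floor(runif(n, 1, lens[chr]))
  GRanges(chr, IRanges(pos, width = 1),
          strand = sample(c("+", "-"), n, TRUE), seqinfo = genome)
}

# Small locus model for estimator tests: equal-width loci on one chromosome.
uniform_loci <- function(n, width = 1000, gap = 1000, occupancy = 0.5,
                         lambda = 1) {
  step <- width + gap
  len <- n * step + gap
  genome <- exchseq::make_genome("chrS", len)
  gr <- GRanges("chrS", IRanges(start = seq(gap + 1, by = step,
                                            length.out = n), width = width),
                seqinfo = genome)
  list(genome = genome,
       loci = exchseq::locus_model(gr, rep_len(occupancy, n),
                                   rep_len(lambda, n)))
}

# Count-level KO simulation used by the power/calibration tests: loci with an
# H3.3-tied target set and a matched reference set at open chromatin, plus a
# heterochromatin pair that the knockout never touches. Depth gives ~200
# fragments per region per replicate.
ko_fixture <- function() {
  n_each <- 100
  lam <- c(rep(4, n_each), rep(4, n_each), rep(0.3, n_each), rep(0.3, n_each))
  u <- uniform_loci(4 * n_each, width = 1000, gap = 1000, occupancy = 0.6,
                    lambda = lam)
  list(fix = u,
       idx = list(enh_target = 1:n_each,
                  enh_ref = (n_each + 1):(2 * n_each),
                  het_target = (2 * n_each + 1):(3 * n_each),
                  het_ref = (3 * n_each + 1):(4 * n_each)))
}

# One WT-vs-KO comparison (2 replicates each); reports WT minus KO.
ko_run <- function(kf, ko_scale, seed, depth = 400 * 200) {
  n <- length(kf$fix$loci)
  scale_vec <- rep(1, n)
  scale_vec[kf$idx$enh_target] <- ko_scale
  wt <- exchseq::simulate_region_counts(kf$fix, depth = depth,
                                        n_replicates = 2, seed = seed)
  ko <- exchseq::simulate_region_counts(kf$fix, depth = depth,
                                        n_replicates = 2,
                                        lambda_scale = scale_vec,
                                        seed = seed + 50000)
  tracks <- function(reps) lapply(reps, function(cc)
    data.frame(ha = cc$ha, exchange = exchseq::exchange_score(cc$myc, cc$ha)))
  contrasts <- list(
    enhancer = list(target = kf$idx$enh_target, reference = kf$idx$enh_ref),
    heterochromatin = list(target = kf$idx$het_target,
                           reference = kf$idx$het_ref))
  exchseq::ko_effect_pipeline(tracks(wt), tracks(ko), contrasts,
                              statistics = "exchange")
}
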