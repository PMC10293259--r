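# Seeded evaluation that never leaks RNG state into the caller's session.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Steady-state uncleaved (myc-retaining) fraction
#'
#' Minimal kinetic model of the dual-tag sensor: a chromatin-bound sensor
#' histone leaves its locus after an exponential residence time (eviction rate
#' `lambda`) while a first-order TEV cleavage (rate `kappa`) removes its myc
#' tag during residence. The probability that eviction wins the race — i.e.
#' the steady-state fraction of myc-retaining (recently exchanged) sensor at
#' the locus — is `lambda / (lambda + kappa)`. Strictly increasing in
#' `lambda`, decreasing in `kappa`; `kappa = 0` (non-cleavable control) gives
#' 1, so myc and HA coincide in expectation.
#'
#' @param lambda Eviction (exchange) rate, > 0. Vectorized.
#' @param kappa Cleavage rate, >= 0.
#' @return Fraction in `[0, 1]`.
#' @export
steady_state_uncleaved <- function(lambda, kappa) {
  stopifnot(all(lambda > 0), all(kappa >= 0))
  lambda / (lambda + kappa)
}

#' Construct a locus model
#'
#' @param intervals `GRanges` of loci.
#' @param occupancy Expected tagged-nucleosome density per locus, in `(0, 1]`.
#' @param lambda Exchange rate per locus, > 0.
#' @param class Class label per locus.
#' @return `GRanges` with `occupancy`, `lambda`, `class` columns.
#' @export
locus_model <- function(intervals, occupancy, lambda, class = "background") {
  stopifnot(all(occupancy > 0), all(occupancy <= 1), all(lambda > 0))
  S4Vectors::mcols(intervals)$occupancy <- occupancy
  S4Vectors::mcols(intervals)$lambda <- lambda
  S4Vectors::mcols(intervals)$class <-
    rep_len(as.character(class), length(intervals))
  intervals
}

# Per-class simulator defaults: typical occupancy and exchange rate (on the
# kappa = 1 scale) with log-normal within-class spread. Promoters and active
# enhancers turn over fast; heterochromatin is occupied but nearly static.
.class_params <- function() {
  data.frame(
    class = c("promoter", "gene_body", "enhancer_active", "enhancer_primed",
              "enhancer_poised", "ctcf_flank", "repeat", "heterochromatin",
              "background"),
    occupancy = c(0.65, 0.55, 0.50, 0.50, 0.50, 0.60, 0.75, 0.90, 0.35),
    lambda = c(6, 1.2, 5, 2, 1, 4, 0.8, 0.3, 0.7),
    stringsAsFactors = FALSE)
}

# Greedy non-overlapping placement of n intervals of the given widths on a
# genome, at least margin bp from chromosome ends and from already-claimed
# space. Deterministic given the RNG state. Overlap checks run on plain
# vectors; the claimed set includes the margin padding.
.place_intervals <- function(genome, widths, claimed, margin = 5100,
                             max_tries = 200L) {
  lens <- GenomeInfoDb::seqlengths(genome)
  chroms <- GenomeInfoDb::seqnames(genome)
  cl_chr <- as.character(GenomicRanges::seqnames(claimed))
  cl_start <- GenomicRanges::start(claimed)
  cl_end <- GenomicRanges::end(claimed)
  out_chr <- character(0); out_start <- integer(0); out_end <- integer(0)
  n_failed <- 0L
  for (w in widths) {
    done <- FALSE
    for (try in seq_len(max_tries)) {
      chr <- sample(chroms, 1, prob = as.numeric(lens))
      lo <- margin + 1
      hi <- lens[[chr]] - margin - w
      if (hi <= lo) next
      s <- floor(runif(1, lo, hi))
      e <- s + w - 1L
      ps <- s - margin; pe <- e + margin
      same <- cl_chr == chr
      if (any(same & cl_start <= pe & cl_end >= ps)) next
      cl_chr <- c(cl_chr, chr)
      cl_start <- c(cl_start, ps)
      cl_end <- c(cl_end, pe)
      out_chr <- c(out_chr, chr)
      out_start <- c(out_start, as.integer(s))
      out_end <- c(out_end, as.integer(e))
      done <- TRUE
      break
    }
    if (!done) n_failed <- n_failed + 1L
  }
  if (n_failed > 0L)
    warning(n_failed, " interval(s) could not be placed without collision; ",
            "fixture is sparser than requested")
  if (length(out_chr) == 0)
    return(GenomicRanges::GRanges(seqinfo = genome))
  GenomicRanges::GRanges(out_chr, IRanges::IRanges(out_start, out_end),
                         seqinfo = genome)
}

#' Build a labeled synthetic genome fixture
#'
#' Generates a small genome with non-overlapping annotations — genes with
#' log-normal expression, stranded CTCF motifs, repeat insertions from a few
#' families, enhancers of three classes and heterochromatin blocks — and a
#' locus model tiling every base exactly once (annotation loci plus 5 kb
#' background tiles in the gaps). Exchange rates and occupancies are drawn
#' per class around the defaults in the package's class table, with log-normal
#' within-class spread; gene-body rates additionally scale with expression so
#' that expressed genes turn over faster. Deterministic given `seed`.
#'
#' @param n_genes,n_ctcf,n_repeats,n_enhancers,n_hetero Annotation counts.
#' @param chrom_lengths Named or unnamed vector of chromosome lengths
#'   (default two 5 Mb chromosomes).
#' @param lambda_spread_sdlog Within-class log-normal spread of exchange rates.
#' @param occupancy_spread_sdlog Within-class spread of occupancy (clipped to 1).
#' @param ctcf_asym_log2 Optional orientation-dependent exchange asymmetry at
#'   CTCF flanks: the motif-downstream flank gets `+ctcf_asym_log2/2` log2
#'   units of lambda, the upstream flank `-ctcf_asym_log2/2`. Default 0
#'   (orientation-independent null).
#' @param repeat_families Family labels sampled for repeat insertions.
#' @param seed Integer seed.
#' @return A list of class `synthetic_genome`: `genome` (`Seqinfo`), `genes`,
#'   `ctcf`, `repeats`, `enhancers`, `heterochromatin` (`GRanges`), and
#'   `loci` (the locus model `GRanges` with `occupancy`, `lambda`, `class`).
#' @export
build_genome_fixture <- function(n_genes = 300, n_ctcf = 200, n_repeats = 100,
                                 n_enhancers = 150, n_hetero = 20,
                                 chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                                 lambda_spread_sdlog = 0.4,
                                 occupancy_spread_sdlog = 0.4,
                                 ctcf_asym_log2 = 0,
                                 repeat_families = c("IAP", "L1", "MERVL",
                                                     "B1", "MTA"),
                                 seed = 1) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  genome <- make_genome(names(chrom_lengths), chrom_lengths)
  .with_seed(seed, {
    claimed <- GenomicRanges::GRanges(seqinfo = genome)

    # largest features claim space first so high packing still succeeds
    het <- .place_intervals(genome, rep(50000L, n_hetero), claimed,
                            margin = 600)
    claimed <- c(claimed, GenomicRanges::granges(het))

    gene_w <- pmin(pmax(round(rlnorm(n_genes, log(5000), 0.6)), 2000), 30000)
    genes <- .place_intervals(genome, gene_w, claimed)
    if (length(genes)) {
      GenomicRanges::strand(genes) <- sample(c("+", "-"), length(genes), TRUE)
      genes$gene_id <- sprintf("gene%04d", seq_along(genes))
      genes$expression <- rlnorm(length(genes), meanlog = 2, sdlog = 1.5)
    }
    claimed <- c(claimed, GenomicRanges::granges(genes))

    rep_w <- pmin(pmax(round(rlnorm(n_repeats, log(3000), 0.7)), 500), 8000)
    repeats <- .place_intervals(genome, rep_w, claimed, margin = 1100)
    if (length(repeats)) {
      GenomicRanges::strand(repeats) <- sample(c("+", "-"), length(repeats), TRUE)
      repeats$family <- sample(repeat_families, length(repeats), TRUE)
    }
    claimed <- c(claimed, GenomicRanges::granges(repeats))

    ctcf <- .place_intervals(genome, rep(19L, n_ctcf), claimed, margin = 1500)
    if (length(ctcf)) {
      GenomicRanges::strand(ctcf) <-
        rep(c("+", "-"), length.out = length(ctcf))[sample(length(ctcf))]
      ctcf$name <- sprintf("ctcf%04d", seq_along(ctcf))
    }
    claimed <- c(claimed, GenomicRanges::granges(ctcf))

    enh_w <- rep(1000L, n_enhancers)
    enhancers <- .place_intervals(genome, enh_w, claimed, margin = 1100)
    if (length(enhancers))
      enhancers$class <- sample(c("enhancer_active", "enhancer_primed",
                                  "enhancer_poised"),
                                length(enhancers), TRUE,
                                prob = c(0.45, 0.35, 0.20))
    claimed <- c(claimed, GenomicRanges::granges(enhancers))

    loci <- .build_loci(genome, genes, ctcf, enhancers, repeats, het,
                        lambda_spread_sdlog, occupancy_spread_sdlog,
                        ctcf_asym_log2)
    structure(list(genome = genome, genes = genes, ctcf = ctcf,
                   repeats = repeats, enhancers = enhancers,
                   heterochromatin = het, loci = loci,
                   params = list(seed = seed,
                                 lambda_spread_sdlog = lambda_spread_sdlog,
                                 occupancy_spread_sdlog = occupancy_spread_sdlog,
                                 ctcf_asym_log2 = ctcf_asym_log2)),
              class = "synthetic_genome")
  })
}

# Assemble the base-covering locus model from the annotation sets. Genes
# contribute a promoter locus (1 kb upstream) and a gene-body locus; CTCF
# motifs contribute two 360 bp flank loci (strand-oriented upstream /
# downstream so orientation-dependent asymmetry can be encoded); gaps become
# 5 kb background tiles.
.build_loci <- function(genome, genes, ctcf, enhancers, repeats, het,
                        lam_sd, occ_sd, ctcf_asym_log2) {
  pars <- .class_params()
  p <- function(cl) pars[pars$class == cl, ]
  draw <- function(gr, cl, lambda_base = NULL) {
    if (length(gr) == 0)
      return(GenomicRanges::GRanges(seqinfo = genome))
    base <- p(cl)
    lam <- if (is.null(lambda_base)) rep(base$lambda, length(gr)) else lambda_base
    locus_model(GenomicRanges::granges(gr),
                occupancy = pmin(1, base$occupancy *
                                   rlnorm(length(gr), 0, occ_sd)),
                lambda = lam * rlnorm(length(gr), 0, lam_sd),
                class = cl)
  }

  prom_loci <- draw(gene_promoters(genes, 1000), "promoter")
  # gene-body lambda scales with expression: expressed genes exchange faster
  gb_lambda <- if (length(genes))
    p("gene_body")$lambda * (0.3 + 0.35 * log1p(genes$expression))
  else NULL
  body_loci <- draw(genes, "gene_body", lambda_base = gb_lambda)

  enh_loci <- GenomicRanges::GRanges(seqinfo = genome)
  if (length(enhancers)) {
    enh_loci <- do.call(c, unname(lapply(split(enhancers, enhancers$class),
                                         function(g) draw(g, unique(g$class)))))
  }

  ctcf_loci <- GenomicRanges::GRanges(seqinfo = genome)
  if (length(ctcf)) {
    mid <- (GenomicRanges::start(ctcf) + GenomicRanges::end(ctcf)) %/% 2L
    minus <- as.character(GenomicRanges::strand(ctcf)) == "-"
    left <- GenomicRanges::GRanges(GenomicRanges::seqnames(ctcf),
                                   IRanges::IRanges(mid - 360L, mid - 1L),
                                   seqinfo = genome)
    right <- GenomicRanges::GRanges(GenomicRanges::seqnames(ctcf),
                                    IRanges::IRanges(mid, mid + 359L),
                                    seqinfo = genome)
    # motif-downstream flank: right of a + motif, left of a - motif
    down <- c(right[!minus], left[minus])
    up <- c(left[!minus], right[minus])
    base <- .class_params()[.class_params()$class == "ctcf_flank", ]
    mk <- function(gr, sign) {
      locus_model(gr,
                  occupancy = pmin(1, base$occupancy *
                                     rlnorm(length(gr), 0, occ_sd)),
                  lambda = base$lambda * 2^(sign * ctcf_asym_log2 / 2) *
                    rlnorm(length(gr), 0, lam_sd),
                  class = "ctcf_flank")
    }
    ctcf_loci <- c(mk(down, +1), mk(up, -1))
  }

  rep_loci <- draw(repeats, "repeat")
  het_loci <- draw(het, "heterochromatin")

  annotated <- c(prom_loci, body_loci, enh_loci, ctcf_loci, rep_loci, het_loci)
  gaps <- GenomicRanges::gaps(GenomicRanges::reduce(
    GenomicRanges::granges(annotated), ignore.strand = TRUE))
  gaps <- gaps[as.character(GenomicRanges::strand(gaps)) == "*"]
  bg_loci <- draw(.split_exact(gaps, 5000), "background")

  out <- c(annotated, bg_loci)
  GenomicRanges::strand(out) <- "*"
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

# Exact integer partition of each range into ~width tiles (no base lost or
# duplicated; boundaries at floor(W * i / n)).
.split_exact <- function(gr, width) {
  n_tiles <- pmax(1L, as.integer(round(GenomicRanges::width(gr) / width)))
  chr <- rep(as.character(GenomicRanges::seqnames(gr)), n_tiles)
  starts <- integer(0); ends <- integer(0)
  W <- GenomicRanges::width(gr)
  s0 <- GenomicRanges::start(gr)
  for (i in seq_along(gr)) {
    b <- floor(W[i] * (0:n_tiles[i]) / n_tiles[i])
    starts <- c(starts, s0[i] + b[-length(b)])
    ends <- c(ends, s0[i] + b[-1] - 1L)
  }
  GenomicRanges::GRanges(chr, IRanges::IRanges(starts, ends),
                         seqinfo = GenomeInfoDb::seqinfo(gr))
}

#' Expected per-locus fragment counts for each channel
#'
#' HA density is proportional to occupancy; myc density is additionally
#' damped by the uncleaved fraction `steady_state_uncleaved(lambda, kappa)`.
#' Each channel is scaled so its expected total equals `depth` (sequencing
#' depths of separate immunoprecipitations are arbitrary, so only relative
#' quantities are meaningful downstream).
#'
#' @param loci Locus model `GRanges` (from [build_genome_fixture()] or
#'   [locus_model()]).
#' @param depth Expected fragments per channel.
#' @param kappa Cleavage rate (0 = non-cleavable control).
#' @return Data frame with `mu_myc`, `mu_ha` and the uncleaved fraction `f`.
#' @export
locus_channel_means <- function(loci, depth, kappa) {
  f <- steady_state_uncleaved(loci$lambda, kappa)
  w_ha <- loci$occupancy * GenomicRanges::width(loci)
  w_myc <- w_ha * f
  data.frame(mu_ha = w_ha / sum(w_ha) * depth,
             mu_myc = w_myc / sum(w_myc) * depth,
             f = f)
}

.truncnorm_pos <- function(n, mean, sd, lower = 20) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  round(x)
}

# Sample a fragment GRanges for one channel given per-locus Poisson means.
.sample_channel <- function(loci, mu, frag_mean, frag_sd, genome) {
  n <- rpois(length(mu), mu)
  tot <- sum(n)
  if (tot == 0) {
    warning("simulated channel is empty at this depth")
    return(GenomicRanges::GRanges(seqinfo = genome))
  }
  idx <- rep.int(seq_along(loci), n)
  w <- GenomicRanges::width(loci)[idx]
  mid <- GenomicRanges::start(loci)[idx] + floor(runif(tot) * w)
  len <- .truncnorm_pos(tot, frag_mean, frag_sd)
  start <- mid - len %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(loci))[idx]
  lens <- GenomeInfoDb::seqlengths(genome)[chrom]
  start <- pmax(1L, pmin(start, lens - len))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start, width = len),
                               strand = ifelse(runif(tot) < 0.5, "+", "-"),
                               mapq = rep(60L, tot),
                               seqinfo = genome)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Simulate sensor ChIP-seq channels from a locus model
#'
#' Draws Poisson fragment counts per locus with the expectations of
#' [locus_channel_means()], places fragment midpoints uniformly within each
#' locus, samples lengths from a truncated normal (default mean 160, sd 40)
#' and strands Bernoulli(1/2). Optional channels: `input` (density tracks
#' occupancy-free genome background), `mark` (class-weighted enrichment, see
#' `mark_weights`), `ATAC` (open-chromatin weighted, with a sub-120 bp
#' nucleosome-free length component at open loci).
#'
#' @param fix A `synthetic_genome` (or any list with `genome` and `loci`).
#' @param depth Expected fragments per channel.
#' @param kappa Cleavage rate; `cleavable = FALSE` overrides it to 0.
#' @param cleavable Set `FALSE` for the non-cleavable control sensor.
#' @param frag_mean,frag_sd Fragment length distribution (bp).
#' @param channels Subset of `c("myc", "HA", "input", "mark", "ATAC")`.
#' @param mark_weights Named per-class density multipliers for the `mark`
#'   channel (classes absent from the vector get weight 1).
#' @param seed Integer seed.
#' @return Named list of fragment `GRanges`, one per requested channel.
#' @export
simulate_channels <- function(fix, depth = 1e5, kappa = 1, cleavable = TRUE,
                              frag_mean = 160, frag_sd = 40,
                              channels = c("myc", "HA"),
                              mark_weights = c(enhancer_active = 8,
                                               enhancer_primed = 4,
                                               promoter = 4),
                              seed = 1) {
  loci <- fix$loci
  genome <- fix$genome
  if (!cleavable) kappa <- 0
  mus <- locus_channel_means(loci, depth, kappa)
  .with_seed(seed, {
    out <- list()
    for (ch in channels) {
      gr <- switch(ch,
        myc = .sample_channel(loci, mus$mu_myc, frag_mean, frag_sd, genome),
        HA = .sample_channel(loci, mus$mu_ha, frag_mean, frag_sd, genome),
        input = {
          w <- GenomicRanges::width(loci)
          .sample_channel(loci, w / sum(w) * depth, frag_mean, frag_sd, genome)
        },
        mark = {
          mult <- mark_weights[loci$class]
          mult[is.na(mult)] <- 1
          w <- loci$occupancy * GenomicRanges::width(loci) * mult
          .sample_channel(loci, w / sum(w) * depth, frag_mean, frag_sd, genome)
        },
        ATAC = .sample_atac(loci, depth, genome),
        stop("unknown channel: ", ch))
      out[[ch]] <- fragment_collection(gr, sample = "sim", channel =
                                         if (ch %in% c("myc", "HA")) ch
                                         else if (ch == "input") "input"
                                         else if (ch == "ATAC") "ATAC"
                                         else "mark")
    }
    out
  })
}

# ATAC channel: accessibility-weighted density; open classes emit a short
# (nucleosome-free, < 120 bp) component alongside mononucleosomal fragments.
.sample_atac <- function(loci, depth, genome) {
  open <- loci$class %in% c("promoter", "enhancer_active", "enhancer_primed")
  w <- GenomicRanges::width(loci) * ifelse(open, 6, 1) * loci$occupancy
  mu <- w / sum(w) * depth
  n <- rpois(length(mu), mu)
  tot <- sum(n)
  if (tot == 0) return(GenomicRanges::GRanges(seqinfo = genome))
  idx <- rep.int(seq_along(loci), n)
  short <- runif(tot) < ifelse(open[idx], 0.6, 0.1)
  len <- integer(tot)
  len[short] <- .truncnorm_pos(sum(short), 80, 15)
  len[!short] <- .truncnorm_pos(sum(!short), 190, 30)
  wloc <- GenomicRanges::width(loci)[idx]
  mid <- GenomicRanges::start(loci)[idx] + floor(runif(tot) * wloc)
  start <- mid - len %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(loci))[idx]
  lens <- GenomeInfoDb::seqlengths(genome)[chrom]
  start <- pmax(1L, pmin(start, lens - len))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = len),
                               strand = ifelse(runif(tot) < 0.5, "+", "-"),
                               mapq = rep(60L, tot), seqinfo = genome)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Fast count-level simulation of myc/HA replicates
#'
#' Skips fragment placement and samples per-locus Poisson counts directly
#' with the same expectations as [simulate_channels()]; used for replicate-
#' level power and calibration studies where only per-region counts matter.
#'
#' @inheritParams simulate_channels
#' @param n_replicates Number of independent replicates.
#' @param lambda_scale Optional per-locus multiplier on lambda (e.g. a
#'   knockout effect); recycled.
#' @return List of `n_replicates` data frames with columns `myc` and `ha`.
#' @export
simulate_region_counts <- function(fix, depth = 1e5, kappa = 1,
                                   n_replicates = 1, lambda_scale = 1,
                                   seed = 1) {
  loci <- fix$loci
  lam <- loci$lambda * rep_len(lambda_scale, length(loci))
  f <- steady_state_uncleaved(lam, kappa)
  w_ha <- loci$occupancy * GenomicRanges::width(loci)
  w_myc <- w_ha * f
  mu_ha <- w_ha / sum(w_ha) * depth
  mu_myc <- w_myc / sum(w_myc) * depth
  .with_seed(seed, {
    lapply(seq_len(n_replicates), function(i)
      data.frame(myc = rpois(length(loci), mu_myc),
                 ha = rpois(length(loci), mu_ha)))
  })
}

#' Write a synthetic genome fixture to disk
#'
#' Emits chrom.sizes, annotation BEDs (CTCF motifs and repeats as BED6 with
#' strand), the gene table TSV and the ground-truth locus TSV
#' (`chrom, start, end, class, occupancy, lambda`; BED-style coordinates).
#'
#' @param fix A `synthetic_genome`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_chrom_sizes(fix$genome, file.path(dir, "genome.chrom.sizes"))
  write_gene_table(fix$genes, file.path(dir, "genes.tsv"))
  ctcf <- fix$ctcf
  if (length(ctcf)) ctcf$score <- 0
  write_bed(ctcf, file.path(dir, "ctcf_motifs.bed"))
  reps <- fix$repeats
  if (length(reps)) {
    reps$name <- reps$family
    reps$score <- 0
  }
  write_bed(reps, file.path(dir, "repeats.bed"))
  enh <- fix$enhancers
  if (length(enh)) {
    enh$name <- enh$class
    enh$score <- 0
  }
  write_bed(enh, file.path(dir, "enhancers.bed"))
  write_bed(fix$heterochromatin, file.path(dir, "heterochromatin.bed"))
  loci <- fix$loci
  truth <- data.frame(chrom = as.character(GenomicRanges::seqnames(loci)),
                      start = GenomicRanges::start(loci) - 1L,
                      end = GenomicRanges::end(loci),
                      class = loci$class,
                      occupancy = loci$occupancy,
                      lambda = loci$lambda)
  utils::write.table(truth, file.path(dir, "locus_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
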