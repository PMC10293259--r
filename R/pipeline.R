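#' Default pipeline parameters
#'
#' Every printed analysis constant is a default here and overridable in the
#' config: fragment cap 300 bp, 80 bp 5' shift, depth target 0.4, exchange
#' pseudocount 0.05, enrichment pseudocount 1, 5 kb tiling, ATAC minimum
#' 120 bp, turnover thresholds (1, 1.55, -0.45), 31 CTCF bins, 10% deciles,
#' 250 repeat windows, 20 kb control shift.
#'
#' @return Named list of defaults.
#' @export
default_params <- function() {
  list(max_fragment_bp = 300, shift_bp = 80, depth_target = 0.4,
       atac_min_bp = 120, pseudocount = 0.05, tile_width = 5000,
       expression_bins = 4, tss_flank_bp = 1000, tss_bin_bp = 50,
       ctcf_nuc_bp = 180, ctcf_n_bins = 31, decile_fraction = 0.1,
       repeat_min_reads = 100, repeat_body_windows = 250,
       control_shift_bp = 20000,
       occupancy_min = 1, high_exchange_min = 1.55, low_exchange_max = -0.45)
}

#' Validate a pipeline configuration
#'
#' Checks structure, parameter ranges, file existence and myc/HA channel
#' pairing without touching any data.
#'
#' @param config A list (or path to a YAML file).
#' @return Character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character()
  if (is.null(config$seed)) errs <- c(errs, "missing field: seed")
  if (is.null(config$out_dir)) errs <- c(errs, "missing field: out_dir")
  p <- utils::modifyList(default_params(), config$params %||% list())
  for (f in c("max_fragment_bp", "shift_bp", "depth_target", "pseudocount",
              "tile_width"))
    if (!is.numeric(p[[f]]) || p[[f]] < 0 ||
        (f != "shift_bp" && p[[f]] == 0))
      errs <- c(errs, sprintf("parameter out of range: %s", f))
  if (is.null(config$simulate) && is.null(config$samples))
    errs <- c(errs, "config needs either a simulate block or a samples list")
  if (!is.null(config$samples)) {
    for (s in config$samples) {
      if (is.null(s$name) || is.null(s$channel) || is.null(s$path)) {
        errs <- c(errs, "each sample needs name, channel and path")
        next
      }
      if (!file.exists(s$path))
        errs <- c(errs, sprintf("sample %s: file not found: %s",
                                s$name, s$path))
    }
    chans <- vapply(config$samples, function(s) s$channel %||% "", "")
    names_ <- vapply(config$samples, function(s) s$name %||% "", "")
    for (nm in unique(names_)) {
      have <- chans[names_ == nm]
      for (need in c("myc", "HA"))
        if (!need %in% have)
          errs <- c(errs, sprintf("sample %s: missing %s channel", nm, need))
    }
  }
  if (!is.null(config$annotations)) {
    for (nm in names(config$annotations)) {
      path <- config$annotations[[nm]]
      if (!file.exists(path))
        errs <- c(errs, sprintf("annotation %s: file not found: %s", nm, path))
    }
  }
  errs
}

#' Run the full exchange analysis pipeline
#'
#' Orchestrates the stages in their canonical order — simulate (or load) the
#' myc/HA channels, length-filter, 5'-shift, count over the genome tiling,
#' depth-normalize, exchange-score, then region analytics (expression-binned
#' TSS metaprofiles, strand-aware CTCF nucleosome bins and asymmetry) — and
#' writes deterministic TSV outputs plus a run manifest. Re-running with the
#' same config and seed reproduces every output byte-identically.
#'
#' @param config Path to a YAML config or an equivalent list. Fields: `seed`,
#'   `out_dir`, a `simulate` block (fixture and depth settings) or a
#'   `samples` manifest, and an optional `params` block overriding
#'   [default_params()].
#' @param out_dir Optional override of `config$out_dir`.
#' @return Invisibly, a list with the output directory and the main result
#'   tables.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  out <- out_dir %||% config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  p <- utils::modifyList(default_params(), config$params %||% list())
  seed <- as.integer(config$seed)

  fix <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    chrom_lengths <- unlist(sim$chrom_lengths %||%
                              list(chr1 = 2e6, chr2 = 2e6))
    fix <- build_genome_fixture(
      n_genes = sim$n_genes %||% 100, n_ctcf = sim$n_ctcf %||% 60,
      n_repeats = sim$n_repeats %||% 30, n_enhancers = sim$n_enhancers %||% 50,
      n_hetero = sim$n_hetero %||% 6, chrom_lengths = chrom_lengths,
      seed = seed)
    write_fixture(fix, file.path(out, "fixture"))
    channels <- simulate_channels(fix, depth = sim$depth %||% 2e5,
                                  kappa = sim$kappa %||% 1,
                                  seed = seed + 1L)
    genome <- fix$genome
    genes <- fix$genes
    ctcf <- fix$ctcf
    myc <- channels$myc
    ha <- channels$HA
    write_fragments(myc, file.path(out, "fixture", "myc.fragments.bed"))
    write_fragments(ha, file.path(out, "fixture", "ha.fragments.bed"))
  } else {
    genome <- read_chrom_sizes(config$annotations$chrom_sizes)
    manifest <- config$samples
    get_chan <- function(chan) {
      paths <- vapply(manifest[vapply(manifest, function(s)
        s$channel == chan, logical(1))], function(s) s$path, "")
      frags <- lapply(paths, read_fragments, min_mapq = p$min_mapq %||% 10,
                      channel = chan, genome = genome)
      if (length(frags) > 1) pool_replicates(frags, seed = seed)
      else frags[[1]]
    }
    myc <- get_chan("myc")
    ha <- get_chan("HA")
    genes <- if (!is.null(config$annotations$genes))
      read_gene_table(config$annotations$genes, genome) else NULL
    ctcf <- if (!is.null(config$annotations$ctcf))
      read_bed(config$annotations$ctcf, genome) else NULL
  }

  myc <- filter_fragments(myc, p$max_fragment_bp)
  ha <- filter_fragments(ha, p$max_fragment_bp)
  p_myc <- shift_five_prime(myc, p$shift_bp)
  p_ha <- shift_five_prime(ha, p$shift_bp)

  tiles <- tile_genome(genome, p$tile_width)
  f_myc <- depth_factor(p_myc, genome, p$depth_target, p$tile_width)
  f_ha <- depth_factor(p_ha, genome, p$depth_target, p$tile_width)
  myc_cov <- count_in_regions(p_myc, tiles) * f_myc
  ha_cov <- count_in_regions(p_ha, tiles) * f_ha
  track <- data.frame(chrom = as.character(GenomicRanges::seqnames(tiles)),
                      start = GenomicRanges::start(tiles) - 1L,
                      end = GenomicRanges::end(tiles),
                      myc = round(myc_cov, 6), ha = round(ha_cov, 6),
                      exchange = round(
                        exchange_score(myc_cov, ha_cov, p$pseudocount), 6))
  .write_tsv(track, file.path(out, "exchange_track.tsv"))

  tss_profile <- NULL
  if (!is.null(genes) && length(genes) >= p$expression_bins) {
    tss <- GenomicRanges::resize(genes, 1, fix = "start")
    m_myc <- anchored_matrix(p_myc, tss, p$tss_flank_bp, p$tss_bin_bp,
                             strand_aware = TRUE)
    m_ha <- anchored_matrix(p_ha, tss, p$tss_flank_bp, p$tss_bin_bp,
                            strand_aware = TRUE)
    bins <- bin_by_covariate(genes$expression, p$expression_bins)
    rows <- lapply(seq_len(p$expression_bins), function(b) {
      sel <- which(bins$assignment == b)
      data.frame(expression_bin = b, column = seq_len(ncol(m_myc)),
                 offset_bp = seq(-p$tss_flank_bp, p$tss_flank_bp - p$tss_bin_bp,
                                 by = p$tss_bin_bp),
                 exchange = round(pooled_bin_exchange(
                   colMeans(m_myc[sel, , drop = FALSE]) * f_myc,
                   colMeans(m_ha[sel, , drop = FALSE]) * f_ha,
                   p$pseudocount), 6))
    })
    tss_profile <- do.call(rbind, rows)
    .write_tsv(tss_profile, file.path(out, "tss_exchange_profile.tsv"))
  }

  ctcf_out <- NULL
  if (!is.null(ctcf) && length(ctcf) >= 20) {
    keep <- if (!is.null(genes)) !overlap_flags(ctcf, genes)
            else rep(TRUE, length(ctcf))
    motifs <- ctcf[keep]
    layout <- nucleosome_layout(p$ctcf_nuc_bp, p$ctcf_n_bins)
    nbe <- nucleosome_bin_exchange(p_myc, p_ha, motifs, layout,
                                   p$pseudocount)
    ctcf_out <- nbe$bins
    ctcf_out$exchange <- round(ctcf_out$exchange, 6)
    ctcf_out$mean_myc <- round(ctcf_out$mean_myc, 6)
    ctcf_out$mean_ha <- round(ctcf_out$mean_ha, 6)
    .write_tsv(ctcf_out, file.path(out, "ctcf_bin_exchange.tsv"))
    asym <- asymmetry_score(nbe$zone_exchange)
    asym_tab <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(motifs)),
      start = GenomicRanges::start(motifs) - 1L,
      end = GenomicRanges::end(motifs),
      strand = as.character(GenomicRanges::strand(motifs)),
      asymmetry = round(asym, 6))
    .write_tsv(asym_tab, file.path(out, "ctcf_asymmetry.tsv"))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("exchseq")),
                   seed = seed, params = p,
                   n_fragments = list(myc = length(myc), ha = length(ha)),
                   depth_factors = list(myc = f_myc, ha = f_ha),
                   filtered = list(
                     myc = S4Vectors::metadata(myc)$n_removed %||% 0L,
                     ha = S4Vectors::metadata(ha)$n_removed %||% 0L))
  yaml::write_yaml(manifest, file.path(out, "run_manifest.yaml"))

  invisible(list(out_dir = out, exchange_track = track,
                 tss_profile = tss_profile, ctcf_bins = ctcf_out,
                 fixture = fix))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
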