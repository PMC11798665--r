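# Synthetic two-class cohorts with planted, gene-anchored epigenomic and
# fragmentomic effects. The generator emits exactly the text formats the
# data_io readers consume, so every pipeline stage can be exercised against
# recoverable ground truth without external data.
#
# Generative model, per sample:
#  * fragment lengths from a mono-/di-nucleosome Gaussian mixture (modes
#    near 167 and 330 bp) plus a per-sample global length jitter; fragments
#    whose midpoint falls in a planted gene's capture interval get, in
#    cancer samples, a length shift and an excess of sub-150 bp fragments;
#  * fragment 5' starts are snapped to nearby CC dinucleotides with a
#    probability combining a small per-sample baseline, a global cancer
#    tilt, and a strong planted-gene cancer bias — this is what plants
#    end/breakpoint-motif signal while keeping coordinates genomic;
#  * promoter methylation ratios are beta-distributed around a class- and
#    gene-state-dependent mean, binomially observed at Poisson coverage;
#  * promoter H3K4me3 counts are negative-binomial around a gene baseline
#    with a planted log2 fold-change in cancer;
#  * TSS coverage is Poisson around a flat flank depth with a promoter dip
#    whose depth deepens at planted activated genes in cancer.

#' Simulation configuration
#'
#' Defaults describe the standard study conditions: a 60 cancer vs 30
#' benign + 30 healthy training cohort (and an equally sized validation
#' cohort), a 2 x 2 Mb toy genome carrying 1000 genes in 4 kb slots, 5% of
#' genes planted as activated, and effect sizes large enough for the
#' planted structure to be recoverable by the full pipeline.
#'
#' @param seed Mandatory integer seed; every downstream draw derives from
#'   it.
#' @param n_cancer,n_benign,n_healthy Per-cohort sample counts.
#' @param include_validation Also generate a validation cohort of the same
#'   composition.
#' @param n_chrom,chrom_length,gc Toy genome shape.
#' @param n_genes Number of genes (must divide evenly over chromosomes).
#' @param planted_fraction,planted_state Fraction of genes planted and
#'   their regulatory state.
#' @param fragments_per_sample Fragments drawn per sample.
#' @param size_shift Fragment-length shift (bp) at planted genes in cancer.
#' @param short_excess Extra probability of a sub-150 bp fragment at
#'   planted genes in cancer.
#' @param motif_bias Probability of snapping a fragment start to a CC
#'   dinucleotide at planted genes in cancer.
#' @param motif_bias_global Global cancer snapping tilt.
#' @param ndr_delta Extra promoter coverage dip depth at planted activated
#'   genes in cancer.
#' @param meth_delta Promoter methylation mean shift at planted genes in
#'   cancer (negative = hypomethylation).
#' @param h3k4me3_lfc Planted H3K4me3 log2 fold-change in cancer.
#' @param ... Advanced knobs: mixture (`mono_mean`, `mono_sd`, `di_mean`,
#'   `di_sd`, `mono_weight`, `short_mean`, `short_sd`), noise
#'   (`sample_size_sd`, `sample_motif_sd`, `baseline_snap`,
#'   `depth_jitter_sd`, `ndr_dip_sd`), layer scales (`h3k4me3_base_mean`,
#'   `h3k4me3_dispersion`, `meth_mean`, `meth_concentration`,
#'   `cpg_coverage`, `coverage_depth`, `coverage_step`, `ndr_base_dip`,
#'   `cpg_spacing`, `promoter_halfwidth`).
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              n_cancer = 60L, n_benign = 30L,
                              n_healthy = 30L, include_validation = TRUE,
                              n_chrom = 2L, chrom_length = 2e6, gc = 0.5,
                              n_genes = 1000L,
                              planted_fraction = 0.05,
                              planted_state = "activated",
                              fragments_per_sample = 15000L,
                              size_shift = -20, short_excess = 0.15,
                              motif_bias = 0.4, motif_bias_global = 0.02,
                              ndr_delta = 0.3, meth_delta = -0.3,
                              h3k4me3_lfc = 1, ...) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  extra <- list(...)
  defaults <- list(mono_mean = 167, mono_sd = 10, di_mean = 330, di_sd = 25,
                   mono_weight = 0.8, short_mean = 110, short_sd = 15,
                   sample_size_sd = 2, sample_motif_sd = 0.02,
                   baseline_snap = 0.01, depth_jitter_sd = 0.1,
                   ndr_dip_sd = 0.05, h3k4me3_base_mean = 100,
                   h3k4me3_dispersion = 0.2, meth_mean = 0.6,
                   meth_concentration = 50, cpg_coverage = 30,
                   coverage_depth = 30, coverage_step = 50L,
                   ndr_base_dip = 0.4, cpg_spacing = 50L,
                   promoter_halfwidth = 500L)
  bad <- setdiff(names(extra), names(defaults))
  if (length(bad)) stop("unknown config field: ", bad[1], call. = FALSE)
  adv <- utils::modifyList(defaults, extra)
  cfg <- c(list(seed = as.integer(seed), n_cancer = as.integer(n_cancer),
                n_benign = as.integer(n_benign),
                n_healthy = as.integer(n_healthy),
                include_validation = isTRUE(include_validation),
                n_chrom = as.integer(n_chrom),
                chrom_length = as.integer(chrom_length), gc = gc,
                n_genes = as.integer(n_genes),
                planted_fraction = planted_fraction,
                planted_state = match.arg(planted_state,
                                          c("activated", "repressed")),
                fragments_per_sample = as.integer(fragments_per_sample),
                size_shift = size_shift, short_excess = short_excess,
                motif_bias = motif_bias,
                motif_bias_global = motif_bias_global,
                ndr_delta = ndr_delta, meth_delta = meth_delta,
                h3k4me3_lfc = h3k4me3_lfc),
           adv)
  stopifnot(cfg$n_cancer >= 0, cfg$n_benign >= 0, cfg$n_healthy >= 0,
            cfg$planted_fraction >= 0, cfg$planted_fraction <= 1,
            cfg$short_excess >= 0, cfg$short_excess <= 1,
            cfg$motif_bias >= 0, cfg$motif_bias <= 1,
            cfg$fragments_per_sample >= 0,
            (cfg$n_chrom * cfg$chrom_length) %% cfg$n_genes == 0)
  structure(cfg, class = "sim_config")
}

# deterministic genome + gene layout shared by simulate_cohort/truth_set.
# Genes sit in equal slots with the TSS fixed at slot + 2000 for both
# strands, so NDR tracks tile the genome without overlap.
build_layout <- function(config) {
  set.seed(derive_seed(config$seed, "layout"))
  slot <- (config$n_chrom * config$chrom_length) %/% config$n_genes
  if (slot < 4000L) stop("gene slots need >= 4000 bp; enlarge the genome",
                         call. = FALSE)
  per_chrom <- config$n_genes %/% config$n_chrom
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  bases <- c("A", "C", "G", "T")
  pb <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
          (1 - config$gc) / 2)
  seqs <- vapply(chroms, function(ch) {
    paste(sample(bases, config$chrom_length, replace = TRUE, prob = pb),
          collapse = "")
  }, character(1))
  genes <- data.table::rbindlist(lapply(seq_along(chroms), function(ci) {
    slot_start <- (seq_len(per_chrom) - 1L) * slot
    tss <- slot_start + 2000L
    strand <- rep(c("+", "-"), length.out = per_chrom)
    len <- sample(1000:2000, per_chrom, replace = TRUE)
    data.table::data.table(
      gene_id = sprintf("g%04d", (ci - 1L) * per_chrom + seq_len(per_chrom)),
      chrom = chroms[ci], strand = strand, tss = tss,
      body_start = ifelse(strand == "+", tss, tss + 1L - len),
      body_end = ifelse(strand == "+", tss + len, tss + 1L))
  }))
  genes[, promoter_start := tss - config$promoter_halfwidth]
  genes[, promoter_end := tss + config$promoter_halfwidth]
  # place genuine CpG dinucleotides on a fixed grid inside each promoter
  n_cpg <- (2L * config$promoter_halfwidth) %/% config$cpg_spacing
  cpg <- genes[, .(pos = promoter_start[1] +
                     config$cpg_spacing * (seq_len(n_cpg) - 1L)),
               by = .(gene_id, chrom)]
  for (ch in chroms) {
    p <- cpg$pos[cpg$chrom == ch]
    s <- strsplit(seqs[[ch]], "", fixed = TRUE)[[1]]
    s[p + 1L] <- "C"
    s[p + 2L] <- "G"
    seqs[[ch]] <- paste(s, collapse = "")
  }
  n_planted <- round(config$n_genes * config$planted_fraction)
  planted <- sort(sample(genes$gene_id, n_planted))
  capture <- gene_capture_intervals(genes)
  cc_pos <- lapply(seqs, function(s) {
    r <- charToRaw(s)
    which(r[-length(r)] == charToRaw("C") & r[-1] == charToRaw("C")) - 1L
  })
  list(seqs = seqs, genes = genes, cpg = cpg, planted = planted,
       capture = capture, slot = slot, cc_pos = cc_pos, chroms = chroms)
}

#' Planted-gene truth table
#'
#' @param config A `sim_config`.
#' @return `data.table`: `gene_id`, `state`, and the per-layer effects
#'   actually applied (`size_shift`, `short_excess`, `motif_bias`,
#'   `ndr_delta`, `meth_delta`, `h3k4me3_lfc`).
#' @export
truth_set <- function(config) {
  layout <- build_layout(config)
  data.table::data.table(gene_id = layout$planted,
                         state = config$planted_state,
                         size_shift = config$size_shift,
                         short_excess = config$short_excess,
                         motif_bias = config$motif_bias,
                         ndr_delta = config$ndr_delta,
                         meth_delta = config$meth_delta,
                         h3k4me3_lfc = config$h3k4me3_lfc)
}

simulate_sample <- function(config, layout, sample_id, label) {
  set.seed(derive_seed(config$seed, sample_id))
  cancer <- label == "cancer"
  genes <- layout$genes
  planted <- genes$gene_id %in% layout$planted
  # planted effects act in the "activated" direction by default; the
  # repressed state mirrors every sign
  sgn <- if (config$planted_state == "activated") 1 else -1

  ## fragments -------------------------------------------------------------
  n <- config$fragments_per_sample
  if (n <= 0L) stop("zero fragments requested", call. = FALSE)
  chrom_i <- sample.int(config$n_chrom, n, replace = TRUE)
  mid <- floor(stats::runif(n, 0, config$chrom_length))
  slot_i <- mid %/% layout$slot + 1L
  per_chrom <- config$n_genes %/% config$n_chrom
  gene_i <- (chrom_i - 1L) * per_chrom + slot_i
  cap <- layout$capture
  affected <- cancer & planted[gene_i] &
    mid >= cap$start[gene_i] & mid < cap$end[gene_i]
  size_jit <- stats::rnorm(1, 0, config$sample_size_sd)
  shift <- size_jit + ifelse(affected, sgn * config$size_shift, 0)
  mono <- stats::runif(n) < config$mono_weight
  len <- ifelse(mono,
                stats::rnorm(n, config$mono_mean + shift, config$mono_sd),
                stats::rnorm(n, config$di_mean + shift, config$di_sd))
  shorten <- affected & stats::runif(n) < sgn * config$short_excess
  len[shorten] <- stats::rnorm(sum(shorten), config$short_mean,
                               config$short_sd)
  len <- pmin(pmax(round(len), 66L), 999L)
  start <- mid - len %/% 2L
  snap_base <- max(0, min(1, config$baseline_snap +
                            (if (cancer) config$motif_bias_global else 0) +
                            stats::rnorm(1, 0, config$sample_motif_sd)))
  p_snap <- snap_base + ifelse(affected, sgn * config$motif_bias, 0)
  do_snap <- stats::runif(n) < p_snap
  for (ci in seq_along(layout$chroms)) {
    sel <- which(do_snap & chrom_i == ci)
    if (!length(sel)) next
    ccp <- layout$cc_pos[[ci]]
    j <- findInterval(start[sel], ccp)
    lo <- ccp[pmax(j, 1L)]
    hi <- ccp[pmin(j + 1L, length(ccp))]
    start[sel] <- ifelse(abs(start[sel] - lo) <= abs(hi - start[sel]),
                         lo, hi)
  }
  start <- pmin(pmax(start, 8L), config$chrom_length - len - 8L)
  frags <- data.table::data.table(chrom = layout$chroms[chrom_i],
                                  start = as.integer(start),
                                  end = as.integer(start + len))
  data.table::setorder(frags, chrom, start, end)

  ## methylation ------------------------------------------------------------
  m_gene <- config$meth_mean +
    ifelse(cancer & planted, sgn * config$meth_delta, 0)
  m_gene <- pmin(pmax(m_gene, 0.02), 0.98)
  cpg <- data.table::copy(layout$cpg)
  gm <- m_gene[match(cpg$gene_id, genes$gene_id)]
  conc <- config$meth_concentration
  ratio <- stats::rbeta(nrow(cpg), gm * conc, (1 - gm) * conc)
  total <- stats::rpois(nrow(cpg), config$cpg_coverage) + 1L
  meth <- stats::rbinom(nrow(cpg), total, ratio)
  meth_dt <- data.table::data.table(chrom = cpg$chrom, pos = cpg$pos,
                                    methylated_count = meth,
                                    total_count = total)
  data.table::setorder(meth_dt, chrom, pos)

  ## H3K4me3 promoter counts -----------------------------------------------
  set.seed(derive_seed(config$seed, "gene_baselines"))
  base_mu <- stats::rlnorm(config$n_genes, log(config$h3k4me3_base_mean), 0.5)
  set.seed(derive_seed(config$seed, paste0(sample_id, ":chip")))
  lib <- exp(stats::rnorm(1, 0, 0.2))
  mu <- base_mu * lib *
    2^(ifelse(cancer & planted, sgn * config$h3k4me3_lfc, 0))
  counts <- stats::rnbinom(config$n_genes, mu = mu,
                           size = 1 / config$h3k4me3_dispersion)
  chip_dt <- data.table::data.table(gene_id = genes$gene_id, count = counts)
  on_target <- sum(counts)
  total_reads <- round(on_target / stats::runif(1, 0.45, 0.65))

  ## TSS coverage track ------------------------------------------------------
  step <- config$coverage_step
  nb <- 4000L %/% step
  offs <- seq(-2000L, 2000L - step, by = step)
  depth <- config$coverage_depth * exp(stats::rnorm(1, 0,
                                                    config$depth_jitter_sd))
  dip <- pmin(pmax(config$ndr_base_dip +
                     ifelse(cancer & planted, sgn * config$ndr_delta, 0),
                   0.02), 0.95)
  centre_off <- rep(offs + step / 2, config$n_genes)
  gidx <- rep(seq_len(config$n_genes), each = nb)
  orient <- ifelse(genes$strand[gidx] == "+", centre_off, -centre_off)
  in_prom <- orient >= -150 & orient < 50
  lambda <- depth * ifelse(in_prom, 1 - dip[gidx], 1)
  value <- stats::rpois(length(lambda), lambda)
  cov_dt <- data.table::data.table(
    chrom = genes$chrom[gidx],
    start = genes$tss[gidx] - 2000L + rep(offs + 2000L, config$n_genes),
    value = value)
  cov_dt[, end := start + step]
  data.table::setorder(cov_dt, chrom, start)
  data.table::setcolorder(cov_dt, c("chrom", "start", "end", "value"))

  list(fragments = frags, methylation = meth_dt, chip = chip_dt,
       coverage = cov_dt, on_target = on_target, total_reads = total_reads)
}

#' Generate a synthetic cohort on disk
#'
#' Writes a genome FASTA, a gene annotation BED (with promoter columns),
#' sample metadata, the planted-gene truth table, a cfChIP QC table, and
#' per-sample fragment BEDPE, methylation calls, promoter count TSV and
#' TSS coverage bedGraph files (all gzip-compressed where large). Rerunning
#' with the same config produces byte-identical files.
#'
#' @param config A `sim_config`.
#' @param outdir Output directory (created if needed).
#' @return Object of class `synthetic_cohort`: file paths, the metadata
#'   and truth tables, and the config.
#' @export
simulate_cohort <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  layout <- build_layout(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("fragments", "methylation", "chip", "coverage")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }
  fa <- Biostrings::DNAStringSet(layout$seqs)
  Biostrings::writeXStringSet(fa, file.path(outdir, "genome.fa"))
  ann <- layout$genes[, .(chrom, body_start, body_end, gene_id, strand,
                          promoter_start, promoter_end)]
  data.table::fwrite(ann, file.path(outdir, "annotations.bed"), sep = "\t",
                     col.names = FALSE, quote = FALSE)

  cohorts <- if (config$include_validation) c("train", "validation")
             else "train"
  meta <- data.table::rbindlist(lapply(cohorts, function(co) {
    labs <- rep(c("cancer", "benign", "healthy"),
                c(config$n_cancer, config$n_benign, config$n_healthy))
    within_label <- unlist(lapply(c(config$n_cancer, config$n_benign,
                                    config$n_healthy), seq_len))
    stage <- rep("", length(labs))
    stage[labs == "cancer"] <- rep_len(c("I", "I", "II"), config$n_cancer)
    subtype <- rep("none", length(labs))
    subtype[labs == "cancer"] <- rep_len(c("AIS", "MIA", "IAC"),
                                         config$n_cancer)
    data.table::data.table(
      sample_id = sprintf("%s_%s_%03d", co, labs, within_label),
      cohort = co, label = labs, stage = stage, subtype = subtype)
  }))
  qc <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sm <- simulate_sample(config, layout, meta$sample_id[i], meta$label[i])
    sid <- meta$sample_id[i]
    write_fragments(sm$fragments,
                    file.path(outdir, "fragments", paste0(sid, ".bedpe.gz")))
    data.table::fwrite(sm$methylation,
                       file.path(outdir, "methylation", paste0(sid, ".tsv.gz")),
                       sep = "\t", col.names = FALSE, quote = FALSE)
    data.table::fwrite(sm$chip,
                       file.path(outdir, "chip", paste0(sid, ".tsv.gz")),
                       sep = "\t", quote = FALSE)
    data.table::fwrite(sm$coverage,
                       file.path(outdir, "coverage",
                                 paste0(sid, ".bedgraph.gz")),
                       sep = "\t", col.names = FALSE, quote = FALSE)
    qc[[i]] <- data.table::data.table(sample_id = sid,
                                      on_target_reads = sm$on_target,
                                      total_reads = sm$total_reads)
  }
  data.table::fwrite(meta, file.path(outdir, "meta.tsv"), sep = "\t",
                     quote = FALSE)
  truth <- truth_set(config)
  data.table::fwrite(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(data.table::rbindlist(qc),
                     file.path(outdir, "chip_qc.tsv"), sep = "\t",
                     quote = FALSE)
  jsonlite::write_json(unclass(config), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(dir = outdir, meta = meta, truth = truth, config = config,
                 paths = list(
                   genome = file.path(outdir, "genome.fa"),
                   annotations = file.path(outdir, "annotations.bed"),
                   meta = file.path(outdir, "meta.tsv"),
                   truth = file.path(outdir, "truth.tsv"),
                   chip_qc = file.path(outdir, "chip_qc.tsv"))),
            class = "synthetic_cohort")
}
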