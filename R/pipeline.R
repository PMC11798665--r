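# End-to-end orchestration: simulate/ingest -> QC -> features ->
# differential -> MERGE selection -> feature tables -> base models ->
# ensemble -> evaluation, with a run manifest for reproducibility.
#
# A cohort directory (real or simulated) follows one fixed layout:
#   genome.fa, annotations.bed, meta.tsv, chip_qc.tsv,
#   fragments/<sample>.bedpe[.gz], methylation/<sample>.tsv[.gz],
#   chip/<sample>.tsv[.gz], coverage/<sample>.bedgraph[.gz]

#' Pipeline run configuration
#'
#' Exactly one of `simulation` (a [simulation_config()]) or `input_dir`
#' (a cohort directory in the documented layout) must be supplied.
#'
#' @param seed Mandatory master seed for folds, bootstrap and trees.
#' @param simulation Optional `sim_config` to generate the cohort.
#' @param input_dir Optional path to an existing cohort directory.
#' @param promoter_rule Promoter preset for [read_annotations()].
#' @param alpha BH-adjusted significance threshold for MERGE selection.
#' @param min_detectable Detectability filter (samples) for the
#'   differential stage.
#' @param lambda Ridge penalty of the base models.
#' @param n_folds Shared stratified fold count.
#' @param n_estimators,max_depth,min_samples_split Stacker
#'   hyperparameters.
#' @param cutoff MERGE-score decision cutoff.
#' @param fsr_window FSR window size in bp.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, simulation = NULL, input_dir = NULL,
                       promoter_rule = "annotation", alpha = 0.05,
                       min_detectable = 10L, lambda = 0.1, n_folds = 10L,
                       n_estimators = 1000L, max_depth = 5L,
                       min_samples_split = 5L, cutoff = 0.5,
                       fsr_window = 1e6) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(simulation) == is.null(input_dir)) {
    stop("supply exactly one of 'simulation' or 'input_dir'", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), simulation = simulation,
                 input_dir = input_dir, promoter_rule = promoter_rule,
                 alpha = alpha, min_detectable = as.integer(min_detectable),
                 lambda = lambda, n_folds = as.integer(n_folds),
                 n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 cutoff = cutoff, fsr_window = fsr_window),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' The document may hold any [run_config()] field plus a nested
#' `simulation:` block of [simulation_config()] fields.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the document's.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  doc <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(doc$simulation)) {
    sim_args <- doc$simulation
    if (!is.null(seed)) sim_args$seed <- seed
    if (is.null(sim_args$seed)) sim_args$seed <- doc$seed
    sim <- do.call(simulation_config, sim_args)
  }
  args <- doc[setdiff(names(doc), "simulation")]
  args$simulation <- sim
  if (!is.null(seed)) args$seed <- seed
  do.call(run_config, args)
}

sample_file <- function(dir, sub, sid, exts) {
  for (e in exts) {
    p <- file.path(dir, sub, paste0(sid, e))
    if (file.exists(p)) return(p)
  }
  stop("no ", sub, " file for sample ", sid, call. = FALSE)
}

# chromosome arms for FSD: each chromosome split at its midpoint
make_arms <- function(genome) {
  data.table::rbindlist(lapply(names(genome$seq), function(ch) {
    L <- genome$lengths[[ch]]
    half <- L %/% 2L
    data.table::data.table(arm_id = paste0(ch, c("p", "q")), chrom = ch,
                           start = c(0L, half), end = c(half, L))
  }))
}

# per-gene FSR restricted to capture intervals (MERGE-scope FSR)
gene_fsr <- function(fragments, capture) {
  idx <- assign_to_intervals(fragments, capture)
  n <- tabulate(idx, nbins = nrow(capture))
  mono <- fragments$length >= 151L & fragments$length <= 220L
  k <- tabulate(idx[mono], nbins = nrow(capture))
  stats::setNames(ifelse(n > 0, k / n, NA_real_), capture$gene_id)
}

extract_cohort_features <- function(dir, meta, genome, annotations,
                                    qc_pass, fsr_window, log) {
  windows <- make_windows(genome, fsr_window)
  arms <- make_arms(genome)
  edges <- seq(65L, 400L, by = 5L)
  fsd_cols <- as.vector(outer(sprintf("len_%d_%d", edges[-68], edges[-1] - 1L),
                              arms$arm_id,
                              function(b, a) paste(a, b, sep = ".")))
  ns <- nrow(meta)
  k6 <- kmer_alphabet(6L)
  mk <- function(cols) matrix(NA_real_, ns, length(cols),
                              dimnames = list(meta$sample_id, cols))
  out <- list(edm = mk(k6), bpm = mk(k6),
              fsr = mk(windows$window_id), fsd = mk(fsd_cols),
              h3k4me3 = mk(annotations$gene_id),
              methylation = mk(annotations$gene_id),
              ndr = mk(annotations$gene_id))
  fragments <- vector("list", ns)
  names(fragments) <- meta$sample_id
  n_dropped <- 0L
  for (i in seq_len(ns)) {
    sid <- meta$sample_id[i]
    fr <- read_fragments(sample_file(dir, "fragments", sid,
                                     c(".bedpe.gz", ".bedpe")))
    n_dropped <- n_dropped + attr(fr, "n_dropped")
    fragments[[i]] <- fr
    out$edm[i, ] <- end_motif_profile(fr, genome, k = 6L)$frequencies
    out$bpm[i, ] <- breakpoint_motif_profile(fr, genome)$frequencies
    out$fsr[i, ] <- fsr_per_window(fr, windows)$value
    fsd <- fsd_per_arm(fr, arms)
    out$fsd[i, ] <- as.vector(t(fsd$proportions))
    meth <- read_methylation(sample_file(dir, "methylation", sid,
                                         c(".tsv.gz", ".tsv")))
    pm <- promoter_methylation_all(meth, annotations)
    out$methylation[i, ] <- pm$meth_ratio
    cov <- read_coverage(sample_file(dir, "coverage", sid,
                                     c(".bedgraph.gz", ".bedgraph")))
    out$ndr[i, ] <- ndr_score_table(cov, annotations)
    if (qc_pass[[sid]]) {
      chip <- fread_auto(sample_file(dir, "chip", sid,
                                            c(".tsv.gz", ".tsv")))
      cnt <- chip$count[match(annotations$gene_id, chip$gene_id)]
      total <- sum(chip$count)
      out$h3k4me3[i, ] <- promoter_rpkm(
        cnt, annotations$promoter_end - annotations$promoter_start, total)
    }
  }
  log(sprintf("features: %d samples, %d length-filtered fragments dropped",
              ns, n_dropped))
  list(tables = out, fragments = fragments)
}

merge_scope_features <- function(fragments, meta, genome, capture) {
  ns <- length(fragments)
  k6 <- kmer_alphabet(6L)
  mbpm <- matrix(NA_real_, ns, length(k6),
                 dimnames = list(meta$sample_id, k6))
  medm <- mbpm
  mfsr <- matrix(NA_real_, ns, nrow(capture),
                 dimnames = list(meta$sample_id, capture$gene_id))
  for (i in seq_len(ns)) {
    fr <- fragments[[i]]
    idx <- assign_to_intervals(fr, capture)
    sub <- fr[!is.na(idx), ]
    medm[i, ] <- end_motif_profile(sub, genome, k = 6L)$frequencies
    mbpm[i, ] <- breakpoint_motif_profile(sub, genome)$frequencies
    mfsr[i, ] <- gene_fsr(fr, capture)
  }
  list(mbpm = mbpm, medm = medm, mfsr = mfsr)
}

#' Run the full pipeline
#'
#' Executes every stage on a simulated or pre-existing cohort directory
#' and writes all artifacts plus a manifest under `outdir`. Stage errors
#' abort with the stage name.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the manifest, MERGE set, ensemble model,
#'   training/validation reports and score tables.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    writeLines(line, log_con)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    log(paste("stage:", name))
    tryCatch(expr, error = function(e) {
      stop_stage(name, conditionMessage(e))
    })
  }

  cohort_dir <- stage("simulate", {
    if (!is.null(config$simulation)) {
      sim <- simulate_cohort(config$simulation, file.path(outdir, "cohort"))
      sim$dir
    } else config$input_dir
  })

  ing <- stage("ingest", {
    list(genome = read_reference(file.path(cohort_dir, "genome.fa")),
         annotations = read_annotations(
           file.path(cohort_dir, "annotations.bed"),
           promoter_rule = config$promoter_rule),
         meta = read_sample_meta(file.path(cohort_dir, "meta.tsv")),
         qc_tab = data.table::fread(file.path(cohort_dir, "chip_qc.tsv")))
  })
  meta <- ing$meta

  qc_pass <- stage("qc", {
    qc <- lapply(seq_len(nrow(ing$qc_tab)), function(i) {
      chip_sample_qc(ing$qc_tab$on_target_reads[i],
                     ing$qc_tab$total_reads[i], ing$qc_tab$sample_id[i])
    })
    pass <- stats::setNames(vapply(qc, `[[`, logical(1), "pass"),
                            ing$qc_tab$sample_id)
    miss <- setdiff(meta$sample_id, names(pass))
    pass[miss] <- FALSE
    log(sprintf("qc: %d/%d cfChIP samples pass", sum(pass), length(pass)))
    pass
  })

  feats <- stage("features", {
    extract_cohort_features(cohort_dir, meta, ing$genome, ing$annotations,
                            qc_pass, config$fsr_window, log)
  })

  train_idx <- which(meta$cohort == "train")
  meta_train <- meta[train_idx, ]
  tr <- function(m) m[meta_train$sample_id, , drop = FALSE]

  diff_res <- stage("differential", {
    layers <- list(
      h3k4me3 = median_ratio_normalize(t(tr(feats$tables$h3k4me3))),
      methylation = t(tr(feats$tables$methylation)),
      ndr = t(tr(feats$tables$ndr)))
    res <- list()
    for (ly in names(layers)) {
      for (cmp in c("cancer_vs_benign", "cancer_vs_healthy",
                    "cancer_vs_noncancer")) {
        res[[paste(ly, cmp)]] <- layer_differential(
          layers[[ly]], meta_train, comparison_spec(cmp), ly,
          min_detectable = config$min_detectable)
      }
    }
    out <- data.table::rbindlist(res)
    data.table::fwrite(out, file.path(outdir, "differential.tsv.gz"),
                       sep = "\t", quote = FALSE)
    out
  })

  merges <- stage("merge", {
    ms <- select_merges(diff_res, alpha = config$alpha)
    write_merge_set(ms, ing$annotations,
                    tsv_path = file.path(outdir, "merge_set.tsv"),
                    bed_path = file.path(outdir, "merge_intervals.bed"))
    log(sprintf("merge: %d genes selected at alpha=%g", nrow(ms$genes),
                config$alpha))
    ms
  })

  all_feats <- stage("tables", {
    f <- feats$tables[c("bpm", "edm", "fsr", "fsd")]
    if (nrow(merges$genes) > 0L) {
      cap <- gene_capture_intervals(
        ing$annotations[ing$annotations$gene_id %in% merges$genes$gene_id, ])
      f <- c(f, merge_scope_features(feats$fragments, meta, ing$genome, cap))
    } else {
      log("tables: empty MERGE set; merge-scope tables skipped")
    }
    f
  })

  train_tables <- stage("tables", {
    assemble_feature_tables(lapply(all_feats, function(m)
      m[meta_train$sample_id, , drop = FALSE]),
      meta_train, seed = config$seed, n_folds = config$n_folds)
  })
  labels_train <- as.integer(meta_train$label == "cancer")

  candidates <- stage("base_models", {
    out <- lapply(train_tables, train_base_model, labels = labels_train,
                  seed = config$seed, lambda = config$lambda)
    for (nm in names(out)) {
      log(sprintf("base model %s (%s/%s): oof AUC %.3f", nm,
                  out[[nm]]$family, out[[nm]]$scope, out[[nm]]$auc))
    }
    out
  })

  base_set <- stage("selection", select_base_models(candidates))

  ensemble <- stage("ensemble", {
    train_ensemble(base_set, labels_train, seed = config$seed,
                   n_estimators = config$n_estimators,
                   max_depth = config$max_depth,
                   min_samples_split = config$min_samples_split,
                   cutoff = config$cutoff)
  })

  results <- stage("evaluation", {
    train_report <- evaluate(ensemble$cv_scores, labels_train,
                             cutoff = config$cutoff,
                             seed = config$seed)
    train_scores <- data.table::data.table(
      sample_id = meta_train$sample_id, cohort = "train",
      label = meta_train$label, score = ensemble$cv_scores,
      call = ifelse(ensemble$cv_scores >= config$cutoff, "cancer",
                    "non-cancer"))
    val_report <- NULL
    val_scores <- NULL
    if (any(meta$cohort == "validation")) {
      meta_val <- meta[meta$cohort == "validation", ]
      fam_feats <- lapply(base_set, function(bm) {
        key <- paste0(if (bm$scope == "merge") "m" else "",
                      tolower(bm$family))
        all_feats[[key]][meta_val$sample_id, , drop = FALSE]
      })
      sc <- merge_score(ensemble, fam_feats)
      val_scores <- cbind(data.table::data.table(cohort = "validation",
                                                 label = meta_val$label),
                          sc)
      data.table::setcolorder(val_scores, c("sample_id", "cohort", "label",
                                            "score", "call"))
      val_report <- evaluate(sc$score,
                             as.integer(meta_val$label == "cancer"),
                             cutoff = config$cutoff, seed = config$seed)
    }
    scores <- data.table::rbindlist(list(train_scores, val_scores),
                                    fill = TRUE)
    data.table::fwrite(scores, file.path(outdir, "merge_scores.tsv"),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(
      list(training_cv = performance_report_json(train_report),
           validation = if (!is.null(val_report))
             performance_report_json(val_report)),
      file.path(outdir, "performance.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    list(train_report = train_report, val_report = val_report,
         scores = scores)
  })

  manifest <- stage("manifest", {
    arts <- c("differential.tsv.gz", "merge_set.tsv", "merge_intervals.bed",
              "merge_scores.tsv", "performance.json")
    arts <- arts[file.exists(file.path(outdir, arts))]
    mf <- list(
      package_version = as.character(utils::packageVersion("cfmerge")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = config$seed,
      config = serialize_config(config),
      checksums = as.list(tools::md5sum(file.path(outdir, arts))))
    names(mf$checksums) <- arts
    jsonlite::write_json(mf, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    mf
  })

  invisible(list(manifest = manifest, merge_set = merges,
                 differential = diff_res, candidates = candidates,
                 base_models = base_set, ensemble = ensemble,
                 train_report = results$train_report,
                 val_report = results$val_report,
                 scores = results$scores, outdir = outdir,
                 cohort_dir = cohort_dir))
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulation)) cfg$simulation <- unclass(cfg$simulation)
  cfg
}
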