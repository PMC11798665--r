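# Classifier stack: per-family base models on fragmentomic feature tables
# (genome-wide and MERGE-restricted), genome-vs-MERGE selection, and an
# extremely-randomized-trees stacker emitting MERGE scores in [0, 1].

#' Assemble the candidate feature tables
#'
#' Builds the seven candidate sample-by-feature tables — BPM, MERGE-BPM,
#' EDM, MERGE-EDM, FSR, MERGE-FSR, FSD — from per-sample fragmentomic
#' outputs, imputes missing values by column median, drops all-missing
#' columns, and attaches one shared stratified 10-fold assignment. MERGE
#' tables are produced only when `merge` matrices are supplied (i.e. the
#' MERGE set was nonempty).
#'
#' @param features Named list of sample x feature matrices; recognised
#'   names: `bpm`, `edm`, `fsr`, `fsd` and optionally `mbpm`, `medm`,
#'   `mfsr`.
#' @param meta Sample metadata restricted to the training cohort.
#' @param seed Seed driving the fold assignment.
#' @param n_folds Number of folds.
#' @return Named list of `feature_table` objects (`x`, `family`, `scope`,
#'   `folds`, `medians`, `kept`).
#' @export
assemble_feature_tables <- function(features, meta, seed, n_folds = 10L) {
  scope_of <- c(bpm = "genome", edm = "genome", fsr = "genome",
                fsd = "genome", mbpm = "merge", medm = "merge",
                mfsr = "merge")
  family_of <- c(bpm = "BPM", edm = "EDM", fsr = "FSR", fsd = "FSD",
                 mbpm = "BPM", medm = "EDM", mfsr = "FSR")
  unknown <- setdiff(names(features), names(scope_of))
  if (length(unknown)) stop("unknown feature table: ", unknown[1],
                            call. = FALSE)
  labels <- ifelse(meta$label == "cancer", 1L, 0L)
  folds <- make_folds(labels, k = n_folds, seed = seed)
  out <- list()
  for (nm in names(features)) {
    x <- features[[nm]]
    missing_samples <- setdiff(meta$sample_id, rownames(x))
    if (length(missing_samples)) {
      stop("sample(s) in metadata lack '", nm, "' features: ",
           paste(missing_samples, collapse = ", "), call. = FALSE)
    }
    x <- x[meta$sample_id, , drop = FALSE]
    kept <- colSums(!is.na(x)) > 0L
    x <- x[, kept, drop = FALSE]
    med <- apply(x, 2, stats::median, na.rm = TRUE)
    for (j in which(colSums(is.na(x)) > 0L)) {
      x[is.na(x[, j]), j] <- med[j]
    }
    out[[nm]] <- structure(
      list(x = x, family = family_of[[nm]], scope = scope_of[[nm]],
           folds = folds, medians = med, kept = names(kept)[kept]),
      class = "feature_table")
  }
  out
}

# apply a trained table's imputation schema to new samples
apply_table_schema <- function(table, x_new) {
  miss <- setdiff(table$kept, colnames(x_new))
  if (length(miss)) {
    add <- matrix(NA_real_, nrow(x_new), length(miss),
                  dimnames = list(rownames(x_new), miss))
    x_new <- cbind(x_new, add)
  }
  x <- x_new[, table$kept, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- table$medians[[colnames(x)[j]]]
  }
  x
}

fit_ridge <- function(x, y, lambda) {
  if (ncol(x) < 2L) {   # glmnet needs >= 2 columns; pad with a constant
    x <- cbind(x, .pad = 0)
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  list(fit = fit, center = ctr, scale = scl, lambda = lambda)
}

predict_ridge <- function(model, x) {
  if (".pad" %in% names(model$center) && !".pad" %in% colnames(x)) {
    x <- cbind(x, .pad = 0)
  }
  xs <- sweep(sweep(x[, names(model$center), drop = FALSE], 2,
                    model$center, "-"), 2, model$scale, "/")
  as.vector(stats::predict(model$fit, newx = xs, s = model$lambda,
                           type = "response"))
}

#' Train one base model on a feature table
#'
#' L2-regularised logistic regression on standardised features;
#' out-of-fold probabilities come from the table's shared stratified
#' 10-fold split, and the model is refit on all training samples for
#' later prediction. The training AUC is the out-of-fold AUC.
#'
#' @param table A `feature_table` from [assemble_feature_tables()].
#' @param labels 0/1 vector (1 = cancer), aligned with the table rows.
#' @param seed Seed (recorded; the fit itself is deterministic).
#' @param lambda Ridge penalty.
#' @return Object of class `base_model` with `oof_prob`, `auc`, the full
#'   refit, and the imputation/standardisation schema.
#' @export
train_base_model <- function(table, labels, seed = 1L, lambda = 0.1) {
  x <- table$x
  folds <- table$folds
  labels <- as.integer(labels)
  for (f in sort(unique(folds))) {
    tr <- labels[folds != f]
    if (sum(tr == 1L) < 2L || sum(tr == 0L) < 2L) {
      stop("fold ", f, " leaves fewer than 2 samples of one class; ",
           "re-stratify or reduce the fold count", call. = FALSE)
    }
  }
  oof <- rep(NA_real_, nrow(x))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    m <- fit_ridge(x[tr, , drop = FALSE], labels[tr], lambda)
    oof[!tr] <- predict_ridge(m, x[!tr, , drop = FALSE])
  }
  full <- fit_ridge(x, labels, lambda)
  structure(list(family = table$family, scope = table$scope,
                 fit = full, oof_prob = oof,
                 auc = auc_concordance(oof, labels),
                 folds = folds, labels = labels, seed = seed,
                 medians = table$medians, kept = table$kept,
                 table_schema = table[c("medians", "kept")]),
            class = "base_model")
}

# predict refit-on-full probabilities for new samples
predict_base <- function(model, x_new) {
  x <- apply_table_schema(model$table_schema, x_new)
  predict_ridge(model$fit, x)
}

#' Select the final base-model set
#'
#' For each of the BPM, EDM and FSR families, the genome-wide and the
#' MERGE-restricted candidate are compared on out-of-fold AUC and the
#' better one kept (ties break toward MERGE scope). The surviving EDM
#' model is then dropped when its AUC does not exceed the surviving BPM's
#' (the two motif families carry similar-dimensional information). FSD is
#' always retained.
#'
#' @param candidates Named list of `base_model`s keyed `bpm`, `edm`,
#'   `fsr`, `fsd` and optionally `mbpm`, `medm`, `mfsr`.
#' @return Ordered named list of the selected base models.
#' @export
select_base_models <- function(candidates) {
  pick <- function(genome, merge) {
    g <- candidates[[genome]]
    m <- candidates[[merge]]
    if (is.null(m)) return(g)
    if (is.null(g)) return(m)
    if (m$auc >= g$auc) m else g
  }
  bpm <- pick("bpm", "mbpm")
  edm <- pick("edm", "medm")
  fsr <- pick("fsr", "mfsr")
  fsd <- candidates[["fsd"]]
  if (is.null(bpm) || is.null(fsr) || is.null(fsd)) {
    stop("base-model selection needs BPM, FSR and FSD candidates",
         call. = FALSE)
  }
  out <- list(BPM = bpm)
  if (!is.null(edm) && edm$auc > bpm$auc) out$EDM <- edm
  out$FSR <- fsr
  out$FSD <- fsd
  out
}

#' Train the stacked extra-trees ensemble
#'
#' The stacker is an extremely-randomized-trees classifier (1000 trees,
#' depth 5, minimum node size 5, no bootstrap resampling) fitted on the
#' base models' out-of-fold probabilities. Cross-validated training scores
#' are produced by refitting the stacker over the shared 10-fold split.
#'
#' @param base_models Selected base models ([select_base_models()]).
#' @param labels 0/1 vector (1 = cancer).
#' @param seed Seed for the tree ensemble.
#' @param n_estimators,max_depth,min_samples_split Tree hyperparameters.
#' @param cutoff Decision cutoff on the MERGE score.
#' @return Object of class `ensemble_model` with the fitted stacker, the
#'   base models, cross-validated training scores (`cv_scores`) and their
#'   AUC (`cv_auc`).
#' @export
train_ensemble <- function(base_models, labels, seed = 1L,
                           n_estimators = 1000L, max_depth = 5L,
                           min_samples_split = 5L, cutoff = 0.5) {
  labels <- as.integer(labels)
  X <- vapply(base_models, function(m) m$oof_prob, numeric(length(labels)))
  colnames(X) <- names(base_models)
  if (any(vapply(base_models, function(m) !identical(m$folds,
                                                     base_models[[1]]$folds),
                 logical(1)))) {
    stop("base models do not share a fold assignment", call. = FALSE)
  }
  if (nrow(X) != length(labels)) {
    stop("mismatched sample sets across base models", call. = FALSE)
  }
  fit_et <- function(x, y, s) {
    ranger::ranger(x = as.data.frame(x),
                   y = factor(y, levels = c(0, 1)),
                   num.trees = n_estimators, max.depth = max_depth,
                   min.node.size = min_samples_split,
                   splitrule = "extratrees", num.random.splits = 1L,
                   replace = FALSE, sample.fraction = 1,
                   probability = TRUE, seed = s, num.threads = 1L)
  }
  stacker <- fit_et(X, labels, derive_seed(seed, "stacker"))
  folds <- base_models[[1]]$folds
  cv <- rep(NA_real_, length(labels))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    m <- fit_et(X[tr, , drop = FALSE], labels[tr],
                derive_seed(seed, paste0("cv", f)))
    cv[!tr] <- stats::predict(
      m, data = as.data.frame(X[!tr, , drop = FALSE]),
      num.threads = 1L)$predictions[, "1"]
  }
  structure(list(base_models = base_models, stacker = stacker,
                 base_order = names(base_models), cutoff = cutoff,
                 cv_scores = cv, cv_auc = auc_concordance(cv, labels),
                 labels = labels, seed = seed,
                 hyperparameters = list(n_estimators = n_estimators,
                                        max_depth = max_depth,
                                        min_samples_split = min_samples_split)),
            class = "ensemble_model")
}

#' MERGE scores and calls for new samples
#'
#' Runs each base model (refit on the full training set) on the sample's
#' feature family, stacks the probabilities through the tree ensemble, and
#' applies the decision cutoff (a score exactly at the cutoff calls
#' cancer).
#'
#' @param model An `ensemble_model`.
#' @param features Named list of sample x feature matrices; must contain
#'   one entry per base-model family key used at training (`BPM`, `EDM`,
#'   `FSR`, `FSD`).
#' @return `data.table` with `sample_id`, `score`, `call`.
#' @export
merge_score <- function(model, features) {
  miss <- setdiff(model$base_order, names(features))
  if (length(miss)) {
    stop("missing feature famil", if (length(miss) > 1) "ies: " else "y: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(features[[model$base_order[1]]])
  X <- matrix(NA_real_, n, length(model$base_order),
              dimnames = list(rownames(features[[model$base_order[1]]]),
                              model$base_order))
  for (k in model$base_order) {
    X[, k] <- predict_base(model$base_models[[k]], features[[k]])
  }
  score <- stats::predict(model$stacker, data = as.data.frame(X),
                          num.threads = 1L)$predictions[, "1"]
  data.table::data.table(sample_id = rownames(X), score = score,
                         call = ifelse(score >= model$cutoff,
                                       "cancer", "non-cancer"))
}

#' AUC as all-pairs concordance
#'
#' Probability that a random positive scores above a random negative,
#' ties counted one half (the Mann-Whitney construction of the AUC).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
auc_concordance <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Successes.
#' @param n Trials.
#' @param conf Confidence level.
#' @return Named vector `estimate`, `lower`, `upper`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # clamp away floating residue at the k = 0 / k = n boundaries
  c(estimate = p, lower = min(max(centre - half, 0), p),
    upper = max(min(centre + half, 1), p))
}

#' Classifier performance report
#'
#' Confusion counts at the cutoff; sensitivity, specificity, PPV and NPV
#' with Wilson 95% intervals; AUC with a stratified-bootstrap interval
#' (2000 replicates); optional DeLong comparison against a second score
#' vector (via pROC).
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels 0/1 vector (1 = cancer).
#' @param cutoff Decision cutoff (score >= cutoff calls cancer).
#' @param comparator Optional second score vector on the same samples.
#' @param n_boot Bootstrap replicates for the AUC interval.
#' @param seed Bootstrap seed.
#' @return Object of class `performance_report`.
#' @export
evaluate <- function(scores, labels, cutoff = 0.5, comparator = NULL,
                     n_boot = 2000L, seed = 1L) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    stop("evaluation needs at least one sample of each class", call. = FALSE)
  }
  call <- as.integer(scores >= cutoff)
  tp <- sum(call == 1L & labels == 1L)
  fp <- sum(call == 1L & labels == 0L)
  tn <- sum(call == 0L & labels == 0L)
  fn <- sum(call == 0L & labels == 1L)
  metr <- list(sensitivity = wilson_ci(tp, tp + fn),
               specificity = wilson_ci(tn, tn + fp),
               ppv = if (tp + fp > 0) wilson_ci(tp, tp + fp) else
                 c(estimate = NA, lower = NA, upper = NA),
               npv = if (tn + fn > 0) wilson_ci(tn, tn + fn) else
                 c(estimate = NA, lower = NA, upper = NA))
  auc <- auc_concordance(scores, labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  set.seed(derive_seed(seed, "bootstrap"))
  boot <- vapply(seq_len(n_boot), function(i) {
    bi <- c(sample(pos, length(pos), replace = TRUE),
            sample(neg, length(neg), replace = TRUE))
    auc_concordance(scores[bi], labels[bi])
  }, numeric(1))
  auc_ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  delong_p <- NA_real_
  if (!is.null(comparator)) {
    r1 <- pROC::roc(labels, scores, quiet = TRUE, direction = "<",
                    levels = c(0, 1))
    r2 <- pROC::roc(labels, comparator, quiet = TRUE, direction = "<",
                    levels = c(0, 1))
    delong_p <- pROC::roc.test(r1, r2, method = "delong")$p.value
  }
  structure(list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 metrics = metr, auc = auc,
                 auc_ci = c(lower = auc_ci[1], upper = auc_ci[2]),
                 delong_p = delong_p, cutoff = cutoff, n = length(labels)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("performance_report (n = %d, cutoff = %g)\n", x$n, x$cutoff))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$confusion["TP"],
              x$confusion["FP"], x$confusion["TN"], x$confusion["FN"]))
  for (m in names(x$metrics)) {
    v <- x$metrics[[m]]
    cat(sprintf("  %-12s %.3f (95%% CI %.3f-%.3f)\n", m, v["estimate"],
                v["lower"], v["upper"]))
  }
  cat(sprintf("  AUC          %.3f (95%% CI %.3f-%.3f)\n", x$auc,
              x$auc_ci["lower"], x$auc_ci["upper"]))
  if (!is.na(x$delong_p)) {
    cat(sprintf("  DeLong p vs comparator: %.4g\n", x$delong_p))
  }
  invisible(x)
}

performance_report_json <- function(report) {
  list(n = report$n, cutoff = report$cutoff,
       confusion = as.list(report$confusion),
       metrics = lapply(report$metrics, as.list),
       auc = report$auc, auc_ci = as.list(report$auc_ci),
       delong_p = if (is.na(report$delong_p)) NULL else report$delong_p)
}
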