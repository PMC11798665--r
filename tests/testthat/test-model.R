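# deterministic two-class feature generator with a controllable signal
sim_features <- function(n_per_class, p, delta, seed, prefix = "s") {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("%s%03d", prefix, 1:n),
                              sprintf("f%04d", 1:p)))
  labels <- rep(c(1L, 0L), each = n_per_class)
  x[labels == 1L, 1:min(5, p)] <- x[labels == 1L, 1:min(5, p)] + delta
  list(x = x, labels = labels,
       meta = data.table::data.table(
         sample_id = rownames(x), cohort = "train",
         label = ifelse(labels == 1L, "cancer", "benign"),
         stage = "", subtype = "none"))
}

test_that("table assembly imputes medians and shares fold assignments", {
  sf <- sim_features(20, 30, 1, seed = 1)
  sf$x[3, 7] <- NA
  sf$x[, 9] <- NA
  tabs <- assemble_feature_tables(list(bpm = sf$x, fsd = sf$x), sf$meta,
                                  seed = 42)
  expect_identical(tabs$bpm$folds, tabs$fsd$folds)
  expect_false(anyNA(tabs$bpm$x))
  expect_false("f0009" %in% colnames(tabs$bpm$x))   # all-missing dropped
  expect_equal(tabs$bpm$x[3, "f0007"],
               median(sf$x[-3, "f0007"], na.rm = TRUE), ignore_attr = TRUE)
  tabs2 <- assemble_feature_tables(list(bpm = sf$x), sf$meta, seed = 42)
  expect_identical(tabs$bpm$folds, tabs2$bpm$folds)  # seed-determined

  bad_meta <- data.table::rbindlist(list(
    sf$meta, list(sample_id = "ghost", cohort = "train", label = "benign",
                  stage = "", subtype = "none")))
  expect_error(assemble_feature_tables(list(bpm = sf$x), bad_meta, seed = 1),
               "ghost")
})

test_that("base models separate separable data and stay null on noise", {
  sep <- sim_features(30, 20, 3, seed = 11)
  tabs <- assemble_feature_tables(list(bpm = sep$x), sep$meta, seed = 11)
  bm <- train_base_model(tabs$bpm, sep$labels, seed = 11)
  expect_true(all(bm$oof_prob >= 0 & bm$oof_prob <= 1))
  expect_gte(bm$auc, 0.95)

  null <- sim_features(30, 20, 0, seed = 12)
  tabs0 <- assemble_feature_tables(list(bpm = null$x), null$meta, seed = 12)
  bm0 <- train_base_model(tabs0$bpm, null$labels, seed = 12)
  expect_gte(bm0$auc, 0.35)
  expect_lte(bm0$auc, 0.65)
})

test_that("base-model selection prefers MERGE scope and prunes EDM", {
  mk <- function(auc, family, scope) {
    structure(list(family = family, scope = scope, auc = auc,
                   oof_prob = rep(0.5, 10), folds = rep(1:5, 2)),
              class = "base_model")
  }
  cand <- list(bpm = mk(0.85, "BPM", "genome"),
               mbpm = mk(0.90, "BPM", "merge"),
               edm = mk(0.80, "EDM", "genome"),
               medm = mk(0.70, "EDM", "merge"),
               fsr = mk(0.75, "FSR", "genome"),
               mfsr = mk(0.88, "FSR", "merge"),
               fsd = mk(0.8, "FSD", "genome"))
  sel <- select_base_models(cand)
  expect_equal(sel$BPM$auc, 0.90)                  # mBPM beats BPM
  expect_false("EDM" %in% names(sel))              # EDM <= BPM dropped
  expect_equal(sel$FSR$auc, 0.88)
  expect_equal(names(sel), c("BPM", "FSR", "FSD"))

  cand$medm$auc <- 0.95
  sel2 <- select_base_models(cand)
  expect_equal(names(sel2), c("BPM", "EDM", "FSR", "FSD"))
  expect_equal(sel2$EDM$auc, 0.95)

  # AUC tie breaks toward MERGE scope
  cand$mbpm$auc <- 0.85
  expect_equal(select_base_models(cand)$BPM$scope, "merge")

  # missing MERGE candidates fall back to genome scope
  sel3 <- select_base_models(cand[c("bpm", "edm", "fsr", "fsd")])
  expect_equal(sel3$BPM$scope, "genome")
})

test_that("ensemble stacking is deterministic and tracks its inputs", {
  sep <- sim_features(30, 10, 2.5, seed = 21)
  tabs <- assemble_feature_tables(list(bpm = sep$x, fsr = sep$x + 1,
                                       fsd = sep$x * 2),
                                  sep$meta, seed = 21)
  bms <- lapply(tabs, train_base_model, labels = sep$labels, seed = 21)
  sel <- select_base_models(bms)
  e1 <- train_ensemble(sel, sep$labels, seed = 21)
  e2 <- train_ensemble(sel, sep$labels, seed = 21)
  expect_identical(e1$cv_scores, e2$cv_scores)
  expect_gte(e1$cv_auc, 0.9)                       # separable input
  expect_true(all(e1$cv_scores >= 0 & e1$cv_scores <= 1))

  null <- sim_features(30, 10, 0, seed = 22)
  tabs0 <- assemble_feature_tables(list(bpm = null$x, fsr = null$x[, 1:5],
                                        fsd = null$x[, 6:10]),
                                   null$meta, seed = 22)
  bms0 <- lapply(tabs0, train_base_model, labels = null$labels, seed = 22)
  e0 <- train_ensemble(select_base_models(bms0), null$labels, seed = 22)
  expect_gte(e0$cv_auc, 0.35)
  expect_lte(e0$cv_auc, 0.65)
})

test_that("merge_score applies the 0.5 cutoff with >= convention", {
  sep <- sim_features(30, 10, 2.5, seed = 31)
  tabs <- assemble_feature_tables(list(bpm = sep$x, fsr = sep$x,
                                       fsd = sep$x), sep$meta, seed = 31)
  bms <- lapply(tabs, train_base_model, labels = sep$labels, seed = 31)
  ens <- train_ensemble(select_base_models(bms), sep$labels, seed = 31)
  new <- sim_features(10, 10, 2.5, seed = 32, prefix = "v")
  feats <- list(BPM = new$x, FSR = new$x, FSD = new$x)
  sc <- merge_score(ens, feats)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_identical(sc$call, ifelse(sc$score >= 0.5, "cancer", "non-cancer"))
  expect_gte(auc_concordance(sc$score, new$labels), 0.9)
  expect_error(merge_score(ens, feats[c("BPM", "FSR")]), "FSD")
})

test_that("AUC equals all-pairs concordance with half ties", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    pairs <- 0; wins <- 0
    for (i1 in which(labels == 1L)) for (j in which(labels == 0L)) {
      pairs <- pairs + 1
      wins <- wins + (scores[i1] > scores[j]) + 0.5 * (scores[i1] == scores[j])
    }
    expect_identical(auc_concordance(scores, labels), wins / pairs)
  }
  expect_equal(auc_concordance(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
})

test_that("AUC matches pROC on tie-free scores", {
  set.seed(43)
  labels <- rep(c(1L, 0L), each = 25)
  scores <- rnorm(50) + labels
  expect_equal(auc_concordance(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))))
})

test_that("Wilson CI matches an independent score-equation solver", {
  # oracle: endpoints are the roots of (p-hat - p)^2 = z^2 p(1-p)/n
  wilson_oracle <- function(k, n, conf = 0.95) {
    z <- qnorm(1 - (1 - conf) / 2)
    ph <- k / n
    f <- function(p) (ph - p)^2 - z^2 * p * (1 - p) / n
    # p-hat itself is a root of the score equation, so bracket strictly
    # inside (0, ph) and (ph, 1); at the boundaries the endpoint is exact
    lo <- if (k == 0) 0 else
      uniroot(f, c(1e-9, ph * (1 - 1e-9)), tol = 1e-14)$root
    hi <- if (k == n) 1 else
      uniroot(f, c(ph + (1 - ph) * 1e-9, 1 - 1e-9), tol = 1e-14)$root
    c(lower = lo, upper = hi)
  }
  set.seed(44)
  for (i in 1:100) {
    n <- sample(5:500, 1)
    k <- sample(0:n, 1)
    got <- wilson_ci(k, n)
    want <- wilson_oracle(k, n)
    expect_equal(unname(got[c("lower", "upper")]), unname(want),
                 tolerance = 1e-8)
    expect_gte(got["estimate"], got["lower"])
    expect_lte(got["estimate"], got["upper"])
  }
  expect_equal(unname(wilson_ci(9, 10)["estimate"]), 0.9)
})

test_that("evaluation reports confusion metrics, bootstrap CI and DeLong", {
  set.seed(45)
  labels <- rep(c(1L, 0L), each = 30)
  scores <- plogis(rnorm(60) + 2 * labels - 1)
  rep1 <- evaluate(scores, labels, n_boot = 200, seed = 9)
  cm <- rep1$confusion
  expect_equal(unname(cm["TP"] + cm["FN"]), 30)
  expect_equal(unname(rep1$metrics$sensitivity["estimate"]),
               unname(cm["TP"] / (cm["TP"] + cm["FN"])))
  expect_true(rep1$auc_ci["lower"] <= rep1$auc &
                rep1$auc <= rep1$auc_ci["upper"])
  rep2 <- evaluate(scores, labels, comparator = runif(60),
                   n_boot = 100, seed = 9)
  expect_true(rep2$delong_p >= 0 && rep2$delong_p <= 1)
  expect_error(evaluate(scores[labels == 1], labels[labels == 1]),
               "each class")
})
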