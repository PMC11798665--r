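# Rank-based differential statistics per gene and omics layer, plus the
# descriptive profiling tools: percentile profiles, 500 bp hotspot scans,
# and subtype profile distances.

#' Mann-Whitney U statistic with normal-approximation Z
#'
#' `U` is the mid-rank sum of group 1 minus `n1(n1+1)/2`;
#' `Z = (U - n1*n2/2) / sqrt(n1*n2*(n1+n2+1)/12)` (no tie correction by
#' default, matching the printed formula; set `tie_correction = TRUE` for
#' the tie-adjusted variance). Positive Z means group 1 (cancer) is shifted
#' high. The two-sided p-value uses the normal approximation.
#'
#' @param values1,values2 Numeric vectors; `NA`s are removed within each
#'   group.
#' @param tie_correction Use the tie-corrected variance.
#' @return List with `U`, `Z`, `p`, `n1`, `n2` (all `NA` when a group is
#'   empty after missing-value removal).
#' @export
mann_whitney_z <- function(values1, values2, tie_correction = FALSE) {
  x <- values1[!is.na(values1)]
  y <- values2[!is.na(values2)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) {
    return(list(U = NA_real_, Z = NA_real_, p = NA_real_, n1 = n1, n2 = n2))
  }
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (tie_correction) {
    n <- n1 + n2
    tie <- table(c(x, y))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1))))
  } else {
    sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  }
  Z <- if (sigma > 0) (U - mu) / sigma else 0
  list(U = U, Z = Z, p = 2 * stats::pnorm(-abs(Z)), n1 = n1, n2 = n2)
}

#' The three case-control comparison designs
#'
#' @param name One of `cancer_vs_benign`, `cancer_vs_healthy`,
#'   `cancer_vs_noncancer`.
#' @return List with `name`, `group1` (label set), `group2`.
#' @export
comparison_spec <- function(name = c("cancer_vs_benign", "cancer_vs_healthy",
                                     "cancer_vs_noncancer")) {
  name <- match.arg(name)
  group2 <- switch(name,
                   cancer_vs_benign = "benign",
                   cancer_vs_healthy = "healthy",
                   cancer_vs_noncancer = c("benign", "healthy"))
  list(name = name, group1 = "cancer", group2 = group2)
}

#' Median-of-ratios sample normalisation
#'
#' DESeq-style size factors: each sample is divided by the median of its
#' gene-wise ratios to the geometric-mean reference profile (genes with a
#' zero anywhere are excluded from the reference).
#'
#' @param mat genes x samples matrix of nonnegative values.
#' @return Matrix of the same shape, normalised.
#' @export
median_ratio_normalize <- function(mat) {
  lg <- log(mat)
  lg[!is.finite(lg)] <- NA
  ref <- rowMeans(lg, na.rm = FALSE)          # geometric mean, complete genes
  use <- is.finite(ref)
  if (!any(use)) return(mat)
  sf <- apply(lg[use, , drop = FALSE] - ref[use], 2,
              stats::median, na.rm = TRUE)
  sweep(mat, 2, exp(sf), "/")
}

#' Per-gene rank differential for one omics layer
#'
#' Genes with detectable signal (non-missing and nonzero) in fewer than
#' `min_detectable` of the comparison's samples are dropped. Each surviving
#' gene gets a Mann-Whitney U/Z/p ([mann_whitney_z()]); p-values are
#' BH-adjusted within this (layer, comparison) batch.
#'
#' @param mat genes x samples matrix (rownames = gene ids, colnames =
#'   sample ids).
#' @param meta Sample metadata ([read_sample_meta()]).
#' @param spec A [comparison_spec()].
#' @param layer Layer tag (`h3k4me3`, `methylation`, `ndr`).
#' @param min_detectable Detectability threshold (samples).
#' @return `data.table`: `gene_id`, `layer`, `comparison`, `u_statistic`,
#'   `z_score`, `p_value`, `p_adj`, `direction`, `n1`, `n2`.
#' @export
layer_differential <- function(mat, meta, spec, layer,
                               min_detectable = 10L) {
  s1 <- meta$sample_id[meta$label %in% spec$group1]
  s2 <- meta$sample_id[meta$label %in% spec$group2]
  s1 <- intersect(s1, colnames(mat))
  s2 <- intersect(s2, colnames(mat))
  if (length(s1) == 0L || length(s2) == 0L) {
    stop("comparison '", spec$name, "' has an empty group in the data",
         call. = FALSE)
  }
  sub <- mat[, c(s1, s2), drop = FALSE]
  detect <- rowSums(!is.na(sub) & sub != 0)
  keep <- which(detect >= min_detectable)
  res <- lapply(keep, function(i) {
    mw <- mann_whitney_z(mat[i, s1], mat[i, s2])
    data.table::data.table(gene_id = rownames(mat)[i],
                           u_statistic = mw$U, z_score = mw$Z,
                           p_value = mw$p, n1 = mw$n1, n2 = mw$n2)
  })
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L) {
    return(data.table::data.table(gene_id = character(), layer = character(),
                                  comparison = character(),
                                  u_statistic = numeric(),
                                  z_score = numeric(), p_value = numeric(),
                                  p_adj = numeric(), direction = character(),
                                  n1 = integer(), n2 = integer()))
  }
  out[, layer := layer]
  out[, comparison := spec$name]
  out[, p_adj := stats::p.adjust(p_value, method = "BH")]
  out[, direction := ifelse(z_score > 0, "up", "down")]
  data.table::setcolorder(out, c("gene_id", "layer", "comparison",
                                 "u_statistic", "z_score", "p_value",
                                 "p_adj", "direction", "n1", "n2"))
  out[]
}

#' Percentile profile of companion features along a ranking
#'
#' Genes are sorted by the ranking value from highest to lowest and split
#' into `n_groups` near-equal groups (sizes differ by at most one); each
#' companion feature is averaged within every group.
#'
#' @param ranking Named numeric vector (one value per gene).
#' @param companions Matrix (genes x features) or named list of vectors,
#'   indexed by the same gene ids.
#' @param n_groups Number of groups (100 percentiles by default).
#' @return `data.table` with `group` (1 = highest ranking values),
#'   `n_genes`, mean ranking value, and one column per companion feature.
#' @export
percentile_profile <- function(ranking, companions, n_groups = 100L) {
  ranking <- ranking[!is.na(ranking)]
  if (length(ranking) < n_groups) {
    stop("only ", length(ranking), " genes with ranking values; use fewer ",
         "than ", n_groups, " groups", call. = FALSE)
  }
  if (is.list(companions)) companions <- do.call(cbind, companions)
  ord <- names(sort(ranking, decreasing = TRUE))
  n <- length(ord)
  sizes <- rep(n %/% n_groups, n_groups)
  extra <- n %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp <- rep(seq_len(n_groups), times = sizes)
  cm <- companions[ord, , drop = FALSE]
  out <- data.table::data.table(group = seq_len(n_groups),
                                n_genes = sizes,
                                ranking_mean = as.vector(
                                  rowsum(ranking[ord], grp) / sizes))
  for (j in colnames(cm)) {
    out[[j]] <- as.vector(rowsum(cm[, j], grp) / sizes)
  }
  out
}

#' Hotspot scan over fixed-size bins
#'
#' Per bin, the difference between the pooled-cancer and the
#' pooled-noncancer value; a bin is flagged when its absolute difference
#' exceeds twice the standard deviation of all (non-missing) bin
#' differences in the scan. Bins missing in either pooled group are
#' excluded from the SD.
#'
#' @param bin_ids Bin identifiers.
#' @param values_group1,values_group2 Pooled per-bin values (cancer /
#'   non-cancer), computed from the concatenated fragments of each group.
#' @return `data.table` with `bin_id`, `difference`, `flagged`, plus the
#'   scan SD as attribute `sigma`.
#' @export
hotspot_scan <- function(bin_ids, values_group1, values_group2) {
  stopifnot(length(bin_ids) == length(values_group1),
            length(values_group1) == length(values_group2))
  d <- values_group1 - values_group2
  sigma <- stats::sd(d[!is.na(d)])
  if (is.na(sigma)) sigma <- 0
  out <- data.table::data.table(bin_id = bin_ids, difference = d,
                                flagged = !is.na(d) & abs(d) > 2 * sigma)
  data.table::setattr(out, "sigma", sigma)
  out[]
}

#' Subtype profile correlation and distance matrices
#'
#' Pairwise Pearson correlation and Euclidean distance between per-subtype
#' mean profiles over a shared gene index.
#'
#' @param profiles genes x subtypes numeric matrix.
#' @return List with `correlation` and `distance` (symmetric matrices).
#' @export
subtype_profile_distance <- function(profiles) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2L)
  r <- suppressWarnings(stats::cor(profiles, method = "pearson"))
  diag(r) <- 1
  d <- as.matrix(stats::dist(t(profiles), method = "euclidean"))
  list(correlation = r, distance = d)
}
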