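# MERGE selection: integrate rank-differential evidence across the three
# epigenomic layers and three comparison designs into the set of
# multi-epigenetically regulated genes.

#' Biological state implied by a (layer, direction) result
#'
#' Gene activation is implied by H3K4me3 up, promoter methylation down, or
#' NDR score down (deeper promoter depletion); the mirror combinations
#' imply repression.
#'
#' @param layer `h3k4me3`, `methylation` or `ndr`.
#' @param direction `up` or `down` (sign of the cancer-vs-control Z).
#' @return `"activated"` or `"repressed"` (vectorised).
#' @export
implied_state <- function(layer, direction) {
  known <- c("h3k4me3", "methylation", "ndr")
  if (any(!layer %in% known)) {
    stop("unknown layer: ", setdiff(layer, known)[1], call. = FALSE)
  }
  stopifnot(all(direction %in% c("up", "down")))
  act <- (layer == "h3k4me3" & direction == "up") |
    (layer %in% c("methylation", "ndr") & direction == "down")
  ifelse(act, "activated", "repressed")
}

#' Select multi-epigenetically regulated genes (MERGEs)
#'
#' A gene enters the MERGE set when it carries at least two significant
#' (BH-adjusted p < `alpha`) differential results — across layers,
#' comparisons, or both — whose implied biological states all agree.
#' Genes with conflicting significant states are excluded outright.
#'
#' @param results Row-bound [layer_differential()] output across the
#'   layer x comparison grid.
#' @param alpha Significance threshold on `p_adj`.
#' @return Object of class `merge_set`: `genes` (`gene_id`, `state`,
#'   `n_evidence`, `evidence` string), `evidence` (the retained significant
#'   rows), `layer_pairs` (gene counts with significant evidence in both
#'   layers of each pair and in all three), `per_comparison` counts, and
#'   `alpha`.
#' @export
select_merges <- function(results, alpha = 0.05) {
  empty <- data.table::data.table(gene_id = character(), state = character(),
                                  n_evidence = integer(),
                                  evidence = character())
  if (is.null(results) || nrow(results) == 0L) {
    return(structure(list(genes = empty, evidence = results,
                          layer_pairs = integer(), per_comparison = integer(),
                          alpha = alpha), class = "merge_set"))
  }
  sig <- results[!is.na(results$p_adj) & results$p_adj < alpha, ]
  if (nrow(sig) > 0L) {
    sig <- data.table::as.data.table(sig)
    sig[, state := implied_state(layer, direction)]
    byg <- sig[, .(n_evidence = .N,
                   n_states = data.table::uniqueN(state),
                   state = state[1],
                   evidence = paste(sprintf("%s:%s:%s", layer, comparison,
                                            direction), collapse = ";")),
               by = gene_id]
    genes <- byg[n_evidence >= 2L & n_states == 1L,
                 .(gene_id, state, n_evidence, evidence)]
  } else {
    genes <- empty
  }
  data.table::setorder(genes, gene_id)
  ev <- sig[sig$gene_id %in% genes$gene_id, ]
  layer_sets <- if (nrow(ev)) {
    split(ev$layer, ev$gene_id)
  } else list()
  has <- function(lyrs) {
    sum(vapply(layer_sets, function(s) all(lyrs %in% s), logical(1)))
  }
  layer_pairs <- c(
    "h3k4me3+methylation" = has(c("h3k4me3", "methylation")),
    "h3k4me3+ndr" = has(c("h3k4me3", "ndr")),
    "methylation+ndr" = has(c("methylation", "ndr")),
    "all_three" = has(c("h3k4me3", "methylation", "ndr")))
  per_comparison <- if (nrow(ev)) {
    vapply(split(ev$gene_id, ev$comparison), data.table::uniqueN, integer(1))
  } else integer()
  structure(list(genes = genes, evidence = ev, layer_pairs = layer_pairs,
                 per_comparison = per_comparison, alpha = alpha),
            class = "merge_set")
}

#' @export
print.merge_set <- function(x, ...) {
  cat(sprintf("merge_set: %d genes (alpha = %g)\n", nrow(x$genes), x$alpha))
  if (nrow(x$genes)) {
    cat("  states:", paste(sprintf("%s=%d", names(table(x$genes$state)),
                                   table(x$genes$state)), collapse = ", "),
        "\n")
    cat("  layer pairs:", paste(sprintf("%s=%d", names(x$layer_pairs),
                                        x$layer_pairs), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write a MERGE set as TSV and capture-interval BED
#'
#' @param merge_set A `merge_set`.
#' @param annotations Annotation table (for capture intervals).
#' @param tsv_path,bed_path Output paths (either may be `NULL`).
#' @export
write_merge_set <- function(merge_set, annotations, tsv_path = NULL,
                            bed_path = NULL) {
  if (!is.null(tsv_path)) {
    data.table::fwrite(merge_set$genes, tsv_path, sep = "\t", quote = FALSE)
  }
  if (!is.null(bed_path)) {
    iv <- gene_capture_intervals(
      annotations[annotations$gene_id %in% merge_set$genes$gene_id, ])
    data.table::fwrite(iv[, c("chrom", "start", "end", "gene_id")],
                       bed_path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
  invisible(merge_set)
}
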