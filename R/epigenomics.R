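# Cell-free epigenomic layers at gene resolution: cfChIP-seq promoter
# H3K4me3 RPKM with sample-level QC, cfRRBS promoter methylation, and the
# TSS nucleosome-depleted-region (NDR) score from lpWGS coverage.

#' cfChIP-seq sample QC
#'
#' A sample passes when it has at least 100,000 on-target reads AND an
#' on-target rate of at least 30%.
#'
#' @param on_target_reads,total_reads Read counts (deduplicated).
#' @param sample_id Optional identifier carried into the report.
#' @return List with `sample_id`, `on_target_reads`, `on_target_rate`,
#'   `pass`.
#' @export
chip_sample_qc <- function(on_target_reads, total_reads, sample_id = NA) {
  stopifnot(on_target_reads >= 0, total_reads >= on_target_reads)
  rate <- if (total_reads > 0) on_target_reads / total_reads else NA_real_
  pass <- !is.na(rate) && on_target_reads >= 1e5 && rate >= 0.30
  list(sample_id = sample_id, on_target_reads = on_target_reads,
       on_target_rate = rate, pass = pass)
}

#' Promoter RPKM
#'
#' `rpkm = count / (length_kb * total_mapped_millions)`. The library size
#' is the sample's total deduplicated mapped read count.
#'
#' @param counts Per-promoter read counts.
#' @param lengths_bp Promoter lengths in bp (> 0).
#' @param total_mapped_reads Library size (> 0).
#' @return Numeric vector of RPKM values.
#' @export
promoter_rpkm <- function(counts, lengths_bp, total_mapped_reads) {
  if (total_mapped_reads <= 0) stop("total_mapped_reads must be > 0",
                                    call. = FALSE)
  stopifnot(all(lengths_bp > 0))
  counts / ((lengths_bp / 1e3) * (total_mapped_reads / 1e6))
}

#' Mean promoter CpG methylation
#'
#' Unweighted mean of the per-CpG methylation ratios falling inside the
#' half-open promoter interval. Missing when the promoter holds no CpG.
#'
#' @param calls Methylation calls ([read_methylation()]).
#' @param chrom,start,end Promoter interval (0-based half-open).
#' @return List with `meth_ratio` and `n_cpg`.
#' @export
promoter_methylation <- function(calls, chrom, start, end) {
  sel <- calls$chrom == chrom & calls$pos >= start & calls$pos < end
  n <- sum(sel)
  list(meth_ratio = if (n > 0) mean(calls$ratio[sel]) else NA_real_,
       n_cpg = n)
}

# vectorised promoter methylation over all genes (promoters assumed
# disjoint within a chromosome, as in the bundled annotation layouts)
promoter_methylation_all <- function(calls, annotations) {
  iv <- data.table::data.table(chrom = annotations$chrom,
                               start = annotations$promoter_start,
                               end = annotations$promoter_end)
  idx <- assign_point_to_intervals(calls$chrom, calls$pos, iv)
  n <- tabulate(idx, nbins = nrow(iv))
  s <- rep(0, nrow(iv))
  ok <- !is.na(idx)
  if (any(ok)) {
    agg <- rowsum(calls$ratio[ok], group = idx[ok])
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  data.table::data.table(gene_id = annotations$gene_id,
                         meth_ratio = ifelse(n > 0, s / n, NA_real_),
                         n_cpg = as.integer(n))
}

assign_point_to_intervals <- function(chrom, pos, intervals) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(intervals$chrom)) {
    rows <- which(intervals$chrom == ch)
    iv <- intervals[rows, ]
    o <- order(iv$start)
    iv <- iv[o, ]
    sel <- which(chrom == ch)
    j <- findInterval(pos[sel], iv$start)
    inside <- j >= 1L & pos[sel] < iv$end[pmax(j, 1L)]
    idx[sel[inside]] <- rows[o][j[inside]]
  }
  idx
}

#' TSS nucleosome-depleted-region score
#'
#' Mean raw coverage over the promoter window (-150 to +50 bp relative to
#' the TSS, in gene orientation) divided by the mean coverage of the pooled
#' upstream (-2000 to -1000) and downstream (+1000 to +2000) flanks. Lower
#' scores indicate deeper nucleosome depletion. Windows are half-open in
#' gene-orientation offsets; bins are selected by their centre offset, so
#' the computation is exact for tracks whose step divides 50 and aligns
#' with the TSS grid.
#'
#' @param coverage `data.frame` with columns `start`, `end` (0-based
#'   half-open bins of one fixed step) and `value` (raw read coverage),
#'   spanning at least `[tss - 2000, tss + 2000)`.
#' @param tss 0-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @return Score (>= 0), or `NA` when the pooled flank mean is zero or a
#'   window holds no bins.
#' @export
tss_ndr_score <- function(coverage, tss, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  centre <- (coverage$start + coverage$end) / 2
  off <- if (strand == "+") centre - tss else tss - centre
  prom <- off >= -150 & off < 50
  flank <- (off >= -2000 & off < -1000) | (off >= 1000 & off < 2000)
  if (!any(prom) || !any(flank)) return(NA_real_)
  fl <- mean(coverage$value[flank])
  if (fl == 0) return(NA_real_)
  mean(coverage$value[prom]) / fl
}

#' Read a fixed-step coverage track (bedGraph)
#'
#' @param path Tab-separated chrom, start, end, value (no header).
#' @return `data.table` with those columns.
#' @export
read_coverage <- function(path) {
  dt <- fread_auto(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 4L) stop("bedGraph needs 4 columns", call. = FALSE)
  dt <- dt[, 1:4]
  data.table::setnames(dt, c("chrom", "start", "end", "value"))
  if (any(dt$value < 0)) stop("negative coverage value", call. = FALSE)
  dt[]
}

# NDR scores for all genes from one fixed-step track. Bins are assigned to
# genes by centre position over the (disjoint) [tss-2000, tss+2000) spans,
# then promoter/flank means are aggregated in one grouped pass.
ndr_score_table <- function(coverage, annotations) {
  iv <- data.table::data.table(chrom = annotations$chrom,
                               start = annotations$tss - 2000L,
                               end = annotations$tss + 2000L)
  centre <- (coverage$start + coverage$end) / 2
  gi <- assign_point_to_intervals(coverage$chrom, centre, iv)
  ok <- !is.na(gi)
  scores <- rep(NA_real_, nrow(annotations))
  if (!any(ok)) return(scores)
  gi <- gi[ok]
  off <- centre[ok] - annotations$tss[gi]
  off <- ifelse(annotations$strand[gi] == "+", off, -off)
  val <- coverage$value[ok]
  prom <- off >= -150 & off < 50
  flank <- (off >= -2000 & off < -1000) | (off >= 1000 & off < 2000)
  pm <- group_mean(val[prom], gi[prom], nrow(annotations))
  fm <- group_mean(val[flank], gi[flank], nrow(annotations))
  has <- !is.na(pm) & !is.na(fm) & fm > 0
  scores[has] <- pm[has] / fm[has]
  scores
}

group_mean <- function(x, g, n) {
  cnt <- tabulate(g, nbins = n)
  s <- rep(0, n)
  if (length(x)) {
    agg <- rowsum(x, group = g)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  ifelse(cnt > 0, s / cnt, NA_real_)
}
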