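# Fragment-level features: end/breakpoint motifs, size ratios and
# distributions, motif entropy, nuclease F-profile deconvolution, and
# gene-level aggregates.
#
# Motif convention: both fragment ends contribute, each read 5'->3' on its
# own strand. The plus-strand end is the k bases from `start` forward; the
# minus-strand end is the reverse complement of the k bases ending at
# `end - 1`. Motifs containing N are never counted.

new_motif_profile <- function(counts, k, n_skipped = 0L) {
  total <- sum(counts)
  freq <- if (total > 0) counts / total else counts * 0
  structure(list(k = k, counts = counts, frequencies = freq,
                 n_motifs = total, n_skipped = n_skipped),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("motif_profile: k=%d, %d motifs counted, %d skipped\n",
              x$k, x$n_motifs, x$n_skipped))
  invisible(x)
}

# pull both 5' terminal windows for every fragment: the plus end as
# [start + off5, start + off3) and the minus end from the precomputed
# reverse-complemented chromosome. Offsets are relative to the breakpoint
# (0 = first base inside the fragment); off5 may be negative (upstream of
# the breakpoint). Returns character vector of motifs; out-of-range
# windows are dropped and counted.
extract_break_motifs <- function(fragments, genome, off5, off3) {
  stopifnot(inherits(genome, "ref_genome"))
  width <- off3 - off5
  motifs <- vector("list", 2L * length(unique(fragments$chrom)))
  skipped <- 0L
  i <- 0L
  for (ch in unique(fragments$chrom)) {
    if (!ch %in% names(genome$seq)) {
      stop("fragment chromosome absent from genome: ", ch, call. = FALSE)
    }
    L <- genome$lengths[[ch]]
    fr <- fragments[fragments$chrom == ch, ]
    # plus-strand breakpoint p = start: window [p+off5, p+off3)
    a <- fr$start + off5
    b <- fr$start + off3
    ok <- a >= 0L & b <= L
    skipped <- skipped + sum(!ok)
    i <- i + 1L
    motifs[[i]] <- substring(genome$seq[[ch]], a[ok] + 1L, b[ok])
    # minus-strand breakpoint p = end-1: same offsets on the minus strand,
    # i.e. rc coordinates [L-end+off5, L-end+off3)
    a2 <- L - fr$end + off5
    b2 <- L - fr$end + off3
    ok2 <- a2 >= 0L & b2 <= L
    skipped <- skipped + sum(!ok2)
    i <- i + 1L
    motifs[[i]] <- substring(genome$rc[[ch]], a2[ok2] + 1L, b2[ok2])
  }
  out <- unlist(motifs, use.names = FALSE)
  attr(out, "n_skipped") <- skipped
  attr(out, "k") <- width
  out
}

count_motifs <- function(motifs, k, n_skipped = 0L) {
  alpha <- kmer_alphabet(k)
  idx <- match(motifs, alpha)   # motifs containing N don't match -> dropped
  counts <- tabulate(idx[!is.na(idx)], nbins = length(alpha))
  names(counts) <- alpha
  new_motif_profile(counts, k, n_skipped = n_skipped)
}

#' End-motif profile of a fragment set
#'
#' Each fragment contributes its two 5' terminal k-mers, read 5'->3' on the
#' end's own strand (the minus-strand end is reverse-complemented).
#' Frequencies sum to 1 whenever any motif was counted; k-mers containing N
#' are excluded.
#'
#' @param fragments Fragment table ([read_fragments()]).
#' @param genome A `ref_genome`.
#' @param k Motif length, 4 or 6 bp.
#' @return A `motif_profile`.
#' @export
end_motif_profile <- function(fragments, genome, k = 6L) {
  stopifnot(k %in% c(4L, 6L))
  m <- extract_break_motifs(fragments, genome, off5 = 0L, off3 = as.integer(k))
  if (attr(m, "n_skipped") > 0L) {
    warning(attr(m, "n_skipped"), " terminal window(s) off chromosome, skipped")
  }
  count_motifs(m, k, n_skipped = attr(m, "n_skipped"))
}

#' Breakpoint-motif profile (2+4 bp by default)
#'
#' The motif spans `up` bases 5' of each aligned 5' breakpoint and `down`
#' bases 3' of it, read from the reference on the breakpoint's strand. Both
#' breakpoints of every fragment are used.
#'
#' @inheritParams end_motif_profile
#' @param up,down Extension in bp outside / inside the fragment.
#' @return A `motif_profile` with `k = up + down`.
#' @export
breakpoint_motif_profile <- function(fragments, genome, up = 2L, down = 4L) {
  stopifnot(up >= 0L, down >= 1L, up + down <= 8L)
  m <- extract_break_motifs(fragments, genome, off5 = -as.integer(up),
                            off3 = as.integer(down))
  count_motifs(m, up + down, n_skipped = attr(m, "n_skipped"))
}

#' Tile a genome into fixed-size windows
#'
#' @param genome A `ref_genome`.
#' @param size Window size in bp (1 Mb default).
#' @return `data.table` with `window_id`, `chrom`, `start`, `end`.
#' @export
make_windows <- function(genome, size = 1e6) {
  out <- lapply(names(genome$seq), function(ch) {
    L <- genome$lengths[[ch]]
    starts <- seq(0L, L - 1L, by = as.integer(size))
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + as.integer(size), L))
  })
  dt <- data.table::rbindlist(out)
  dt[, window_id := sprintf("%s:%d-%d", chrom, start, end)]
  data.table::setcolorder(dt, c("window_id", "chrom", "start", "end"))
  dt[]
}

assign_to_intervals <- function(fragments, intervals) {
  # midpoint assignment; intervals must be disjoint within a chromosome
  mid <- (fragments$start + fragments$end) %/% 2L
  idx <- rep(NA_integer_, nrow(fragments))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, ]
    o <- order(iv$start)
    iv <- iv[o, ]
    sel <- which(fragments$chrom == ch)
    j <- findInterval(mid[sel], iv$start)
    inside <- j >= 1L & mid[sel] < iv$end[pmax(j, 1L)]
    idx[sel[inside]] <- which(intervals$chrom == ch)[o][j[inside]]
  }
  idx
}

#' Fragmentation size ratio per genomic window
#'
#' FSR = fraction of 151-220 bp fragments among all fragments assigned to
#' the window (midpoint assignment). Empty windows get a missing value.
#'
#' @param fragments Fragment table.
#' @param windows Window tiling ([make_windows()]).
#' @return `data.table` with `window_id`, `value`, `n_fragments`.
#' @export
fsr_per_window <- function(fragments, windows) {
  idx <- assign_to_intervals(fragments, windows)
  n <- tabulate(idx, nbins = nrow(windows))
  mono <- fragments$length >= 151L & fragments$length <= 220L
  k <- tabulate(idx[mono], nbins = nrow(windows))
  data.table::data.table(window_id = windows$window_id,
                         value = ifelse(n > 0, k / n, NA_real_),
                         n_fragments = n)
}

#' Fragmentation size distribution per chromosome arm
#'
#' Fragments of length 65-399 bp are binned into 67 half-open 5 bp bins
#' `[65,70), ..., [395,400)`; proportions are taken over the in-range
#' fragments assigned to each arm (midpoint assignment).
#'
#' @param fragments Fragment table.
#' @param arms `data.table` with `arm_id`, `chrom`, `start`, `end`
#'   partitioning the chromosomes.
#' @return List with `proportions` (arms x 67 matrix, rows `NA` when the
#'   arm holds no in-range fragment) and `n_fragments`.
#' @export
fsd_per_arm <- function(fragments, arms) {
  edges <- seq(65L, 400L, by = 5L)
  bins <- sprintf("len_%d_%d", edges[-length(edges)], edges[-1] - 1L)
  idx <- assign_to_intervals(fragments, arms)
  inrange <- fragments$length >= 65L & fragments$length < 400L
  sel <- inrange & !is.na(idx)
  bin <- (fragments$length[sel] - 65L) %/% 5L + 1L
  tab <- matrix(0, nrow(arms), length(bins),
                dimnames = list(arms$arm_id, bins))
  if (any(sel)) {
    cnt <- table(factor(idx[sel], levels = seq_len(nrow(arms))),
                 factor(bin, levels = seq_along(bins)))
    tab[] <- as.numeric(cnt)
  }
  n <- rowSums(tab)
  prop <- tab / ifelse(n > 0, n, NA_real_)
  prop[n == 0, ] <- NA_real_
  list(proportions = prop, n_fragments = as.integer(n))
}

#' Shannon entropy of a 4-mer motif profile
#'
#' @param profile A `motif_profile` (or bare frequency vector) normalised
#'   to sum 1.
#' @return Entropy in bits, in `[0, 2k]`; `NA` for an empty profile.
#' @export
motif_entropy <- function(profile) {
  f <- if (inherits(profile, "motif_profile")) profile$frequencies else profile
  if (sum(f) == 0) return(NA_real_)
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' Nuclease F-profile contributions of a 4-mer profile
#'
#' Dot product of the observed 4-mer end-motif frequencies with each of the
#' six basis profiles (rows I-VI: DNASE1L3, DNASE1, DFFB, Non-DNase C-end,
#' Non-DNase G-end, Non-specific).
#'
#' @param profile A 4-mer `motif_profile` (or 256-vector of frequencies in
#'   lexicographic order).
#' @param F F-profile matrix from [fprofile_matrix()] or [read_fprofile()].
#' @return Named numeric of six contributions.
#' @export
fprofile_contributions <- function(profile, F = fprofile_matrix()) {
  f <- if (inherits(profile, "motif_profile")) profile$frequencies else profile
  if (ncol(F) != length(f)) {
    stop("dimension mismatch: profile has ", length(f), " motifs, F has ",
         ncol(F), " columns", call. = FALSE)
  }
  if (!is.null(names(f)) && !identical(colnames(F), names(f))) {
    stop("motif ordering of profile and F-profile matrix differ",
         call. = FALSE)
  }
  drop(F %*% f)
}

#' Strand-aware gene capture interval (gene body + 1500 bp upstream)
#'
#' @param annotations Annotation table ([read_annotations()]).
#' @param upstream Upstream extension in bp.
#' @return `data.table` with `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_capture_intervals <- function(annotations, upstream = 1500L) {
  data.table::data.table(
    gene_id = annotations$gene_id,
    chrom = annotations$chrom,
    start = ifelse(annotations$strand == "+",
                   pmax(annotations$body_start - upstream, 0L),
                   annotations$body_start),
    end = ifelse(annotations$strand == "+",
                 annotations$body_end,
                 annotations$body_end + upstream))
}

#' Gene-level fragmentomic features
#'
#' For each gene, the fragments whose midpoint falls inside the capture
#' interval (gene body plus 1500 bp strand-aware upstream) feed: the
#' proportion of short (<= 150 bp) and mononucleosomal (151-220 bp)
#' fragments, the 4-mer end-motif profile, its Shannon entropy, and the six
#' F-profile contributions. Overlapping genes each receive a copy of shared
#' fragments.
#'
#' @param fragments Fragment table.
#' @param annotations Annotation table.
#' @param genome A `ref_genome`.
#' @param F F-profile matrix.
#' @param upstream Upstream extension in bp.
#' @return List with `features` (one row per gene) and `motif_freq`
#'   (genes x 256 matrix of 4-mer frequencies).
#' @export
gene_fragment_features <- function(fragments, annotations, genome,
                                   F = fprofile_matrix(), upstream = 1500L) {
  iv <- gene_capture_intervals(annotations, upstream)
  alpha <- kmer_alphabet(4L)
  ng <- nrow(iv)
  feats <- data.table::data.table(
    gene_id = iv$gene_id, n_fragments = 0L,
    prop_short = NA_real_, prop_mono = NA_real_, entropy = NA_real_)
  contrib <- matrix(NA_real_, ng, nrow(F),
                    dimnames = list(iv$gene_id, rownames(F)))
  freq <- matrix(NA_real_, ng, length(alpha),
                 dimnames = list(iv$gene_id, alpha))
  mid <- (fragments$start + fragments$end) %/% 2L
  for (g in seq_len(ng)) {
    sel <- fragments$chrom == iv$chrom[g] & mid >= iv$start[g] &
      mid < iv$end[g]
    n <- sum(sel)
    feats$n_fragments[g] <- n
    if (n == 0L) next
    fr <- fragments[sel, ]
    feats$prop_short[g] <- mean(fr$length <= 150L)
    feats$prop_mono[g] <- mean(fr$length >= 151L & fr$length <= 220L)
    pr <- suppressWarnings(end_motif_profile(fr, genome, k = 4L))
    if (pr$n_motifs > 0L) {
      freq[g, ] <- pr$frequencies
      feats$entropy[g] <- motif_entropy(pr)
      contrib[g, ] <- fprofile_contributions(pr, F)
    }
  }
  out <- cbind(feats, data.table::as.data.table(contrib))
  list(features = out, motif_freq = freq)
}
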