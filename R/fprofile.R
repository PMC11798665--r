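# Six-row F-profile basis over the 256 4-mers. The published basis (fit to
# nuclease-knockout plasma) is external to this package; fprofile_matrix()
# builds a SYNTHETIC stand-in with the documented row labels and the broad
# qualitative end-base preferences attributed to each component (DNASE1L3
# C/CC-ends, DNASE1 T-rich ends, DFFB A-rich ends, the two non-DNase
# single-base components, and a uniform non-specific remainder). Supply the
# real basis through read_fprofile() for production use.

FPROFILE_LABELS <- c("DNASE1L3", "DNASE1", "DFFB", "Non-DNase C-end",
                     "Non-DNase G-end", "Non-specific")

#' Synthetic F-profile basis matrix
#'
#' A deterministic, clearly synthetic 6 x 256 basis with rows labelled
#' I-VI (DNASE1L3, DNASE1, DFFB, Non-DNase C-end, Non-DNase G-end,
#' Non-specific) over the lexicographic 4-mer alphabet. Each row sums to 1.
#' It is a placeholder with plausible first/second-base preferences, not
#' the published basis; use [read_fprofile()] to load a real one.
#'
#' @return 6 x 256 numeric matrix, rows = components, columns = 4-mers.
#' @export
fprofile_matrix <- function() {
  alpha <- kmer_alphabet(4L)
  b1 <- substr(alpha, 1, 1)
  b2 <- substr(alpha, 2, 2)
  w <- function(pref1, pref2 = NULL, strength1 = 6, strength2 = 2) {
    v <- rep(1, length(alpha))
    v[b1 %in% pref1] <- strength1
    if (!is.null(pref2)) v[b2 %in% pref2] <- v[b2 %in% pref2] * strength2
    v / sum(v)
  }
  F <- rbind(
    w("C", "C"),          # DNASE1L3: CC-end preference
    w("T", "A"),          # DNASE1: T-end preference
    w("A", "A"),          # DFFB: A-end preference
    w("C", NULL, 8),      # Non-DNase C-end
    w("G", NULL, 8),      # Non-DNase G-end
    rep(1 / length(alpha), length(alpha)))  # Non-specific: uniform
  dimnames(F) <- list(FPROFILE_LABELS, alpha)
  F
}

#' Read / write an F-profile matrix as labelled TSV
#'
#' Six rows labelled with the component names, 256 columns named by the
#' lexicographic 4-mers; each row must be a frequency vector summing to 1.
#'
#' @param path TSV path (first column = row label).
#' @return `read_fprofile`: the 6 x 256 matrix. `write_fprofile`: `path`.
#' @export
read_fprofile <- function(path) {
  dt <- fread_auto(path, header = TRUE, sep = "\t")
  F <- as.matrix(dt[, -1, with = FALSE])
  rownames(F) <- dt[[1]]
  if (!identical(sort(rownames(F)), sort(FPROFILE_LABELS))) {
    stop("F-profile rows must be exactly: ",
         paste(FPROFILE_LABELS, collapse = ", "), call. = FALSE)
  }
  F <- F[FPROFILE_LABELS, , drop = FALSE]
  if (!identical(colnames(F), kmer_alphabet(4L))) {
    stop("F-profile columns must be the lexicographic 4-mer alphabet",
         call. = FALSE)
  }
  rs <- rowSums(F)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("F-profile rows must each sum to 1", call. = FALSE)
  }
  F
}

#' @rdname read_fprofile
#' @param F 6 x 256 matrix to write.
#' @export
write_fprofile <- function(F, path) {
  dt <- data.table::data.table(component = rownames(F))
  dt <- cbind(dt, data.table::as.data.table(F))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
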