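# internal helpers shared across modules

#' @import data.table
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lexicographic k-mer alphabet over {A,C,G,T}
#'
#' @param k motif length in bp.
#' @return Character vector of the 4^k k-mers in lexicographic order.
#' @export
kmer_alphabet <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1L, k <= 8L)
  bases <- c("A", "C", "G", "T")
  out <- bases
  if (k > 1) {
    for (i in seq_len(k - 1L)) {
      out <- as.vector(t(outer(out, bases, paste0)))
    }
  }
  out
}

# reverse complement of a vector of fixed-length motifs (no Biostrings
# round-trip: used only on short vectors in tests/oracles; bulk paths use
# the precomputed reverse-complemented chromosome instead)
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# deterministic 31-bit sub-seed from a base seed and a string tag
# (polynomial rolling hash mod the Mersenne prime 2^31 - 1; exact in
# doubles since intermediates stay below 2^53)
derive_seed <- function(seed, tag) {
  p <- 2147483647
  h <- as.numeric(seed) %% p
  for (c in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + c) %% p
  }
  as.integer(h)
}

# shared stratified k-fold assignment (same folds for every feature family)
make_folds <- function(labels, k = 10L, seed = 1L) {
  stopifnot(k >= 2L)
  labels <- as.character(labels)
  fold <- integer(length(labels))
  set.seed(derive_seed(seed, "folds"))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# gzip-transparent fread (no external decompression dependency)
fread_auto <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    lines <- readLines(gzfile(path))
    if (length(lines) == 0L) {
      return(data.table::data.table())
    }
    data.table::fread(text = lines, ...)
  } else {
    data.table::fread(path, ...)
  }
}

stop_stage <- function(stage, msg) {
  stop(sprintf("[stage %s] %s", stage, msg), call. = FALSE)
}
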