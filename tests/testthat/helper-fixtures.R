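# Programmatic fixtures shared across the suite. Everything is built in
# code at test time; nothing binary ships with the package.

# a ref_genome from literal sequences (bypasses FASTA for hand-checkable
# toy cases)
toy_genome <- function(seqs) {
  seqs <- toupper(seqs)
  rc <- vapply(seqs, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1))
  names(rc) <- names(seqs)
  structure(list(seq = seqs, rc = rc, lengths = nchar(seqs)),
            class = "ref_genome")
}

random_genome <- function(len, chroms = "chr1", seed = 1) {
  set.seed(seed)
  seqs <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  toy_genome(seqs)
}

frag_table <- function(chrom, start, end) {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end),
                         length = as.integer(end - start))
}

random_fragments <- function(genome, n, seed = 1, min_len = 20L,
                             max_len = 60L) {
  set.seed(seed)
  ch <- sample(names(genome$seq), n, replace = TRUE)
  L <- genome$lengths[ch]
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- floor(runif(n, 10, L - len - 10))
  frag_table(ch, start, start + len)
}

# independent per-fragment string-scan oracle for end/breakpoint motifs:
# walks fragments one by one with base string ops and a hand-rolled
# reverse complement, never touching the package's extraction path
oracle_motif_counts <- function(fragments, genome, off5, off3) {
  k <- off3 - off5
  alpha <- kmer_alphabet(k)
  counts <- stats::setNames(rep(0L, length(alpha)), alpha)
  rcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  for (i in seq_len(nrow(fragments))) {
    ch <- fragments$chrom[i]
    seq <- genome$seq[[ch]]
    L <- nchar(seq)
    p <- fragments$start[i]               # plus-strand 5' breakpoint
    a <- p + off5; b <- p + off3
    if (a >= 0 && b <= L) {
      m <- substr(seq, a + 1, b)
      if (m %in% alpha) counts[m] <- counts[m] + 1L
    }
    q <- fragments$end[i] - 1L            # minus-strand 5' breakpoint
    a2 <- q - off3 + 1L; b2 <- q - off5 + 1L
    if (a2 >= 0 && b2 <= L) {
      m <- rcomp(substr(seq, a2 + 1, b2))
      if (m %in% alpha) counts[m] <- counts[m] + 1L
    }
  }
  counts
}

# tiny cohort configuration for fast structural tests; ... overrides any
# default, including the ones set here
tiny_sim_config <- function(seed = 5, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_cancer = 20, n_benign = 10, n_healthy = 10,
         n_genes = 200, chrom_length = 4e5, fragments_per_sample = 4000,
         include_validation = FALSE),
    list(...))
  do.call(simulation_config, args)
}

# metadata table for in-memory differential tests
toy_meta <- function(n1, n2, labels2 = "benign", cohort = "train") {
  data.table::data.table(
    sample_id = sprintf("s%03d", seq_len(n1 + n2)),
    cohort = cohort,
    label = c(rep("cancer", n1), rep_len(labels2, n2)),
    stage = "", subtype = "none")
}
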