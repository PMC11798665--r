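test_that("end motifs read both 5' termini strand-aware", {
  g <- toy_genome(c(chr1 = "AACCGGTTAACCGGTT"))
  fr <- frag_table("chr1", 2, 10)
  pr <- end_motif_profile(fr, g, k = 4)
  # plus end = positions 2-5 "CCGG"; minus end = revcomp of 6-9 "TTAA"
  expect_equal(unname(pr$frequencies["CCGG"]), 0.5)
  expect_equal(unname(pr$frequencies["TTAA"]), 0.5)
  expect_equal(sum(pr$frequencies), 1)
})

test_that("terminal windows containing N contribute nothing", {
  g <- toy_genome(c(chr1 = "ANCCGGTTAACCGGTT"))
  fr <- frag_table("chr1", 0, 8)   # plus end "ANCC" has an N
  pr <- end_motif_profile(fr, g, k = 4)
  expect_equal(pr$n_motifs, 1L)    # only the minus end counted
  expect_equal(sum(pr$frequencies), 1)
})

test_that("breakpoint motifs span 2 bp out + 4 bp in on each strand", {
  g <- toy_genome(c(chr1 = "AACCGGTTAACC"))
  fr <- frag_table("chr1", 4, 10)
  pr <- breakpoint_motif_profile(fr, g, up = 2, down = 4)
  # plus breakpoint p=4: positions [2,8) = "CCGGTT"
  expect_gt(pr$frequencies[["CCGGTT"]], 0)
  # minus breakpoint p=9: revcomp of [6,12) = revcomp("TTAACC") = "GGTTAA"
  expect_gt(pr$frequencies[["GGTTAA"]], 0)
  expect_equal(sum(pr$frequencies), 1)
})

test_that("single-letter genome collapses breakpoint motifs per strand", {
  g <- toy_genome(c(chr1 = strrep("A", 2000)))
  fr <- random_fragments(g, 50, seed = 3)
  pr <- breakpoint_motif_profile(fr, g)
  # plus-strand breakpoints read A-runs; minus-strand breakpoints are
  # reverse-complemented, so an all-A genome yields exactly two motifs
  expect_equal(unname(pr$frequencies["AAAAAA"]), 0.5)
  expect_equal(unname(pr$frequencies["TTTTTT"]), 0.5)
  expect_equal(sum(pr$frequencies > 0), 2L)
})

test_that("motif extraction matches the string-scan oracle exactly", {
  for (seed in 1:12) {
    g <- random_genome(sample(c(2000, 5000, 10000), 1), seed = seed)
    fr <- random_fragments(g, 300, seed = seed + 100)
    for (spec in list(c(0, 4), c(0, 6), c(-2, 4))) {
      got <- if (spec[1] == 0) {
        end_motif_profile(fr, g, k = spec[2])
      } else {
        breakpoint_motif_profile(fr, g, up = -spec[1], down = spec[2])
      }
      want <- oracle_motif_counts(fr, g, spec[1], spec[2])
      expect_identical(unname(got$counts), unname(as.integer(want)))
      expect_equal(sum(got$frequencies), 1, tolerance = 1e-12)
    }
  }
})

test_that("pooled end-motif profile is invariant under genome mirroring", {
  g <- random_genome(4000, seed = 42)
  fr <- random_fragments(g, 400, seed = 43)
  pr <- end_motif_profile(fr, g, k = 4)
  L <- g$lengths[["chr1"]]
  g_rc <- toy_genome(c(chr1 = g$rc[["chr1"]]))
  fr_rc <- frag_table("chr1", L - fr$end, L - fr$start)
  pr_rc <- end_motif_profile(fr_rc, g_rc, k = 4)
  expect_equal(pr$counts, pr_rc$counts)
})

test_that("FSR is the mono-nucleosomal fraction per window", {
  g <- toy_genome(c(chr1 = strrep("A", 10000)))
  win <- make_windows(g, 10000)
  lens <- c(160, 200, 100, 300, 180)
  fr <- frag_table("chr1", seq(1000, by = 1000, length.out = 5),
                   seq(1000, by = 1000, length.out = 5) + lens)
  out <- fsr_per_window(fr, win)
  expect_equal(out$value, 3 / 5)
  expect_equal(out$n_fragments, 5L)

  all_mono <- frag_table("chr1", c(100, 300), c(260, 500))
  expect_equal(fsr_per_window(all_mono, win)$value, 1)
  empty <- frag_table(character(), integer(), integer())
  expect_true(is.na(fsr_per_window(empty, win)$value))
})

test_that("FSD bins 65-400 bp into 67 half-open 5 bp bins per arm", {
  arms <- data.table::data.table(arm_id = "chr1p", chrom = "chr1",
                                 start = 0L, end = 100000L)
  fr <- frag_table("chr1", c(100, 200, 300), c(166, 267, 371))
  out <- fsd_per_arm(fr, arms)
  expect_equal(ncol(out$proportions), 67L)
  expect_equal(unname(out$proportions[1, "len_65_69"]), 2 / 3)
  expect_equal(unname(out$proportions[1, "len_70_74"]), 1 / 3)
  expect_equal(sum(out$proportions[1, ]), 1)

  big <- frag_table("chr1", 100, 600)
  out2 <- fsd_per_arm(big, arms)
  expect_equal(out2$n_fragments, 0L)
  expect_true(all(is.na(out2$proportions[1, ])))
})

test_that("motif entropy hits its closed-form landmarks", {
  n <- 256
  uniform <- rep(1 / n, n)
  expect_identical(motif_entropy(uniform), 8)
  onehot <- c(1, rep(0, n - 1))
  expect_identical(motif_entropy(onehot), 0)
  two <- c(0.5, 0.5, rep(0, n - 2))
  expect_equal(motif_entropy(two), 1)
  expect_true(is.na(motif_entropy(rep(0, n))))
  set.seed(1)
  f <- runif(n); f <- f / sum(f)
  expect_gte(motif_entropy(f), 0)
  expect_lte(motif_entropy(f), 8)
})

test_that("F-profile contributions equal the brute-force dot product", {
  F <- fprofile_matrix()
  expect_equal(unname(rowSums(F)), rep(1, 6), tolerance = 1e-12)
  n <- ncol(F)
  uniformF <- matrix(1 / n, 6, n, dimnames = dimnames(F))
  f <- rep(1 / n, n)
  expect_equal(unname(fprofile_contributions(f, uniformF)), rep(1 / n, 6))

  onehot <- rep(0, n); onehot[37] <- 1
  expect_equal(unname(fprofile_contributions(onehot, F)), unname(F[, 37]))

  set.seed(9)
  f <- runif(n); f <- f / sum(f)
  brute <- vapply(1:6, function(i) {
    s <- 0
    for (m in seq_len(n)) s <- s + f[m] * F[i, m]
    s
  }, numeric(1))
  expect_equal(unname(fprofile_contributions(f, F)), brute,
               tolerance = 1e-12)
  expect_error(fprofile_contributions(rep(0.5, 2), F), "dimension mismatch")
})

test_that("F-profile matrix TSV round-trips", {
  F <- fprofile_matrix()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_fprofile(F, p)
  expect_equal(read_fprofile(p), F)
})

test_that("gene features count midpoint-captured fragments per gene", {
  g <- toy_genome(c(chr1 = strrep("ACGT", 5000)))
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t5000\t8000\tgA\t+", p)
  ann <- read_annotations(p)
  iv <- gene_capture_intervals(ann)
  expect_equal(iv$start, 3500L)  # 1500 bp upstream of a + gene
  expect_equal(iv$end, 8000L)

  fr <- frag_table("chr1", c(4000, 5000, 6000, 9000),
                   c(4100, 5160, 6300, 9100))
  out <- gene_fragment_features(fr, ann, g)
  expect_equal(out$features$n_fragments, 3L)
  expect_equal(out$features$prop_short, 1 / 3)
  expect_equal(out$features$prop_mono, 1 / 3)
  expect_equal(sum(out$motif_freq[1, ]), 1)

  none <- frag_table("chr1", 100, 300)
  out2 <- gene_fragment_features(none, ann, g)
  expect_equal(out2$features$n_fragments, 0L)
  expect_true(is.na(out2$features$prop_short))
})
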