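brute_force_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

test_that("Mann-Whitney U and Z match the printed formula", {
  r <- mann_whitney_z(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$U, 9)
  expect_equal(r$Z, (9 - 4.5) / sqrt(3 * 3 * 7 / 12))
  expect_equal(r$Z, 1.9640, tolerance = 1e-4)

  same <- mann_whitney_z(1:4, 1:4)
  expect_equal(same$U, 16 / 2)
  expect_equal(same$Z, 0)

  a <- c(2.3, 5.1, 0.4); b <- c(1.1, 7.7, 3.3, 2.2)
  expect_equal(mann_whitney_z(a, b)$Z, -mann_whitney_z(b, a)$Z)
})

test_that("U agrees with all-pairs enumeration incl. ties, Z with formula", {
  set.seed(202)
  for (i in 1:200) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    x <- sample(0:6, n1, replace = TRUE) + sample(c(0, 0.5), n1, TRUE)
    y <- sample(0:6, n2, replace = TRUE) + sample(c(0, 0.5), n2, TRUE)
    r <- mann_whitney_z(x, y)
    expect_identical(r$U, brute_force_u(x, y))
    z_ref <- (r$U - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    expect_equal(r$Z, z_ref, tolerance = 1e-12)
  }
})

test_that("U matches wilcox.test's W on tie-free data", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(9)
    expect_equal(mann_whitney_z(x, y)$U,
                 unname(wilcox.test(x, y)$statistic))
  }
})

test_that("layer differential filters undetectable genes and plants recover", {
  set.seed(31)
  n1 <- 30; n2 <- 30
  meta <- toy_meta(n1, n2)
  ng <- 60
  mat <- matrix(rnorm(ng * (n1 + n2)), ng,
                dimnames = list(sprintf("g%02d", 1:ng), meta$sample_id))
  # gene 1: planted strong up-shift in cancer
  mat[1, 1:n1] <- mat[1, 1:n1] + 5
  # gene 2: detectable in only 9 samples
  mat[2, ] <- 0
  mat[2, 1:9] <- rnorm(9) + 10
  res <- layer_differential(mat, meta, comparison_spec("cancer_vs_benign"),
                            "h3k4me3", min_detectable = 10)
  expect_false("g02" %in% res$gene_id)
  g1 <- res[res$gene_id == "g01", ]
  expect_equal(g1$direction, "up")
  expect_lt(g1$p_adj, 0.05)
  expect_equal(g1$n1, n1)
  # BH never inverts the p-value ordering
  o <- order(res$p_value)
  expect_true(all(diff(res$p_adj[o]) >= -1e-15))
})

test_that("permuted labels give ~5% raw positives", {
  set.seed(77)
  meta <- toy_meta(25, 25)
  ng <- 400
  mat <- matrix(rnorm(ng * 50), ng,
                dimnames = list(sprintf("g%03d", 1:ng), meta$sample_id))
  res <- layer_differential(mat, meta, comparison_spec("cancer_vs_benign"),
                            "ndr")
  frac <- mean(res$p_value < 0.05)
  band <- 3 * sqrt(0.05 * 0.95 / ng)
  expect_gt(frac, 0.05 - band)
  expect_lt(frac, 0.05 + band)
})

test_that("percentile profiling groups genes near-equally by rank", {
  set.seed(5)
  ng <- 250
  rk <- setNames(rnorm(ng), sprintf("g%03d", 1:ng))
  comp <- cbind(same = rk, const = rep(2, ng))
  rownames(comp) <- names(rk)
  pp <- percentile_profile(rk, comp, n_groups = 100)
  expect_equal(nrow(pp), 100L)
  expect_true(all(abs(diff(pp$n_genes)) <= 1))
  expect_equal(sum(pp$n_genes), ng)
  # a companion equal to the ranking is non-increasing across groups
  expect_true(all(diff(pp$same) <= 1e-12))
  expect_equal(pp$const, rep(2, 100))
  expect_error(percentile_profile(rk[1:50], comp[1:50, ]), "fewer")
})

test_that("hotspot scan flags |difference| > 2 sigma", {
  d1 <- rep(0.5, 10)
  out <- hotspot_scan(paste0("b", 1:10), d1, d1)
  expect_false(any(out$flagged))          # sigma = 0, all equal

  set.seed(8)
  g2 <- rnorm(1000, 0, 0.01)
  g1 <- g2
  g1[500] <- g2[500] + 10
  out2 <- hotspot_scan(paste0("b", 1:1000), g1, g2)
  sigma <- sd(g1 - g2)
  expect_equal(attr(out2, "sigma"), sigma)
  expect_true(out2$flagged[500])
  expect_equal(sum(out2$flagged), 1L)

  # adding a constant to one group shifts differences but sigma-centered
  # flags stay put only under centering of the flag rule; here the rule is
  # on raw |difference|, so we check invariance of sigma instead
  out3 <- hotspot_scan(paste0("b", 1:1000), g1 + 5, g2 + 5)
  expect_equal(attr(out3, "sigma"), attr(out2, "sigma"))

  # bins missing in one group drop out of sigma
  g1[3] <- NA
  out4 <- hotspot_scan(paste0("b", 1:1000), g1, g2)
  expect_true(is.na(out4$difference[3]))
  expect_false(out4$flagged[3])
})

test_that("subtype profile distances match textbook formulas", {
  set.seed(12)
  pr <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("AIS", "MIA", "IAC")))
  out <- subtype_profile_distance(pr)
  expect_equal(diag(out$correlation), rep(1, 3), ignore_attr = TRUE)
  expect_equal(diag(out$distance), rep(0, 3), ignore_attr = TRUE)
  # direct formula oracle for one pair
  x <- pr[, 1]; y <- pr[, 2]
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$correlation["AIS", "MIA"], r_oracle, tolerance = 1e-10)
  expect_equal(out$distance["AIS", "MIA"], sqrt(sum((x - y)^2)),
               tolerance = 1e-10)
  # scaling leaves r at 1 and d at the norm
  two <- cbind(a = x, b = 2 * x)
  o2 <- subtype_profile_distance(two)
  expect_equal(o2$correlation["a", "b"], 1)
  expect_equal(o2$distance["a", "b"], sqrt(sum(x^2)))
  expect_identical(out$correlation, t(out$correlation))
})

test_that("median-ratio normalisation equalises scaled samples", {
  set.seed(3)
  base <- rexp(100) + 0.5
  mat <- cbind(s1 = base, s2 = base * 3, s3 = base * 0.25)
  norm <- median_ratio_normalize(mat)
  expect_equal(norm[, "s1"], norm[, "s2"], ignore_attr = TRUE)
  expect_equal(norm[, "s1"], norm[, "s3"], ignore_attr = TRUE)
})
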