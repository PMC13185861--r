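toy_counts <- function(values, groups = c("A", "A", "A", "B", "B", "B"),
                       pool_n = rep(10, 6)) {
  pooled_counts(values, group = groups, pool_n = pool_n)
}

test_that("FPKM follows counts * 1e9 / (length * library size)", {
  m <- matrix(c(100, 0), nrow = 2, dimnames = list(c("g1", "g2"), "p1"))
  f <- compute_fpkm(m, gene_lengths = c(1000, 500), library_sizes = 1e6)
  expect_equal(unname(f["g1", ]), 100)
  expect_equal(unname(f["g2", ]), 0)
  f2 <- compute_fpkm(m, gene_lengths = c(1000, 500), library_sizes = 2e6)
  expect_equal(unname(f2["g1", ]), 50)
  expect_error(compute_fpkm(m, gene_lengths = c(1000, 500, 1)), "per gene")
})

test_that("the zero-count filter removes any gene with a zero in a selected pool", {
  v <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
             g2 = c(1, 0, 3, 4, 5, 6),
             g3 = c(2, 2, 2, 2, 2, 2),
             g4 = c(0, 1, 1, 1, 1, 0),
             g5 = c(9, 9, 9, 9, 9, 9))
  colnames(v) <- c("A1", "A2", "A3", "B1", "B2", "B3")
  pc <- toy_counts(v)
  f <- filter_genes(pc)
  expect_identical(rownames(f$values), c("g1", "g3", "g5"))
  expect_equal(attr(f, "n_filtered"), 2L)
  # batch-discordant pools can be excluded before filtering
  f2 <- filter_genes(pc, pools = c("A2", "A3", "B1", "B2"))
  expect_true("g4" %in% rownames(f2$values))
  expect_false("g2" %in% rownames(f2$values))
  expect_error(filter_genes(toy_counts(matrix(0, 1, 6))), "no genes survive")
})

test_that("pooled CV inverts the SE of the pool means (worked example)", {
  v <- rbind(g1 = c(10, 12, 14, 20, 20, 20))
  cv <- pooled_cv(toy_counts(v), "A", n_eff_policy = "fixed", n_eff = 4)
  expect_equal(cv$mean, 12)
  expect_equal(cv$se, 2)
  expect_equal(cv$sigma, 4)
  expect_equal(cv$cv, 1 / 3)
  expect_equal(cv$grand_mean, mean(c(10, 12, 14, 20, 20, 20)))
  # identical pools -> CV 0; n_eff = 1 -> sigma = SE
  cvB <- pooled_cv(toy_counts(v), "B", n_eff_policy = "fixed", n_eff = 4)
  expect_equal(cvB$cv, 0)
  cv1 <- pooled_cv(toy_counts(v), "A", n_eff_policy = "fixed", n_eff = 1)
  expect_equal(cv1$sigma, cv1$se)
  # default policy: n_eff = mean of the group pool sizes
  cvm <- pooled_cv(toy_counts(v, pool_n = c(5, 10, 15, 8, 8, 8)), "A")
  expect_equal(attr(cvm, "n_eff"), 10)
  expect_equal(cvm$sigma, 2 * sqrt(10))
})

test_that("CV is invariant under multiplicative rescaling of a gene", {
  v <- rbind(g1 = c(10, 12, 14, 9, 13, 15))
  cv_a <- pooled_cv(toy_counts(v), "A")$cv
  cv_b <- pooled_cv(toy_counts(7.3 * v), "A")$cv
  expect_equal(cv_a, cv_b)
})

test_that("bin fractions partition ranked genes into near-equal bins", {
  # 10 genes, 2 bins; top-abundance half engineered so 4/5 have larger
  # group-1 CV, bottom half 1/5
  ng <- 10
  mean_a <- rep(100, ng) * (ng:1)          # ranks genes 1..10 by abundance
  cv1 <- c(2, 2, 2, 2, 1, 1, 1, 1, 1, 2)
  cv2 <- rep(1.5, ng)
  g1 <- structure(data.frame(gene = paste0("g", 1:ng), mean = mean_a, se = 1,
                             sigma = 1, cv = cv1, grand_mean = mean_a),
                  class = c("gene_cv", "data.frame"), group = "A", n_eff = 1)
  g2 <- structure(data.frame(gene = paste0("g", 1:ng), mean = mean_a, se = 1,
                             sigma = 1, cv = cv2, grand_mean = mean_a),
                  class = c("gene_cv", "data.frame"), group = "B", n_eff = 1)
  bf <- bin_fractions(g1, g2, permutation_config(n_bins = 2, n_perm = 100))
  expect_equal(bf$fraction, c(0.8, 0.2))
  expect_equal(bf$n_genes, c(5L, 5L))
  expect_error(bin_fractions(g1, g2, permutation_config(n_bins = 11, n_perm = 100)),
               "fewer genes than bins")
})

test_that("tie and dominance edge cases follow strict-inequality semantics", {
  sim <- null_pooled_sim(500, seed = 21)
  f <- filter_genes(sim)
  cvA <- pooled_cv(f, "g1"); cvB <- pooled_cv(f, "g2")
  cfg <- permutation_config(n_bins = 10, n_perm = 100)
  # identical CVs -> every comparison ties -> all fractions 0
  expect_equal(bin_fractions(cvA, cvA, cfg)$fraction, rep(0, 10))
  # group 1 shifted up by epsilon everywhere -> all fractions 1
  cv_eps <- cvA; cv_eps$cv <- cvB$cv + 1e-9
  expect_equal(bin_fractions(cv_eps, cvB, cfg)$fraction, rep(1, 10))
})

test_that("bin sizes differ by at most one with larger bins first", {
  s <- botmetrics:::bin_sizes(1037, 100)
  expect_equal(sum(s), 1037)
  expect_true(all(s %in% c(10L, 11L)))
  expect_true(all(diff(s) <= 0))
  expect_equal(s[1], 11L)
})

test_that("a fraction at the centre of the permutation null gets p near 1", {
  sim <- null_pooled_sim(2000, seed = 33)
  bf <- bin_fraction_run(sim, permutation_config(n_bins = 4, n_perm = 400, seed = 2))
  bf <- permutation_test(bf, permutation_config(n_bins = 4, n_perm = 400, seed = 2))
  centred <- which.min(abs(bf$fraction - bf$perm_mean))
  expect_gt(bf$p_value[centred], 0.5)
  expect_true(all(bf$p_value >= 0 & bf$p_value <= 1))
})

test_that("Monte-Carlo permutation matches the exhaustive oracle on 6 genes", {
  # 6 genes, 2 bins of 3: the null distribution of the first-bin fraction is
  # hypergeometric over which genes land in bin 1
  gt <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)  # 4 dominant genes
  combos <- utils::combn(6, 3)
  exhaustive <- apply(combos, 2L, function(ix) mean(gt[ix]))
  mean_a <- 6:1
  g1 <- structure(data.frame(gene = paste0("g", 1:6), mean = 1, se = 1, sigma = 1,
                             cv = ifelse(gt, 2, 1), grand_mean = mean_a),
                  class = c("gene_cv", "data.frame"), group = "A", n_eff = 1)
  g2 <- structure(data.frame(gene = paste0("g", 1:6), mean = 1, se = 1, sigma = 1,
                             cv = rep(1.5, 6), grand_mean = mean_a),
                  class = c("gene_cv", "data.frame"), group = "B", n_eff = 1)
  cfg <- permutation_config(n_bins = 2, n_perm = 4000, seed = 8)
  bf <- permutation_test(bin_fractions(g1, g2, cfg), cfg)
  perm <- attr(bf, "perm_fractions")[1L, ]   # first-bin null distribution
  for (v in unique(exhaustive)) {
    p_exact <- mean(exhaustive == v)
    p_mc <- mean(abs(perm - v) < 1e-12)
    se <- sqrt(p_exact * (1 - p_exact) / cfg$n_perm)
    expect_lt(abs(p_mc - p_exact), 4 * se + 1e-12)
  }
  expect_equal(bf$fraction, c(1, 1 / 3))
})

test_that("permutation p-values are invariant to which group is listed first", {
  sim <- null_pooled_sim(1200, seed = 55)
  f <- filter_genes(sim)
  cvA <- pooled_cv(f, "g1"); cvB <- pooled_cv(f, "g2")
  cfg <- permutation_config(n_bins = 6, n_perm = 300, seed = 4)
  ab <- permutation_test(bin_fractions(cvA, cvB, cfg), cfg)
  ba <- permutation_test(bin_fractions(cvB, cvA, cfg), cfg)
  expect_equal(ba$fraction, 1 - ab$fraction)     # continuous CVs: no ties
  expect_equal(ba$p_value, ab$p_value)
})

test_that("group CV comparison: identical groups null, shifted groups detected", {
  same <- list(a = rep(1:20, 2), b = rep(1:20, 2), c = rep(1:20, 2))
  r <- group_cv_comparison(same)
  expect_equal(unname(r$kruskal$statistic), 0, tolerance = 1e-12)
  expect_equal(r$kruskal$p.value, 1)
  set.seed(12)
  shifted <- list(lo = rlnorm(500, 0, 0.3), hi = rlnorm(500, 0.25, 0.3))
  r2 <- group_cv_comparison(shifted)
  expect_lt(r2$kruskal$p.value, 0.05)
  expect_equal(nrow(r2$tukey$grp), 1L)
})

test_that("two-group CV comparison reduces to the normal rank-sum oracle", {
  set.seed(77)
  x <- rnorm(25); y <- rnorm(30) + 0.4
  r <- group_cv_comparison(list(x = x, y = y))
  w <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(r$kruskal$p.value, w$p.value, tolerance = 1e-10)
})

test_that("sample similarity: correlations, constant pools and PCA invariance", {
  sim <- null_pooled_sim(300, seed = 66)
  dup <- pooled_counts(cbind(sim$values, dup1 = sim$values[, 1]),
                       group = c(sim$group, "g1"),
                       pool_n = c(sim$pool_n, sim$pool_n[1]))
  ss <- sample_similarity(dup)
  expect_equal(ss$correlation[1, ncol(dup$values)], 1)
  # constant pool reported NA with a warning
  cst <- pooled_counts(cbind(sim$values[, 1:3], flat = rep(2, 300)),
                       group = c("g1", "g1", "g1", "g2"), pool_n = rep(1, 4))
  expect_warning(ssc <- sample_similarity(cst), "constant pool")
  expect_true(all(is.na(ssc$correlation[, "flat"])))
  # gene reordering leaves PC scores unchanged up to sign
  perm <- sample(nrow(sim$values))
  reord <- pooled_counts(sim$values[perm, ], sim$group, sim$pool_n)
  s1 <- sample_similarity(sim); s2 <- sample_similarity(reord)
  expect_equal(abs(s1$scores), abs(s2$scores), tolerance = 1e-8)
})
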