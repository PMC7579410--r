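test_that("one-way ANOVA decomposition matches the hand-worked example", {
  res <- anova_by_day(list(c(0, 2), c(1, 3)))
  expect_equal(res$F, 0.5)
  expect_equal(res$r2, 0.2)
  expect_equal(res$p, pf(0.5, 1, 2, lower.tail = FALSE))
  expect_equal(res$p, 0.5528, tolerance = 1e-4)

  flat <- anova_by_day(list(c(1, 3), c(0, 4), c(2, 2, 2)))
  expect_equal(flat$F, 0)
  expect_equal(flat$r2, 0)
  expect_equal(flat$p, 1)
  expect_error(anova_by_day(list(c(1, 1), c(1, 1))), "identical")
  expect_error(anova_by_day(list(1:3)), "2 groups")
})

test_that("ANOVA agrees with lm and satisfies the F/R2 identity", {
  set.seed(6)
  for (i in 1:20) {
    k <- sample(3:10, 1L)
    groups <- lapply(seq_len(k), function(g) rnorm(sample(2:8, 1L), g * runif(1)))
    mine <- anova_by_day(groups)
    ref <- oracle_anova(groups)
    expect_equal(mine$F, ref$F, tolerance = 1e-10)
    expect_equal(mine$p, ref$p, tolerance = 1e-10)
    expect_equal(mine$r2, ref$r2, tolerance = 1e-10)
    N <- sum(lengths(groups))
    expect_equal(mine$F,
                 (mine$r2 / (k - 1)) / ((1 - mine$r2) / (N - k)),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(0.031), 0.031)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:200, 1L))^sample(1:3, 1L)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the BH cutoff maps to the published R2 boundary", {
  thr <- r2_threshold_for_q(m = 278, q = 0.05, k = 10, r = 6, n_rejected = 41)
  expect_equal(round(thr, 2), 0.34)
  # boundary limit: everything rejected at q -> 1 drives the boundary to 0
  expect_lt(r2_threshold_for_q(278, 1 - 1e-12, 10, 6, 278), 1e-3)
})

test_that("R2 boundary round-trips through the ANOVA p-value", {
  # construct balanced groups with r2 exactly at the boundary and check the
  # raw p equals the BH raw-p cutoff
  k <- 10L; r <- 6L
  thr <- r2_threshold_for_q(278, 0.05, k, r, 41)
  set.seed(2)
  base <- rnorm(r)
  base <- (base - mean(base)) / sd(base)              # SSW = r - 1 per group
  offs <- scale(seq_len(k), TRUE, FALSE)[, 1L]
  # scale offsets so SSB/SST = thr
  ssw <- k * (r - 1)
  ssb_target <- thr / (1 - thr) * ssw
  offs <- offs * sqrt(ssb_target / (r * sum(offs^2)))
  groups <- lapply(seq_len(k), function(g) base + offs[g])
  res <- anova_by_day(groups)
  expect_equal(res$r2, thr, tolerance = 1e-9)
  expect_equal(res$p, 41 * 0.05 / 278, tolerance = 1e-9)
})

test_that("Tukey letters separate clearly different groups and only those", {
  set.seed(12)
  same <- lapply(1:4, function(i) rnorm(6, 0, 1))
  expect_true(all(tukey_cld(same) == tukey_cld(same)[1L]))

  groups <- list(d0 = rnorm(6, 0, 0.1), d7 = rnorm(6, 0, 0.1),
                 d14 = rnorm(6, 10, 0.1))
  cld <- tukey_cld(groups)
  expect_equal(unname(cld), c("a", "a", "b"))

  # letters encode exactly the non-significant pairs from the q-distribution
  set.seed(77)
  for (i in 1:10) {
    k <- sample(3:6, 1L)
    g <- lapply(seq_len(k), function(j) rnorm(sample(4:8, 1L), j * 0.8))
    cld <- tukey_cld(g, alpha = 0.05)
    n <- lengths(g); means <- vapply(g, mean, 1.0)
    mse <- sum(unlist(lapply(g, function(v) (v - mean(v))^2))) / (sum(n) - k)
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        qs <- abs(means[a] - means[b]) /
          sqrt(mse / 2 * (1 / n[a] + 1 / n[b]))
        sig <- ptukey(qs, k, sum(n) - k, lower.tail = FALSE) < 0.05
        share <- any(strsplit(cld[a], "")[[1L]] %in% strsplit(cld[b], "")[[1L]])
        expect_equal(share, !sig, info = sprintf("iter %d pair %d-%d", i, a, b))
      }
    }
    # reflexive: every group shares a letter with itself
    expect_true(all(nchar(cld) >= 1L))
  }
  expect_error(tukey_cld(list(1:3)), "2 groups")
})

test_that("assumption checks match the textbook AD formula and Levene boundaries", {
  set.seed(5)
  groups <- lapply(1:4, function(i) rnorm(8, i))
  res <- assumption_checks(groups)
  resid <- unlist(lapply(groups, function(g) g - mean(g)))
  expect_equal(res$ad_stat, oracle_ad_stat(resid), tolerance = 1e-8)

  # identical value multisets across groups: Levene statistic 0, p 1
  g0 <- list(c(1, 2, 3, 9), c(2, 1, 9, 3), c(9, 3, 2, 1))
  res0 <- assumption_checks(g0)
  expect_equal(res0$levene_stat, 0)
  expect_equal(res0$levene_p, 1)

  # a strongly bimodal sample must fail AD normality
  bimodal <- list(c(rnorm(100, -5, 0.3), rnorm(100, 5, 0.3)))
  expect_lt(assumption_checks(c(bimodal, list(rnorm(8))))$ad_p, 0.01)
  expect_error(assumption_checks(list(rep(1, 5), rep(1, 5))), "zero-variance")
})

test_that("Levene statistic equals a direct ANOVA on median-centred deviations", {
  set.seed(9)
  g <- list(rnorm(10, 0, 0.2), rnorm(10, 0, 1), rnorm(10, 0, 5))
  res <- assumption_checks(g)
  devs <- lapply(g, function(v) abs(v - median(v)))
  ref <- oracle_anova(devs)
  expect_equal(res$levene_stat, ref$F, tolerance = 1e-10)
  expect_equal(res$levene_p, ref$p, tolerance = 1e-10)
  expect_lt(res$levene_p, 0.05)
})

test_that("PCA scores satisfy the SVD variance identities", {
  line <- cbind(1:10, 2 * (1:10) + 3)
  pc <- pca_scores(line)
  expect_equal(pc$prop_var[1L], 1.0, tolerance = 1e-12)

  set.seed(20)
  mat <- matrix(rnorm(120), 12)
  pc <- pca_scores(mat)
  expect_equal(sum(pc$prop_var), 1.0, tolerance = 1e-12)
  # column permutation leaves variance proportions unchanged
  expect_equal(pca_scores(mat[, sample(ncol(mat))])$prop_var, pc$prop_var,
               tolerance = 1e-10)
  # score variance equals squared singular value / (n - 1)
  sv <- svd(scale(mat, TRUE, FALSE))$d
  expect_equal(apply(pc$scores, 2L, var), sv^2 / (nrow(mat) - 1),
               tolerance = 1e-10, ignore_attr = TRUE)
  mat[1L, 1L] <- NA
  expect_error(pca_scores(mat), "missing")
})

test_that("Spearman correlation: boundaries and exact-permutation agreement", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_corr(x, x * 2 + 1)$rho, 1.0)
  expect_equal(spearman_corr(x, rev(x))$rho, -1.0)
  set.seed(15)
  for (i in 1:8) {
    y <- rnorm(6)
    mine <- spearman_corr(x, y)
    perm <- oracle_spearman_perm(x, y)
    expect_equal(mine$rho, perm$rho, tolerance = 1e-12)
    # the t approximation tracks the exact permutation p closely at n = 6
    expect_lt(abs(mine$p - perm$p), 0.12)
    expect_equal(mine$p < 0.05, perm$p < 0.05)
  }
  expect_error(spearman_corr(c(1, 1, 1, 1), c(1, 2, 3, 4)), "rank variance")
})
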