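make_design_tensor <- function(n_prot = 8, seed = 1, days = c(0, 7, 14, 21),
                               fish = c("F1", "F2", "F3")) {
  set.seed(seed)
  vals <- matrix(rnorm(n_prot * length(days) * length(fish), 20, 2),
                 nrow = n_prot,
                 dimnames = list(sprintf("P%02d", seq_len(n_prot)), NULL))
  toy_tensor(vals, days, fish)
}

test_that("presence filter enforces the per-individual rule", {
  d <- cohort_design(n_proteins = 6, seed = 2)
  sim <- simulate_abundance(d)
  mask <- sim$tensor$mask
  # P0002: one fish drops to 6/10 observed days -> protein must go
  f1_cols <- which(sim$tensor$samples$individual == "F1")
  mask[2L, f1_cols[1:4]] <- FALSE
  # P0003: every fish at exactly 7/10 -> stays
  for (f in unique(sim$tensor$samples$individual)) {
    cols <- which(sim$tensor$samples$individual == f)
    mask[3L, cols[1:3]] <- FALSE
  }
  tensor <- abundance_tensor(sim$tensor$values, sim$tensor$proteins,
                             sim$tensor$samples, mask = mask, scale = "log2")
  res <- filter_presence(tensor)
  expect_setequal(res$tensor$proteins, sim$tensor$proteins[-2L])
  expect_false(res$report$retained[2L])
  expect_equal(res$report$present_F1[2L], 6)
  expect_true(all(res$report$retained[-2L]))
})

test_that("presence filter rejects incomplete designs and counts datapoints", {
  t4 <- make_design_tensor()
  expect_error(filter_presence(t4, min_present = 3, of_days = 5),
               "4 days")
  res <- filter_presence(t4, min_present = 3, of_days = 4)
  expect_equal(length(res$tensor$values),
               nrow(res$tensor$values) * 3 * 4)
  broken <- t4
  broken$samples$day[1L] <- 7L   # duplicates (F1, 7), drops (F1, 0)
  expect_error(abundance_tensor(broken$values, broken$proteins,
                                broken$samples, scale = "log2"),
               "duplicate")
})

test_that("log2 transform is exact, mask-preserving and invertible", {
  vals <- matrix(c(8, 1024, 2, 0.5), 2,
                 dimnames = list(c("P1", "P2"), NULL))
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2)
  tensor <- abundance_tensor(vals, c("P1", "P2"),
                             data.frame(individual = c("F1", "F1"),
                                        day = c(0, 7)),
                             mask = mask, scale = "linear")
  lg <- log2_transform(tensor)
  expect_equal(lg$values["P1", 1L], 3)
  expect_equal(lg$scale, "log2")
  expect_identical(lg$mask, tensor$mask)
  expect_true(is.na(lg$values["P1", 2L]))
  back <- delog2_transform(lg)
  expect_equal(back$values[mask], tensor$values[mask], tolerance = 1e-12)

  neg <- abundance_tensor(matrix(c(-1, 4), 1), "P1",
                          data.frame(individual = c("F1", "F1"),
                                     day = c(0, 7)), scale = "linear")
  expect_error(log2_transform(neg), "P1")
})

test_that("imputation is a deterministic no-op on complete data and never touches observed values", {
  tensor <- make_design_tensor(seed = 5)
  out <- impute_missing(tensor, method = "random_forest", seed = 1)
  expect_identical(out$values, tensor$values)

  mask <- tensor$mask
  mask[cbind(c(1, 3, 5), c(2, 7, 11))] <- FALSE
  holed <- abundance_tensor(tensor$values, tensor$proteins, tensor$samples,
                            mask = mask, scale = "log2")
  for (method in c("day_mean", "knn", "random_forest")) {
    imp <- impute_missing(holed, method = method, seed = 3)
    expect_true(all(imp$mask))
    expect_identical(imp$values[mask], tensor$values[mask])
    expect_identical(attr(imp, "imputed"), !mask)
  }
  rf1 <- impute_missing(holed, method = "random_forest", seed = 3)
  rf2 <- impute_missing(holed, method = "random_forest", seed = 3)
  expect_identical(rf1$values, rf2$values)
})

test_that("random-forest imputation beats day-mean RMSE on correlated cohorts", {
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  wins <- logical(3)
  for (s in 1:3) {
    d <- cohort_design(n_proteins = 60, seed = 300 + s)
    sim <- simulate_abundance(d)
    masked <- apply_missingness(sim$tensor, 0.0078,
                                mnar_strength = d$mnar_strength, seed = s)
    hold <- !masked$mask
    rf <- impute_missing(masked, method = "random_forest", seed = s)
    dm <- impute_missing(masked, method = "day_mean", seed = s)
    wins[s] <- rmse(rf$values[hold], sim$tensor$values[hold]) <=
      rmse(dm$values[hold], sim$tensor$values[hold])
  }
  expect_true(all(wins))
})

test_that("day-0 normalisation zeroes baselines and matches the linear ratio", {
  tensor <- make_design_tensor(seed = 9)
  norm <- day0_normalize(tensor)
  d0 <- norm$samples$day == 0
  expect_true(all(norm$values[, d0] == 0))
  # flat protein: all zero after normalisation
  flat <- tensor
  flat$values[1L, ] <- 15
  expect_true(all(day0_normalize(flat)$values[1L, ] == 0))
  # exp2 of the log difference equals the linear-scale ratio
  lin <- delog2_transform(tensor)
  f1 <- tensor$samples$individual == "F1"
  ratio <- lin$values[, f1 & tensor$samples$day == 7] /
    lin$values[, f1 & tensor$samples$day == 0]
  expect_equal(2^norm$values[, which(f1 & tensor$samples$day == 7)],
               ratio, tolerance = 1e-10, ignore_attr = TRUE)
  # applying it twice changes nothing
  expect_equal(day0_normalize(norm)$values, norm$values)
  nod0 <- make_design_tensor(days = c(7, 14, 21, 28))
  expect_error(day0_normalize(nod0), "day 0")
})

test_that("mean IgM profile equals the brute-force mean of flagged proteins", {
  tensor <- make_design_tensor(n_prot = 10, seed = 13)
  one <- mean_igm_profile(tensor, "P03")
  expect_equal(one$mean_log2, unname(tensor$values["P03", ]))
  # antisymmetric pair averages to zero
  anti <- tensor
  anti$values[2L, ] <- -anti$values[1L, ]
  t2 <- abundance_tensor(anti$values, anti$proteins, anti$samples,
                         scale = "log2")
  expect_equal(mean_igm_profile(t2, c("P01", "P02"))$mean_log2,
               rep(0, ncol(t2$values)))
  set.seed(4)
  for (i in 1:5) {
    pick <- sample(tensor$proteins, sample(2:6, 1L))
    got <- mean_igm_profile(tensor, pick)$mean_log2
    manual <- apply(tensor$values[pick, , drop = FALSE], 2L, mean)
    expect_equal(got, unname(manual), tolerance = 1e-12)
  }
  expect_error(mean_igm_profile(tensor, character()), "empty")
})
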