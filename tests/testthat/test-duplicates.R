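random_aa <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n,
               replace = TRUE), collapse = "")
}

test_that("pairwise identity: boundary cases and substitution counting", {
  s <- random_aa(100, 1)
  expect_equal(pairwise_identity(s, s), 100)
  s10 <- substr(s, 1, 10)
  t10 <- paste0("W", substr(s10, 2, 10))
  if (substr(s10, 1, 1) == "W") t10 <- paste0("A", substr(s10, 2, 10))
  expect_equal(pairwise_identity(s10, t10), 90)
  expect_error(pairwise_identity("", s), "empty")
})

test_that("identity agrees with an affine-gap dynamic-programming oracle", {
  set.seed(3)
  for (i in 1:50) {
    a <- random_aa(sample(60:120, 1L), seed = 1000 + i)
    # mutate: substitutions plus occasionally a short indel
    bb <- strsplit(a, "")[[1L]]
    n_sub <- sample(0:12, 1L)
    pos <- sample(length(bb), n_sub)
    alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    for (p in pos) bb[p] <- sample(setdiff(alphabet, bb[p]), 1L)
    if (runif(1) < 0.5) {
      cut <- sample(length(bb) - 4L, 1L)
      bb <- bb[-(cut:(cut + sample(1:3, 1L)))]
    }
    b <- paste(bb, collapse = "")
    expect_lt(abs(pairwise_identity(a, b) - oracle_identity(a, b)), 0.5,
              label = paste("pair", i))
  }
})

test_that("shared peptide fraction uses the smaller set as denominator", {
  expect_equal(shared_peptide_fraction(c("a", "b"), c("a", "b")), 100)
  expect_equal(shared_peptide_fraction(c("a", "b"), c("c", "d")), 0)
  expect_equal(shared_peptide_fraction(c("a", "b", "c", "d"), c("c", "d", "e")),
               100 * 2 / 3, tolerance = 1e-12)
  # nested sets score 100 under min, less under Jaccard
  expect_equal(shared_peptide_fraction(c("a", "b", "c"), c("a", "b")), 100)
  expect_equal(shared_peptide_fraction(c("a", "b", "c"), c("a", "b"),
                                       denominator = "union"), 100 * 2 / 3,
               tolerance = 1e-12)
  expect_error(shared_peptide_fraction(character(), character()), "empty")
})

test_that("duplicate finding applies identity and coverage cutoffs", {
  tpl <- random_aa(150, 5)
  hi <- simulate_paralog_pair(tpl, 90, seed = 1, accession_prefix = "HI")
  lo <- simulate_paralog_pair(tpl, 60, seed = 2, accession_prefix = "LO")
  lo$accession <- c("LO_a", "LO_b")
  prots <- rbind(hi[1:2, ], lo[2, ], protein_records("OTHER", random_aa(150, 6)))
  pairs <- find_duplicates(prots)
  expect_equal(nrow(pairs), 1L)
  expect_setequal(c(pairs$acc_a, pairs$acc_b), c("HI_a", "HI_b"))
  expect_true(pairs$is_ss4r)
  expect_gt(pairs$identity_pct, 70)
})

test_that("duplicate scan equals all-pairs brute force on a mixed proteome", {
  prots <- simulate_proteome(12, duplicate_fraction = 0.5,
                             identity_range = c(60, 99), seed = 77)
  prots <- prots[1:min(30L, nrow(prots)), ]
  pairs <- find_duplicates(prots, identity_cutoff = 70, coverage_cutoff = 70)
  # brute force over every unordered pair
  expected <- character()
  for (i in seq_len(nrow(prots) - 1L)) {
    for (j in (i + 1L):nrow(prots)) {
      if (prots$gene_id[i] == prots$gene_id[j]) next
      li <- nchar(prots$sequence[i]); lj <- nchar(prots$sequence[j])
      if (100 * min(li, lj) / max(li, lj) <= 70) next
      if (pairwise_identity(prots$sequence[i], prots$sequence[j]) <= 70) next
      expected <- c(expected, paste(sort(c(prots$accession[i],
                                           prots$accession[j])), collapse = "+"))
    }
  }
  expect_setequal(paste(pairs$acc_a, pairs$acc_b, sep = "+"), expected)
})

test_that("scenario classification matches the co-grouping construction", {
  tpl <- random_aa(300, 8)
  near <- simulate_paralog_pair(tpl, 99, seed = 3, accession_prefix = "NEAR")
  far_tpl <- random_aa(300, 9)
  far <- simulate_paralog_pair(far_tpl, 75, seed = 4, accession_prefix = "FAR")
  lone <- protein_records("LONE", random_aa(300, 10))
  prots <- rbind(near, far, lone)
  idx <- build_peptide_index(prots, detectability = 1)
  groups <- assemble_groups(idx)
  pairs <- annotate_shared_peptides(find_duplicates(prots), idx)
  cls <- classify_scenarios(groups, pairs)
  # near-identical paralogs co-group (scenario i); diverged ones split (ii)
  near_row <- cls$pairs[cls$pairs$acc_a == "NEAR_a", ]
  far_row <- cls$pairs[cls$pairs$acc_a == "FAR_a", ]
  expect_true(near_row$same_mpg)
  expect_false(far_row$same_mpg)
  expect_equal(cls$summary$n_scenario_i, 1L)
  expect_equal(cls$summary$n_scenario_ii, 2L)
  expect_equal(cls$summary$n_no_duplicate +
                 cls$summary$n_scenario_i + cls$summary$n_scenario_ii,
               length(groups))
  expect_error(
    classify_scenarios(groups, data.frame(acc_a = "GHOST", acc_b = "LONE")),
    "absent")
})

test_that("identity 100 at full detectability always co-groups", {
  for (s in 1:5) {
    tpl <- random_aa(200, 40 + s)
    pp <- simulate_paralog_pair(tpl, 100, seed = s)
    idx <- build_peptide_index(pp, detectability = 1)
    g <- assemble_groups(idx)
    expect_length(g, 1L)
  }
})

test_that("identity-sharing correlation is positive across a paralog gradient", {
  set.seed(123)
  rows <- lapply(1:50, function(i) {
    tpl <- random_aa(sample(150:250, 1L), 3000 + i)
    target <- runif(1, 70, 100)
    pp <- simulate_paralog_pair(tpl, target, seed = i)
    idx <- build_peptide_index(pp, detectability = 0.9, seed = i)
    data.frame(acc_a = pp$accession[1L], acc_b = pp$accession[2L],
               identity_pct = pairwise_identity(pp$sequence[1L],
                                                pp$sequence[2L]),
               shared_pct = shared_peptide_fraction(idx$prot2pep[[1L]],
                                                    idx$prot2pep[[2L]]),
               same_mpg = TRUE, is_ss4r = TRUE)
  })
  pairs <- do.call(rbind, rows)
  res <- correlate_identity_sharing(pairs)
  expect_gt(res$r, 0)
  expect_lt(res$p, 0.05)

  # perfect linear relation gives r = 1
  toy <- data.frame(identity_pct = c(70, 80, 90, 100),
                    shared_pct = c(70, 80, 90, 100), same_mpg = TRUE)
  expect_equal(correlate_identity_sharing(toy)$r, 1.0, tolerance = 1e-12)
  degenerate <- data.frame(identity_pct = c(90, 90, 90),
                           shared_pct = c(1, 2, 3), same_mpg = TRUE)
  expect_error(correlate_identity_sharing(degenerate), "variance")
})

test_that("correlation matches the direct covariance formula", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:30, 1L)
    pairs <- data.frame(identity_pct = runif(n, 70, 100),
                        shared_pct = runif(n, 0, 100), same_mpg = TRUE)
    res <- correlate_identity_sharing(pairs)
    x <- pairs$identity_pct; y <- pairs$shared_pct
    r_direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r, r_direct, tolerance = 1e-10)
  }
})

test_that("expected peptide sharing is monotone in sequence identity", {
  set.seed(77)
  idents <- numeric(500); shared <- numeric(500)
  tpl <- random_aa(150, 555)
  for (i in 1:500) {
    target <- runif(1, 60, 100)
    pp <- simulate_paralog_pair(tpl, target, seed = 7000 + i)
    peps_a <- tryptic_digest(pp$sequence[1L])
    peps_b <- tryptic_digest(pp$sequence[2L])
    if (length(peps_a) == 0L || length(peps_b) == 0L) next
    idents[i] <- target
    shared[i] <- shared_peptide_fraction(peps_a, peps_b)
  }
  keep <- idents > 0
  bins <- cut(idents[keep], breaks = c(60, 70, 80, 90, 100))
  bin_means <- tapply(shared[keep], bins, mean)
  expect_true(all(diff(bin_means) >= 0))
})
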