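#' One-way ANOVA decomposition for one protein
#'
#' Standard fixed-factor decomposition of a protein's abundances by
#' sampling day: `F = (SSB/(k-1)) / (SSW/(N-k))`, `r2 = SSB/SST` (the
#' fraction of abundance variance explained by day), and the upper-tail
#' probability from `F(k-1, N-k)`.
#'
#' @param groups list of numeric vectors, one per day (>= 2 groups, each
#'   >= 2 values).
#' @return list with `F`, `p`, `r2`, `df1`, `df2`.
#' @export
anova_by_day <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  n <- vapply(groups, length, 1L)
  k <- length(groups)
  N <- length(y)
  gm <- mean(y)
  means <- vapply(groups, mean, 1.0)
  ssb <- sum(n * (means - gm)^2)
  sst <- sum((y - gm)^2)
  if (sst == 0) stop("degenerate input: all values identical")
  ssw <- sst - ssb
  df1 <- k - 1L
  df2 <- N - k
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       r2 = ssb / sst, df1 = df1, df2 = df2)
}

#' Per-protein ANOVA over an abundance tensor
#'
#' Runs [anova_by_day()] for every protein of a complete log2 tensor using
#' sampling day as the fixed factor, applies Benjamini-Hochberg correction
#' across all proteins, and (for proteins passing the FDR cutoff) computes
#' Tukey compact letter displays.
#'
#' @param tensor complete log2-scale [abundance_tensor()].
#' @param q FDR level for the BH cutoff.
#' @param alpha per-comparison level for the Tukey letters.
#' @param letters compute compact letter displays for significant proteins.
#' @return data.frame (class `anova_records`) with columns `protein`, `F`,
#'   `p`, `r2`, `p_bh`, `significant`, `letters` (per-day letters joined by
#'   `;`, `NA` when not significant).
#' @export
anova_tensor <- function(tensor, q = 0.05, alpha = 0.05, letters = TRUE) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  if (!all(tensor$mask)) stop("tensor has missing values; impute first")
  day <- factor(tensor$samples$day, levels = sort(unique(tensor$samples$day)))
  split_idx <- split(seq_along(day), day)
  res <- lapply(seq_along(tensor$proteins), function(p) {
    anova_by_day(lapply(split_idx, function(ix) tensor$values[p, ix]))
  })
  p_raw <- vapply(res, `[[`, 1.0, "p")
  p_bh <- bh_adjust(p_raw)
  sig <- p_bh <= q
  let <- rep(NA_character_, length(sig))
  if (letters && any(sig)) {
    for (p in which(sig)) {
      cld <- tukey_cld(lapply(split_idx, function(ix) tensor$values[p, ix]),
                       alpha = alpha)
      let[p] <- paste(cld, collapse = ";")
    }
  }
  out <- data.frame(protein = tensor$proteins,
                    F = vapply(res, `[[`, 1.0, "F"),
                    p = p_raw, r2 = vapply(res, `[[`, 1.0, "r2"),
                    p_bh = p_bh, significant = sig, letters = let,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("anova_records", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' R-squared boundary equivalent to a BH cutoff
#'
#' In a balanced one-way design the BH decision at FDR level `q` with
#' `n_rejected` rejections among `m` tests corresponds to a raw-p boundary
#' `n_rejected * q / m`; inverting the F tail at df `(k-1, k(r-1))` and
#' mapping F to R-squared gives the variance-explained boundary implied by
#' the multiplicity correction: proteins are selected iff their day
#' R-squared exceeds it.
#'
#' @param m number of tests.
#' @param q FDR level.
#' @param k number of day groups.
#' @param r replicates (individuals) per group.
#' @param n_rejected number of BH rejections.
#' @return the R-squared boundary.
#' @export
r2_threshold_for_q <- function(m, q, k, r, n_rejected) {
  stopifnot(m >= 1L, q > 0, q < 1, k >= 2L, r >= 2L,
            n_rejected >= 1L, n_rejected <= m)
  df1 <- k - 1L
  df2 <- k * (r - 1L)
  p_boundary <- n_rejected * q / m
  Fs <- stats::qf(p_boundary, df1, df2, lower.tail = FALSE)
  df1 * Fs / (df1 * Fs + df2)
}

#' Tukey compact letter display
#'
#' All pairwise day comparisons via the studentized-range distribution
#' (Tukey-Kramer standard errors for unbalanced groups) at level `alpha`,
#' summarised by the insert-and-absorb compact-letter-display algorithm:
#' two days share a letter iff they are not significantly different.
#'
#' @param groups list of numeric vectors, one per day, each >= 2 values.
#' @param alpha familywise level.
#' @return character vector of letter codes, one per group, named by the
#'   group names (or indices).
#' @export
tukey_cld <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs >= 2 values")
  n <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1.0)
  N <- sum(n)
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0)) / (N - k)
  df <- N - k
  sig <- matrix(FALSE, k, k)
  if (mse > 0) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
        qs <- abs(means[i] - means[j]) / se
        pv <- stats::ptukey(qs, k, df, lower.tail = FALSE)
        sig[i, j] <- sig[j, i] <- pv < alpha
      }
    }
  } else {
    # zero within-group variance: any mean difference is significant
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        sig[i, j] <- sig[j, i] <- means[i] != means[j]
      }
    }
  }
  letters_cld(sig, names(groups))
}

# insert-and-absorb: maintain letter columns (sets of groups); split a
# column on each significant pair it contains, then absorb subset columns
letters_cld <- function(sig, labels = NULL) {
  k <- nrow(sig)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!sig[i, j]) next
      hit <- vapply(cols, function(cc) all(c(i, j) %in% cc), TRUE)
      for (h in which(hit)) {
        a <- setdiff(cols[[h]], i)
        b <- setdiff(cols[[h]], j)
        cols[[h]] <- a
        cols[[length(cols) + 1L]] <- b
      }
      # absorb: drop columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (u in seq_along(cols)) {
        for (v in seq_along(cols)) {
          if (u != v && keep[u] && keep[v] &&
              all(cols[[u]] %in% cols[[v]]) &&
              !(all(cols[[v]] %in% cols[[u]]) && u < v)) {
            keep[u] <- FALSE
          }
        }
      }
      cols <- cols[keep]
    }
  }
  # order columns by their first (highest-indexed-first) group for stable labels
  cols <- cols[order(vapply(cols, min, 1L))]
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(cc) g %in% cc, TRUE))],
          collapse = "")
  }, "")
  names(out) <- if (!is.null(labels)) labels else as.character(seq_len(k))
  out
}

#' Residual normality and variance-homogeneity checks
#'
#' Anderson-Darling test (mean and variance estimated from the data) on the
#' within-group residuals, and the Brown-Forsythe (median-centred) Levene
#' test across groups. Reported as diagnostics only; no protein is excluded
#' on their basis.
#'
#' @param groups list of numeric vectors, one per day.
#' @return list with `ad_stat`, `ad_p`, `levene_stat`, `levene_p`.
#' @export
assumption_checks <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  resid <- unlist(lapply(groups, function(g) g - mean(g)), use.names = FALSE)
  if (length(resid) < 8L) stop("need at least 8 residuals")
  if (stats::sd(resid) == 0) stop("zero-variance residuals")
  ad <- nortest::ad.test(resid)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  spread <- unlist(lapply(groups, function(v) abs(v - stats::median(v))),
                   use.names = FALSE)
  if (stats::sd(spread) == 0) {
    lev_stat <- 0
    lev_p <- 1
  } else {
    lev <- car::leveneTest(y, g, center = stats::median)
    lev_stat <- lev[1L, "F value"]
    lev_p <- lev[1L, "Pr(>F)"]
  }
  list(ad_stat = unname(ad$statistic), ad_p = unname(ad$p.value),
       levene_stat = lev_stat, levene_p = lev_p)
}

#' PCA scores and variance proportions
#'
#' Centred (optionally scaled) SVD-based principal component analysis of a
#' samples x features matrix, as `prcomp` computes it.
#'
#' @param mat numeric matrix, samples in rows, features in columns, no
#'   missing values.
#' @param center,scale passed to [stats::prcomp()].
#' @return list with `scores` (samples x components) and `prop_var`
#'   (proportion of variance per component, summing to 1).
#' @export
pca_scores <- function(mat, center = TRUE, scale = FALSE) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix has missing values; impute first")
  if (nrow(mat) < 2L || ncol(mat) < 2L) stop("need >= 2 samples and features")
  pc <- stats::prcomp(mat, center = center, scale. = scale)
  v <- pc$sdev^2
  list(scores = pc$x, prop_var = v / sum(v))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks on ties), with a
#' two-sided p from `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stop("zero rank variance")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}
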