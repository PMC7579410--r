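#' Run the full population-level timecourse analysis
#'
#' Composes the downstream pipeline on a linear-scale abundance tensor:
#' presence filtering (default 7 of 10 days, every individual), log2
#' transformation, missing-value imputation, per-protein one-way ANOVA on
#' sampling day with Benjamini-Hochberg control, the implied R-squared
#' selection boundary, Tukey letters for the selected proteins, PCA of the
#' samples (raw and day-0-normalised), and seriated complete-linkage
#' clustering of the selected proteins' mean temporal profiles.
#'
#' @param tensor an [abundance_tensor()] (linear scale; a log2 tensor is
#'   accepted and used as-is).
#' @param q FDR level for the BH cutoff.
#' @param k_clusters number of profile clusters to report.
#' @param min_present,of_days presence-filter rule.
#' @param impute_method passed to [impute_missing()].
#' @param extra_profiles optional matrix of additional feature rows
#'   (features x days, e.g. mean IgM and titre curves) appended to the
#'   profile matrix before clustering.
#' @param seed integer seed for the imputation forest.
#' @return object of class `lfq_timecourse`: list with elements `tensor`
#'   (complete log2 tensor), `presence_report`, `anova` (the
#'   [anova_tensor()] records), `r2_threshold`, `selected` (accessions),
#'   `pca_raw`, `pca_day0`, `profiles`, `dissimilarity`, `tree`,
#'   `seriation`, `clusters`, and the call parameters.
#' @export
run_timecourse_analysis <- function(tensor, q = 0.05, k_clusters = 5L,
                                    min_present = 7L, of_days = 10L,
                                    impute_method = "random_forest",
                                    extra_profiles = NULL, seed = 1L) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  filt <- filter_presence(tensor, min_present = min_present, of_days = of_days)
  work <- filt$tensor
  if (work$scale == "linear") work <- log2_transform(work)
  work <- impute_missing(work, method = impute_method, seed = seed)

  anova <- anova_tensor(work, q = q)
  n_days <- length(unique(work$samples$day))
  n_fish <- length(unique(work$samples$individual))
  n_sel <- sum(anova$significant)
  r2_thr <- if (n_sel >= 1L) {
    r2_threshold_for_q(m = nrow(anova), q = q, k = n_days, r = n_fish,
                       n_rejected = n_sel)
  } else NA_real_
  selected <- anova$protein[anova$significant]

  pca_raw <- pca_scores(t(work$values))
  pca_day0 <- pca_scores(t(day0_normalize(work)$values))

  profiles <- tree <- seriation <- clusters <- dis <- NULL
  if (length(selected) >= 3L) {
    profiles <- profile_matrix(work, selected)
    if (!is.null(extra_profiles)) profiles <- rbind(profiles, extra_profiles)
    profiles <- zscore_rows(profiles)
    dis <- corr_dissimilarity(profiles)
    tree <- hclust_complete(dis)
    seriation <- mf_seriation(dis, tree)
    clusters <- cut_clusters(tree, k = min(k_clusters, nrow(profiles)),
                             order = seriation)
  }
  structure(list(tensor = work, presence_report = filt$report,
                 anova = anova, r2_threshold = r2_thr, selected = selected,
                 pca_raw = pca_raw, pca_day0 = pca_day0,
                 profiles = profiles, dissimilarity = dis, tree = tree,
                 seriation = seriation, clusters = clusters,
                 q = q, k_clusters = k_clusters, seed = seed),
            class = "lfq_timecourse")
}

#' @export
print.lfq_timecourse <- function(x, ...) {
  nt <- x$tensor
  cat("Longitudinal LFQ timecourse analysis\n")
  cat(sprintf("  retained proteins: %d of %d (presence filter)\n",
              nrow(nt$values), nrow(x$presence_report)))
  cat(sprintf("  datapoints: %d\n", length(nt$values)))
  cat(sprintf("  day-responsive proteins (BH q <= %.2g): %d (%.1f%%)\n",
              x$q, length(x$selected),
              100 * length(x$selected) / nrow(x$anova)))
  if (!is.na(x$r2_threshold)) {
    cat(sprintf("  equivalent R2 selection boundary: %.2f\n", x$r2_threshold))
  }
  if (!is.null(x$clusters)) {
    k <- length(unique(x$clusters))
    cat(sprintf("  profile clusters (k = %d): %s\n", k,
                paste(table(x$clusters), collapse = "/")))
  }
  invisible(x)
}

#' @export
summary.lfq_timecourse <- function(object, ...) {
  print(object)
  cat(sprintf("  PC1/PC2 variance (raw): %.1f%% / %.1f%%\n",
              100 * object$pca_raw$prop_var[1L],
              100 * object$pca_raw$prop_var[2L]))
  cat(sprintf("  PC1/PC2 variance (day-0 normalised): %.1f%% / %.1f%%\n",
              100 * object$pca_day0$prop_var[1L],
              100 * object$pca_day0$prop_var[2L]))
  top <- utils::head(object$anova[order(object$anova$p), ], 5L)
  cat("  strongest day effects:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %s  F = %.2f, R2 = %.3f, BH p = %.3g\n",
                top$protein[i], top$F[i], top$r2[i], top$p_bh[i]))
  }
  invisible(object)
}
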