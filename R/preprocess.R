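#' Presence filter: retain consistently measured proteins
#'
#' A protein is retained iff, for every individual, it was observed on at
#' least `min_present` of the `of_days` sampling days. The default (7 of 10,
#' in all individuals) keeps only proteins quantified consistently enough
#' for reliable per-protein inference across a repeated-measures timecourse.
#'
#' @param tensor an [abundance_tensor()] covering a complete
#'   individual x day design.
#' @param min_present minimum observed days per individual.
#' @param of_days expected number of days per individual.
#' @param require_all_individuals if `FALSE`, a protein is retained when at
#'   least one individual meets the rule.
#' @return list with `tensor` (the retained subset) and `report`
#'   (data.frame: per-protein per-individual presence counts plus a
#'   `retained` flag); attribute-free so it writes directly as TSV.
#' @export
filter_presence <- function(tensor, min_present = 7L, of_days = 10L,
                            require_all_individuals = TRUE) {
  stopifnot(inherits(tensor, "abundance_tensor"),
            min_present >= 1L, min_present <= of_days)
  fish <- unique(tensor$samples$individual)
  days <- unique(tensor$samples$day)
  if (length(days) != of_days) {
    stop("tensor has ", length(days), " days but of_days = ", of_days)
  }
  tab <- table(tensor$samples$individual, tensor$samples$day)
  if (any(tab != 1L)) stop("incomplete design: missing (individual, day) column")
  counts <- vapply(fish, function(f) {
    rowSums(tensor$mask[, tensor$samples$individual == f, drop = FALSE])
  }, numeric(length(tensor$proteins)))
  if (length(tensor$proteins) == 1L) counts <- matrix(counts, nrow = 1L)
  ok <- counts >= min_present
  retained <- if (require_all_individuals) {
    rowSums(ok) == length(fish)
  } else {
    rowSums(ok) >= 1L
  }
  report <- data.frame(protein = tensor$proteins, counts, retained = retained,
                       stringsAsFactors = FALSE, check.names = FALSE,
                       row.names = NULL)
  names(report) <- c("protein", paste0("present_", fish), "retained")
  list(tensor = tensor_subset(tensor, which(retained)), report = report)
}

#' Log2-transform a linear-scale tensor
#'
#' @param tensor linear-scale [abundance_tensor()] with positive observed
#'   values.
#' @return the tensor on the log2 scale (mask unchanged).
#' @export
log2_transform <- function(tensor) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  if (tensor$scale != "linear") stop("tensor already on log2 scale")
  bad <- which(tensor$mask & tensor$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive observed value at protein %s, sample %s",
                 tensor$proteins[bad[1L, 1L]],
                 sample_names(tensor$samples)[bad[1L, 2L]]))
  }
  values <- tensor$values
  values[tensor$mask] <- log2(values[tensor$mask])
  abundance_tensor(values, tensor$proteins, tensor$samples,
                   mask = tensor$mask, scale = "log2")
}

#' Back-transform a log2 tensor to the linear scale
#'
#' @param tensor log2-scale [abundance_tensor()].
#' @return the tensor on the linear scale.
#' @export
delog2_transform <- function(tensor) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  if (tensor$scale != "log2") stop("tensor not on log2 scale")
  values <- tensor$values
  values[tensor$mask] <- 2^(values[tensor$mask])
  abundance_tensor(values, tensor$proteins, tensor$samples,
                   mask = tensor$mask, scale = "linear")
}

#' Impute missing log2 abundances
#'
#' Three methods. `"day_mean"`: each missing entry takes the mean of the
#' observed values of the same protein on the same day (falling back to the
#' protein mean if a whole day is unobserved). `"knn"`: the mean of the
#' `k = 10` most correlated complete-in-common proteins' values at that
#' sample, after matching location/scale. `"random_forest"`: iterative
#' forest imputation in the missForest style — initialise with day means,
#' then loop over proteins in increasing-missingness order, regressing each
#' protein's sample vector on all other proteins (ranger, 100 trees,
#' `mtry = floor(sqrt(p - 1))`) and replacing its missing entries with
#' forest predictions; iterate until the relative change in imputed values
#' rises or `max_iter` is reached. Deterministic given `seed`. Observed
#' entries are never altered.
#'
#' @param tensor log2-scale [abundance_tensor()]; every protein must have at
#'   least one observed value.
#' @param method `"random_forest"`, `"knn"` or `"day_mean"`.
#' @param max_iter maximum forest iterations.
#' @param num_trees trees per forest.
#' @param seed integer seed.
#' @return a complete tensor (mask all `TRUE`); attribute `imputed` holds
#'   the logical matrix of entries that were filled in.
#' @export
impute_missing <- function(tensor, method = c("random_forest", "knn", "day_mean"),
                           max_iter = 10L, num_trees = 100L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(tensor, "abundance_tensor"))
  if (tensor$scale != "log2") stop("impute on the log2 scale")
  if (any(rowSums(tensor$mask) == 0L)) {
    stop("protein with zero observed values: ",
         tensor$proteins[rowSums(tensor$mask) == 0L][1L])
  }
  imputed <- !tensor$mask
  if (!any(imputed)) {
    out <- tensor
    attr(out, "imputed") <- imputed
    return(out)
  }
  values <- impute_day_mean(tensor)
  if (method == "knn") {
    values <- impute_knn(tensor, values)
  } else if (method == "random_forest") {
    values <- impute_forest(tensor, values, max_iter, num_trees, seed)
  }
  out <- abundance_tensor(values, tensor$proteins, tensor$samples,
                          scale = "log2")
  attr(out, "imputed") <- imputed
  out
}

impute_day_mean <- function(tensor) {
  values <- tensor$values
  day <- tensor$samples$day
  for (p in which(rowSums(!tensor$mask) > 0L)) {
    for (s in which(!tensor$mask[p, ])) {
      same_day <- day == day[s] & tensor$mask[p, ]
      values[p, s] <- if (any(same_day)) {
        mean(tensor$values[p, same_day])
      } else {
        mean(tensor$values[p, tensor$mask[p, ]])
      }
    }
  }
  values
}

impute_knn <- function(tensor, init, k = 10L) {
  values <- init
  z <- t(scale(t(init)))
  for (p in which(rowSums(!tensor$mask) > 0L)) {
    r <- suppressWarnings(stats::cor(init[p, ], t(init)))
    r[p] <- NA
    nb <- order(-abs(r))[seq_len(min(k, nrow(init) - 1L))]
    mu <- mean(init[p, tensor$mask[p, ]])
    sdev <- stats::sd(init[p, tensor$mask[p, ]])
    if (!is.finite(sdev) || sdev == 0) sdev <- 0
    for (s in which(!tensor$mask[p, ])) {
      values[p, s] <- mu + sdev * mean(z[nb, s] * sign(r[nb]), na.rm = TRUE)
    }
  }
  values
}

impute_forest <- function(tensor, init, max_iter, num_trees, seed) {
  values <- init
  miss_per <- rowSums(!tensor$mask)
  todo <- which(miss_per > 0L)[order(miss_per[miss_per > 0L])]
  prev_diff <- Inf
  best <- values
  for (iter in seq_len(max_iter)) {
    old_imp <- values[!tensor$mask]
    counter <- 0L
    for (p in todo) {
      counter <- counter + 1L
      obs <- tensor$mask[p, ]
      x <- t(values[-p, , drop = FALSE])
      colnames(x) <- paste0("v", seq_len(ncol(x)))
      df_train <- data.frame(.y = values[p, obs], x[obs, , drop = FALSE])
      fit <- ranger::ranger(
        .y ~ ., data = df_train, num.trees = num_trees,
        mtry = max(1L, floor(sqrt(ncol(x)))),
        seed = substream_seed(seed, iter * 100000L + counter),
        num.threads = 1L, verbose = FALSE)
      pred <- stats::predict(fit,
                             data = data.frame(x[!obs, , drop = FALSE]))$predictions
      values[p, !obs] <- pred
    }
    new_imp <- values[!tensor$mask]
    diff <- sum((new_imp - old_imp)^2) / max(sum(new_imp^2), .Machine$double.eps)
    if (diff >= prev_diff) return(best)  # stop when the update worsens
    best <- values
    prev_diff <- diff
    if (diff < 1e-6) break
  }
  best
}

#' Day-0 (baseline) normalisation on the log2 scale
#'
#' Subtracts each individual's day-0 value from that individual's values on
#' every day, protein by protein: the log-scale equivalent of expressing
#' each later timepoint as a ratio to the pre-immunization baseline. Day-0
#' entries become exactly 0.
#'
#' @param tensor complete log2-scale [abundance_tensor()] including day 0.
#' @return the normalized tensor.
#' @export
day0_normalize <- function(tensor) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  if (tensor$scale != "log2") stop("normalize on the log2 scale")
  if (!all(tensor$mask)) stop("tensor has missing values; impute first")
  if (!0L %in% tensor$samples$day) stop("day 0 absent from the design")
  values <- tensor$values
  for (f in unique(tensor$samples$individual)) {
    cols <- which(tensor$samples$individual == f)
    d0 <- cols[tensor$samples$day[cols] == 0L]
    if (length(d0) != 1L) stop("individual ", f, " lacks a day-0 sample")
    values[, cols] <- values[, cols] - values[, d0]
  }
  abundance_tensor(values, tensor$proteins, tensor$samples, scale = "log2")
}

#' Mean profile of a designated protein set (e.g. total IgM)
#'
#' Arithmetic mean of log2 values over the flagged proteins, per individual
#' and day — the log-scale average used to approximate a total
#' immunoglobulin response from several closely related IgM proteins
#' (geometric-mean semantics on the linear scale).
#'
#' @param tensor complete log2-scale [abundance_tensor()].
#' @param accessions non-empty protein set to average.
#' @return data.frame with columns `individual`, `day`, `mean_log2`.
#' @export
mean_igm_profile <- function(tensor, accessions) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  if (length(accessions) == 0L) stop("empty accession set")
  missing <- setdiff(accessions, tensor$proteins)
  if (length(missing)) stop("unknown protein: ", missing[1L])
  if (!all(tensor$mask)) stop("tensor has missing values; impute first")
  rows <- match(accessions, tensor$proteins)
  data.frame(individual = tensor$samples$individual,
             day = tensor$samples$day,
             mean_log2 = colMeans(tensor$values[rows, , drop = FALSE]),
             stringsAsFactors = FALSE, row.names = NULL)
}
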