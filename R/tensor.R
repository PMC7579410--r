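#' Abundance tensor: protein x sample LFQ values with an explicit missing mask
#'
#' The central container of the package: a numeric protein x sample matrix of
#' label-free quantification (LFQ) values together with a logical mask
#' (`TRUE` = observed), the two-factor sample design (individual, day), and a
#' scale flag (`"linear"` for raw LFQ intensities, `"log2"` after
#' transformation). Columns are one sample each and are named
#' `"<individual>_d<day>"`.
#'
#' @param values numeric matrix, proteins in rows, samples in columns.
#' @param proteins character vector of protein (accession) row labels.
#' @param samples data.frame with columns `individual` (character) and `day`
#'   (integer days post-immunization), one row per column of `values`.
#' @param mask logical matrix of the same dimension as `values`; `TRUE` marks
#'   an observed value. Defaults to everything observed.
#' @param scale `"linear"` or `"log2"`.
#'
#' @return An object of class `abundance_tensor`.
#' @export
abundance_tensor <- function(values, proteins, samples,
                             mask = NULL, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!is.logical(mask)) stop("`mask` must be a logical matrix")
  if (!all(dim(values) == dim(mask))) stop("`values` and `mask` dimensions differ")
  proteins <- as.character(proteins)
  if (length(proteins) != nrow(values)) {
    stop("length(proteins) != nrow(values)")
  }
  if (anyDuplicated(proteins)) {
    stop("duplicate protein accession: ",
         proteins[duplicated(proteins)][1L])
  }
  if (!is.data.frame(samples) ||
      !all(c("individual", "day") %in% names(samples))) {
    stop("`samples` must be a data.frame with columns individual, day")
  }
  if (nrow(samples) != ncol(values)) stop("nrow(samples) != ncol(values)")
  samples <- data.frame(individual = as.character(samples$individual),
                        day = as.integer(samples$day),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(samples[c("individual", "day")])) {
    stop("duplicate (individual, day) sample key")
  }
  if (any(!is.finite(values[mask]))) {
    stop("non-finite value at an observed (mask = TRUE) position")
  }
  values[!mask] <- NA_real_
  dimnames(values) <- list(proteins, sample_names(samples))
  dimnames(mask) <- dimnames(values)
  structure(list(values = values, mask = mask, proteins = proteins,
                 samples = samples, scale = scale),
            class = "abundance_tensor")
}

#' @export
print.abundance_tensor <- function(x, ...) {
  cat(sprintf(
    "abundance_tensor: %d proteins x %d samples (%d individuals x %d days), %s scale\n",
    nrow(x$values), ncol(x$values),
    length(unique(x$samples$individual)), length(unique(x$samples$day)),
    x$scale))
  n_miss <- sum(!x$mask)
  cat(sprintf("  missing: %d / %d datapoints (%.2f%%)\n",
              n_miss, length(x$mask), 100 * n_miss / length(x$mask)))
  invisible(x)
}

#' @export
dim.abundance_tensor <- function(x) dim(x$values)

#' Canonical sample column names
#'
#' @param samples data.frame with `individual` and `day` columns.
#' @return character vector `"<individual>_d<day>"`.
#' @keywords internal
sample_names <- function(samples) {
  paste0(samples$individual, "_d", samples$day)
}

#' Parse sample column names of the generic abundance dialect
#'
#' Inverts [sample_names()]: `"F1_d14"` becomes individual `"F1"`, day 14.
#' The individual id may itself contain underscores; the day token is the
#' final `_d<integer>` suffix.
#'
#' @param x character vector of column names.
#' @return data.frame with columns `individual`, `day`.
#' @keywords internal
parse_sample_names <- function(x) {
  m <- regmatches(x, regexec("^(.*)_d([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("unparseable sample column name (expected <individual>_d<day>): ",
         x[bad][1L])
  }
  data.frame(individual = vapply(m, `[`, "", 2L),
             day = as.integer(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Subset an abundance tensor by protein
#'
#' @param tensor an [abundance_tensor()].
#' @param proteins accessions (or logical/integer index) to keep.
#' @return the subset `abundance_tensor`.
#' @export
tensor_subset <- function(tensor, proteins) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  if (is.character(proteins)) {
    missing <- setdiff(proteins, tensor$proteins)
    if (length(missing)) stop("unknown protein: ", missing[1L])
    idx <- match(proteins, tensor$proteins)
  } else {
    idx <- seq_along(tensor$proteins)[proteins]
  }
  abundance_tensor(tensor$values[idx, , drop = FALSE],
                   tensor$proteins[idx], tensor$samples,
                   mask = tensor$mask[idx, , drop = FALSE],
                   scale = tensor$scale)
}
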