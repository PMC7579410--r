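#' Percent identity from a trimmed global alignment
#'
#' Globally aligns the two sequences (match 1, mismatch -1, gap open 10,
#' gap extend 0.5), trims alignment columns outside the shorter sequence's
#' aligned span (i.e. leading/trailing overhang of the longer protein), and
#' returns `100 * matches / trimmed columns`. This mirrors the common
#' practice of trimming pairwise alignments to the shortest protein before
#' recording identity.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  # shorter sequence is the pattern so its span defines the trim
  swap <- nchar(seq_b) < nchar(seq_a)
  p <- if (swap) seq_b else seq_a
  s <- if (swap) seq_a else seq_b
  sm <- aa_score_matrix()
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p), Biostrings::AAString(s),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  as <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  non_gap <- which(ap != "-")
  span <- seq(min(non_gap), max(non_gap))
  100 * sum(ap[span] == as[span]) / length(span)
}

aa_score_matrix <- function() {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1L]]
  m <- matrix(-1, length(letters20), length(letters20),
              dimnames = list(letters20, letters20))
  diag(m) <- 1
  m
}

#' Percent of peptides shared between two proteins
#'
#' `100 * |A inter B| / min(|A|, |B|)`: the smaller peptide set is the
#' denominator, so a protein whose peptides are nested within another's
#' scores 100 even when the sequences differ.
#'
#' @param pep_a,pep_b character vectors of peptides.
#' @param denominator `"min"` (default) or `"union"` (Jaccard).
#' @return percent in `[0, 100]`.
#' @export
shared_peptide_fraction <- function(pep_a, pep_b,
                                    denominator = c("min", "union")) {
  denominator <- match.arg(denominator)
  pep_a <- unique(pep_a); pep_b <- unique(pep_b)
  if (length(pep_a) == 0L && length(pep_b) == 0L) {
    stop("both peptide sets empty")
  }
  inter <- sum(pep_a %in% pep_b)
  den <- if (denominator == "min") min(length(pep_a), length(pep_b)) else
    length(union(pep_a, pep_b))
  if (den == 0L) return(0)
  100 * inter / den
}

#' Find duplicated proteins by identity and coverage
#'
#' All unordered pairs with trimmed-alignment identity above
#' `identity_cutoff` and mutual length coverage (shorter/longer length)
#' above `coverage_cutoff`, excluding pairs annotated to the same gene
#' (isoforms are not duplicates). Pairs are returned in canonical
#' `acc_a < acc_b` order with an `is_ss4r` flag from reciprocal ohnolog
#' metadata when present.
#'
#' @param proteins a [protein_records()] data.frame (>= 2 rows).
#' @param identity_cutoff,coverage_cutoff percent cutoffs (defaults 70/70,
#'   the usual BLASTp screening thresholds for WGD duplicates).
#' @return data.frame with columns `acc_a`, `acc_b`, `identity_pct`,
#'   `coverage_pct`, `is_ss4r`.
#' @export
find_duplicates <- function(proteins, identity_cutoff = 70,
                            coverage_cutoff = 70) {
  if (nrow(proteins) < 2L) stop("need at least two proteins")
  use <- !proteins$is_decoy & !proteins$is_contaminant
  prot <- proteins[use, , drop = FALSE]
  n <- nrow(prot)
  lens <- nchar(prot$sequence)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!is.na(prot$gene_id[i]) && !is.na(prot$gene_id[j]) &&
          prot$gene_id[i] == prot$gene_id[j]) next
      cov <- 100 * min(lens[i], lens[j]) / max(lens[i], lens[j])
      if (cov <= coverage_cutoff) next
      ident <- pairwise_identity(prot$sequence[i], prot$sequence[j])
      if (ident <= identity_cutoff) next
      a <- i; b <- j
      if (prot$accession[b] < prot$accession[a]) { a <- j; b <- i }
      rows[[length(rows) + 1L]] <- data.frame(
        acc_a = prot$accession[a], acc_b = prot$accession[b],
        identity_pct = ident, coverage_pct = cov,
        is_ss4r = is_ohnolog_pair(prot, a, b),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(acc_a = character(), acc_b = character(),
                      identity_pct = numeric(), coverage_pct = numeric(),
                      is_ss4r = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

is_ohnolog_pair <- function(prot, i, j) {
  ci <- prot$chromosome[i]; cj <- prot$chromosome[j]
  !is.na(ci) && !is.na(cj) &&
    identical(ci, paste0("ohnolog:", prot$accession[j])) &&
    identical(cj, paste0("ohnolog:", prot$accession[i]))
}

#' Classify duplicate pairs against the protein-group structure
#'
#' Annotates each duplicate pair with whether its two proteins fell into
#' the same majority protein group, the shared-peptide percentage, and an
#' Ss4R (whole-genome-duplication ohnolog) flag; classifies each group as
#' scenario i (contains a duplicate pair from distinct genes), scenario ii
#' (its members' duplicates all sit in other groups), or no-duplicate. An
#' optional homeolog chromosome-pair table (`data.frame` with columns
#' `chr_a`, `chr_b`) can supply the Ss4R labels from chromosome metadata
#' instead of generator ohnolog tags.
#'
#' @param groups an `mpg_list` from [assemble_groups()].
#' @param pairs data.frame from [find_duplicates()].
#' @param proteins optional [protein_records()] for chromosome lookup.
#' @param homeolog_pairs optional data.frame of homeologous chromosome
#'   pairs (`chr_a`, `chr_b`).
#' @return list with `pairs` (annotated: + `same_mpg`, `shared_pct` left to
#'   the caller via [annotate_shared_peptides()]) and `summary` (data.frame
#'   counts: `n_no_duplicate`, `n_scenario_i`, `n_scenario_ii`).
#' @export
classify_scenarios <- function(groups, pairs, proteins = NULL,
                               homeolog_pairs = NULL) {
  stopifnot(inherits(groups, "mpg_list"))
  member_of <- group_membership(groups)
  in_pairs <- unique(c(pairs$acc_a, pairs$acc_b))
  unknown <- setdiff(in_pairs, names(member_of))
  if (length(unknown)) {
    stop("pair references protein absent from groups: ", unknown[1L])
  }
  pairs$same_mpg <- if (nrow(pairs)) {
    member_of[pairs$acc_a] == member_of[pairs$acc_b]
  } else logical(0)
  if (!is.null(homeolog_pairs) && !is.null(proteins) && nrow(pairs)) {
    chr <- stats::setNames(proteins$chromosome, proteins$accession)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    homeo <- key(homeolog_pairs$chr_a, homeolog_pairs$chr_b)
    pairs$is_ss4r <- key(chr[pairs$acc_a], chr[pairs$acc_b]) %in% homeo
  }
  gid <- vapply(groups, `[[`, 1L, "group_id")
  has_dup <- unique(member_of[in_pairs])
  internal <- unique(member_of[pairs$acc_a[pairs$same_mpg]])
  n_i <- length(internal)
  n_ii <- length(setdiff(has_dup, internal))
  n_none <- length(gid) - n_i - n_ii
  list(pairs = pairs,
       summary = data.frame(n_no_duplicate = n_none,
                            n_scenario_i = n_i,
                            n_scenario_ii = n_ii))
}

group_membership <- function(groups) {
  members <- lapply(groups, `[[`, "members")
  stats::setNames(rep(vapply(groups, `[[`, 1L, "group_id"),
                      vapply(members, length, 1L)),
                  unlist(members, use.names = FALSE))
}

#' Annotate duplicate pairs with shared-peptide percentages
#'
#' @param pairs data.frame from [find_duplicates()].
#' @param index a [build_peptide_index()] result.
#' @return `pairs` with a `shared_pct` column.
#' @export
annotate_shared_peptides <- function(pairs, index) {
  stopifnot(inherits(index, "peptide_index"))
  pairs$shared_pct <- vapply(seq_len(nrow(pairs)), function(i) {
    shared_peptide_fraction(index$prot2pep[[pairs$acc_a[i]]],
                            index$prot2pep[[pairs$acc_b[i]]])
  }, 1.0)
  pairs
}

#' Table-1-style stratum summary of duplicate pairs
#'
#' Means, SDs and ranges of percent identity and percent shared peptides,
#' stratified by same-group vs different-group and Ss4R vs other.
#'
#' @param pairs annotated pairs (`identity_pct`, `shared_pct`, `same_mpg`,
#'   `is_ss4r`).
#' @return data.frame, one row per stratum.
#' @export
scenario_table <- function(pairs) {
  strat <- function(sub, label) {
    if (nrow(sub) == 0L) return(NULL)
    data.frame(stratum = label, n = nrow(sub),
               identity_mean = mean(sub$identity_pct),
               identity_sd = stats::sd(sub$identity_pct),
               identity_min = min(sub$identity_pct),
               identity_max = max(sub$identity_pct),
               shared_mean = mean(sub$shared_pct),
               shared_sd = stats::sd(sub$shared_pct),
               shared_min = min(sub$shared_pct),
               shared_max = max(sub$shared_pct),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    strat(pairs[pairs$same_mpg & pairs$is_ss4r, ], "same_mpg_ss4r"),
    strat(pairs[pairs$same_mpg & !pairs$is_ss4r, ], "same_mpg_other"),
    strat(pairs[!pairs$same_mpg & pairs$is_ss4r, ], "diff_mpg_ss4r"),
    strat(pairs[!pairs$same_mpg & !pairs$is_ss4r, ], "diff_mpg_other")))
}

#' Correlate percent identity with shared-peptide percentage
#'
#' Pearson correlation with a two-sided p-value from the t transform,
#' within one group-membership stratum, quantifying how sequence
#' divergence drives peptide sharing (and hence co-grouping) of
#' duplicated proteins.
#'
#' @param pairs annotated pairs.
#' @param stratum `"same_mpg"`, `"different_mpg"` or `"all"`.
#' @return list with `r`, `p`, `n`.
#' @export
correlate_identity_sharing <- function(pairs,
                                       stratum = c("all", "same_mpg",
                                                   "different_mpg")) {
  stratum <- match.arg(stratum)
  sub <- switch(stratum,
                all = pairs,
                same_mpg = pairs[pairs$same_mpg, , drop = FALSE],
                different_mpg = pairs[!pairs$same_mpg, , drop = FALSE])
  if (nrow(sub) < 3L) stop("fewer than 3 pairs in stratum")
  x <- sub$identity_pct; y <- sub$shared_pct
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in identity or sharing")
  }
  r <- stats::cor(x, y)
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE), n = n)
}
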