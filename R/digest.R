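#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P (the
#' classical trypsin rule), returns every fragment spanning at most
#' `missed_cleavages` internal cleavage sites, filtered to
#' `[min_len, max_len]` residues. Duplicate fragments collapse to a set.
#'
#' @param sequence amino-acid string.
#' @param missed_cleavages maximum internal cleavage sites per peptide.
#' @param min_len,max_len peptide length bounds (defaults 7 and 35, typical
#'   LC-MS detectability bounds).
#' @return character vector of unique peptides.
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 2L,
                           min_len = 7L, max_len = 35L) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence")
  stopifnot(missed_cleavages >= 0L, min_len >= 1L, min_len <= max_len)
  aa <- strsplit(sequence, "")[[1L]]
  n <- length(aa)
  # cleavage after position i: K/R at i, not followed by P
  cut_after <- which(aa[-n] %in% c("K", "R") & aa[-1L] != "P")
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  n_frag <- length(starts)
  peps <- character(0)
  for (i in seq_len(n_frag)) {
    for (j in i:min(n_frag, i + missed_cleavages)) {
      len <- ends[j] - starts[i] + 1L
      if (len >= min_len && len <= max_len) {
        peps <- c(peps, substr(sequence, starts[i], ends[j]))
      }
    }
  }
  unique(peps)
}

#' Peptide index: bipartite map between peptides and proteins
#'
#' Digests every non-decoy, non-contaminant protein and retains each
#' distinct peptide with probability `detectability` — atomically, so a
#' shared peptide is observed (or not) for all proteins carrying it, as a
#' real LC-MS run would. Proteins whose peptides are all dropped stay in
#' the index with an empty set and are listed in the `warnings` attribute.
#'
#' @param proteins a [protein_records()] data.frame.
#' @param missed_cleavages,min_len,max_len digestion parameters, see
#'   [tryptic_digest()].
#' @param detectability probability a distinct peptide is observed.
#' @param seed integer seed for the detectability draw.
#' @return object of class `peptide_index`: list with `prot2pep` (named list
#'   accession -> peptide character vector) and `pep2prot` (named list
#'   peptide -> accession character vector).
#' @export
build_peptide_index <- function(proteins, missed_cleavages = 2L,
                                min_len = 7L, max_len = 35L,
                                detectability = 1, seed = 1L) {
  if (detectability <= 0 || detectability > 1) {
    stop("detectability must be in (0, 1]")
  }
  use <- !proteins$is_decoy & !proteins$is_contaminant
  acc <- proteins$accession[use]
  prot2pep <- lapply(proteins$sequence[use], tryptic_digest,
                     missed_cleavages = missed_cleavages,
                     min_len = min_len, max_len = max_len)
  names(prot2pep) <- acc
  all_peps <- sort(unique(unlist(prot2pep, use.names = FALSE)))
  if (detectability < 1) {
    keep <- with_seed(substream_seed(seed, 11L),
                      stats::runif(length(all_peps)) < detectability)
    kept <- all_peps[keep]
    prot2pep <- lapply(prot2pep, function(p) p[p %in% kept])
    all_peps <- kept
  }
  empty <- acc[vapply(prot2pep, length, 1L) == 0L]
  if (length(empty)) {
    warning("proteins with no retained peptides: ",
            paste(empty, collapse = ", "))
  }
  pep2prot <- split(
    rep(names(prot2pep), vapply(prot2pep, length, 1L)),
    unlist(prot2pep, use.names = FALSE)
  )
  structure(list(prot2pep = prot2pep, pep2prot = pep2prot),
            class = "peptide_index", warnings = empty)
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("peptide_index: %d proteins, %d distinct peptides\n",
              length(x$prot2pep), length(x$pep2prot)))
  invisible(x)
}

#' Assemble majority protein groups under the shared-peptide rule
#'
#' Greedy seeding: proteins are sorted by descending peptide count (ties by
#' ascending accession); the first unassigned protein seeds a group as its
#' lead, and every other unassigned protein P joins if
#' `|pep(P) inter pep(lead)| / |pep(P)| >= sharing_threshold` — the
#' candidate's own peptides are the denominator, so a protein whose
#' peptides are a subset of the lead's always joins (majority semantics, as
#' protein-group tools treat indistinguishable isoforms). Membership is
#' evaluated against the lead only, not transitively. Proteins with empty
#' peptide sets are excluded and reported.
#'
#' @param index a [build_peptide_index()] result.
#' @param sharing_threshold minimum shared fraction, in `(0, 1]`; the
#'   field-standard rule uses 0.5 ("at least 50% of their peptides").
#' @return list of class `mpg_list`: each element has `group_id`, `lead`,
#'   `members`, `group_peptides`; groups ordered by descending group peptide
#'   count. Attribute `excluded` lists empty-set proteins.
#' @export
assemble_groups <- function(index, sharing_threshold = 0.5) {
  stopifnot(inherits(index, "peptide_index"))
  if (sharing_threshold <= 0 || sharing_threshold > 1) {
    stop("sharing_threshold must be in (0, 1]")
  }
  sets <- index$prot2pep
  counts <- vapply(sets, length, 1L)
  excluded <- names(sets)[counts == 0L]
  sets <- sets[counts > 0L]
  ord <- order(-vapply(sets, length, 1L), names(sets))
  sets <- sets[ord]
  acc <- names(sets)
  assigned <- rep(FALSE, length(sets))
  groups <- list()
  while (!all(assigned)) {
    lead_i <- which(!assigned)[1L]
    lead_pep <- sets[[lead_i]]
    members <- lead_i
    for (j in which(!assigned)) {
      if (j == lead_i) next
      shared <- sum(sets[[j]] %in% lead_pep)
      if (shared / length(sets[[j]]) >= sharing_threshold) {
        members <- c(members, j)
      }
    }
    assigned[members] <- TRUE
    groups[[length(groups) + 1L]] <- list(
      lead = acc[lead_i],
      members = sort(acc[members]),
      group_peptides = sort(unique(unlist(sets[members], use.names = FALSE)))
    )
  }
  sizes <- vapply(groups, function(g) length(g$group_peptides), 1L)
  groups <- groups[order(-sizes)]
  for (i in seq_along(groups)) groups[[i]]$group_id <- i
  structure(groups, class = "mpg_list", excluded = excluded)
}

#' @export
print.mpg_list <- function(x, ...) {
  cat(sprintf("mpg_list: %d majority protein groups over %d proteins\n",
              length(x), sum(vapply(x, function(g) length(g$members), 1L))))
  invisible(x)
}

#' Flatten a group list to a data.frame
#'
#' @param groups an `mpg_list` from [assemble_groups()].
#' @return data.frame with columns `group_id`, `lead`, `members`
#'   (semicolon-joined), `n_members`, `n_peptides`.
#' @export
groups_table <- function(groups) {
  stopifnot(inherits(groups, "mpg_list"))
  data.frame(
    group_id = vapply(groups, `[[`, 1L, "group_id"),
    lead = vapply(groups, `[[`, "", "lead"),
    members = vapply(groups, function(g) paste(g$members, collapse = ";"), ""),
    n_members = vapply(groups, function(g) length(g$members), 1L),
    n_peptides = vapply(groups, function(g) length(g$group_peptides), 1L),
    stringsAsFactors = FALSE)
}
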