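#' Protein record table
#'
#' Proteins are carried as a plain data.frame with one row per sequence and
#' columns `accession`, `sequence`, `gene_id`, `chromosome`,
#' `is_contaminant`, `is_decoy`. `gene_id`/`chromosome` are `NA` when absent.
#'
#' @param accession character accessions (unique, non-empty).
#' @param sequence character amino-acid sequences (uppercase, the 20
#'   canonical residues plus X).
#' @param gene_id,chromosome optional metadata.
#' @param is_contaminant,is_decoy logical flags.
#' @return data.frame of protein records.
#' @export
protein_records <- function(accession, sequence, gene_id = NA_character_,
                            chromosome = NA_character_,
                            is_contaminant = FALSE, is_decoy = FALSE) {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(accession))) stop("empty accession")
  if (anyDuplicated(accession)) {
    stop("duplicate accession: ", accession[duplicated(accession)][1L])
  }
  if (any(nchar(sequence) < 1L)) stop("zero-length sequence")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)
  if (any(bad)) {
    stop("non-canonical residue in sequence of ", accession[bad][1L])
  }
  data.frame(accession = accession, sequence = sequence,
             gene_id = rep_len(as.character(gene_id), length(accession)),
             chromosome = rep_len(as.character(chromosome), length(accession)),
             is_contaminant = rep_len(is_contaminant, length(accession)),
             is_decoy = rep_len(is_decoy, length(accession)),
             stringsAsFactors = FALSE)
}

#' Read a protein FASTA file
#'
#' The accession is the header token before the first whitespace. Headers
#' whose accession begins with a configured prefix are flagged as
#' contaminants / decoys (MaxQuant's `CON__` / `REV__` convention); the
#' prefix is retained in the accession.
#'
#' @param path FASTA file.
#' @param contaminant_prefix,decoy_prefix accession prefixes marking
#'   contaminant and decoy (reversed) entries.
#' @return a [protein_records()] data.frame.
#' @export
read_fasta <- function(path, contaminant_prefix = "CON__",
                       decoy_prefix = "REV__") {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  acc <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(acc)) {
    stop("duplicate accession in FASTA: ", acc[duplicated(acc)][1L])
  }
  protein_records(acc, as.character(aa),
                  is_contaminant = startsWith(acc, contaminant_prefix),
                  is_decoy = startsWith(acc, decoy_prefix))
}

#' Write protein records as 60-column-wrapped FASTA
#'
#' @param records a [protein_records()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0L) stop("no records to write")
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- records$accession
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a protein x sample abundance table
#'
#' Two tab-delimited dialects are supported. `generic`: first column the
#' accession, remaining columns named `"<individual>_d<day>"`, values linear
#' LFQ intensities. `maxquant`: the proteinGroups.txt layout with columns
#' `Majority protein IDs`, `LFQ intensity <sample>` (sample again
#' `<individual>_d<day>`), `Reverse` and `Potential contaminant`; rows
#' flagged `+` in either flag column are dropped. In both dialects a zero or
#' blank cell is a non-detection and enters the tensor as missing, following
#' the MaxQuant convention that LFQ zero means "not quantified".
#'
#' @param path tab-delimited file.
#' @param dialect `"generic"` or `"maxquant"`.
#' @return an [abundance_tensor()] on the linear scale.
#' @export
read_abundance_table <- function(path, dialect = c("generic", "maxquant")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  if (nrow(tab) == 0L) stop("no data rows in ", path)
  if (dialect == "generic") {
    acc <- tab[[1L]]
    value_cols <- names(tab)[-1L]
    samples <- parse_sample_names(value_cols)
    raw <- tab[value_cols]
  } else {
    need <- c("Majority protein IDs", "Reverse", "Potential contaminant")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("maxquant dialect: missing column ", miss[1L])
    keep <- tab$Reverse != "+" & tab$`Potential contaminant` != "+"
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) == 0L) stop("all rows flagged Reverse/contaminant in ", path)
    acc <- tab$`Majority protein IDs`
    value_cols <- grep("^LFQ intensity ", names(tab), value = TRUE)
    if (length(value_cols) == 0L) stop("maxquant dialect: no 'LFQ intensity' columns")
    samples <- parse_sample_names(sub("^LFQ intensity ", "", value_cols))
    raw <- tab[value_cols]
  }
  values <- vapply(raw, parse_lfq_column, numeric(nrow(tab)))
  if (nrow(tab) == 1L) values <- matrix(values, nrow = 1L)
  mask <- is.finite(values) & values != 0
  values[!mask] <- NA_real_
  abundance_tensor(values, acc, samples, mask = mask, scale = "linear")
}

# strict locale-independent numeric parse: decimal point only, blanks allowed
parse_lfq_column <- function(x) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  nonblank <- nzchar(x)
  ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$",
              x[nonblank])
  if (any(!ok)) {
    stop("unparseable abundance value: '", x[nonblank][!ok][1L], "'")
  }
  out[nonblank] <- as.numeric(x[nonblank])
  out
}

#' Write an abundance tensor as a generic-dialect TSV
#'
#' Missing entries are written as empty cells; on the linear scale they may
#' equivalently be read back from zeros.
#'
#' @param tensor an [abundance_tensor()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(tensor, path) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  vals <- format_num(tensor$values)
  vals[!tensor$mask] <- ""
  out <- data.frame(protein = tensor$proteins, vals,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("protein", sample_names(tensor$samples))
  write_results(out, path)
}

#' Write a tabular result as TSV
#'
#' Tab-delimited, UTF-8, LF line endings, header row, columns in the order
#' given. Numeric columns are written with 15 significant digits so a
#' write/read round trip is lossless well past 12 significant digits.
#'
#' @param records non-empty data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records to write")
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

format_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[!is.finite(x) & !is.na(x)] <- as.character(x[!is.finite(x) & !is.na(x)])
  out[is.na(x)] <- NA_character_
  gsub(" ", "", out)
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values that parse as numbers are returned numeric; comma-separated values
#' become vectors (so `days = 0,7,14` yields a numeric vector).
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!all(grepl("=", lines, fixed = TRUE))) {
    stop("configuration line without '=': ",
         lines[!grepl("=", lines, fixed = TRUE)][1L])
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  parse1 <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }
  stats::setNames(lapply(vals, parse1), keys)
}
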