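#' Column mapping for MaxQuant-dialect peptide tables
#'
#' Resolves dialect differences between MaxQuant versions. The defaults
#' match the 1.5.x modification-specific peptide table: reporter columns
#' named `"Reporter intensity corrected <i> <experiment>"` and quality flags
#' encoded as `"+"` / blank.
#'
#' @param sequence,proteins,reverse,contaminant,only_by_site Column names.
#' @param reporter_prefix Prefix identifying reporter-intensity columns; all
#'   columns starting with it are loaded as channels.
#' @return A named list used by [read_peptide_table()].
#' @export
mq_column_map <- function(sequence = "Sequence",
                          proteins = "Proteins",
                          reverse = "Reverse",
                          contaminant = "Potential contaminant",
                          only_by_site = "Only identified by site",
                          reporter_prefix = "Reporter intensity corrected") {
  list(sequence = sequence, proteins = proteins, reverse = reverse,
       contaminant = contaminant, only_by_site = only_by_site,
       reporter_prefix = reporter_prefix)
}

#' Read a MaxQuant-style modification-specific peptide table
#'
#' Loads a tab-separated peptide table, normalizes the MaxQuant conventions
#' (flags `"+"`/blank to logical, reporter intensities of 0 or blank to
#' missing) and derives the leading protein accession. A reporter intensity
#' written as exactly 0 is treated as missing, not as a measured zero:
#' MaxQuant writes 0 for unquantified reporter channels, and the downstream
#' SH-to-zero imputation presupposes absence.
#'
#' @param path Path to the TSV file.
#' @param column_map A [mq_column_map()].
#' @return A tibble with columns `sequence`, `proteins`, `leading_protein`,
#'   logical flags `reverse`, `contaminant`, `only_by_site`, and one numeric
#'   column per reporter channel (the original column names). The channel
#'   names are stored in attribute `channels`. No rows are dropped.
#' @export
read_peptide_table <- function(path, column_map = mq_column_map()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  mandatory <- c(column_map$sequence, column_map$proteins)
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stopf("cysredox_format_error",
          "peptide table is missing mandatory columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  channels <- grep(paste0("^", column_map$reporter_prefix), names(raw),
                   value = TRUE)
  if (!length(channels)) {
    stopf("cysredox_format_error",
          "no reporter-intensity columns with prefix '%s' found",
          column_map$reporter_prefix)
  }

  flag <- function(col) {
    if (col %in% names(raw)) {
      trimws(raw[[col]]) == "+"
    } else {
      rep(FALSE, nrow(raw))
    }
  }
  out <- tibble::tibble(
    sequence = toupper(raw[[column_map$sequence]]),
    proteins = raw[[column_map$proteins]],
    leading_protein = first_accession(raw[[column_map$proteins]]),
    reverse = flag(column_map$reverse),
    contaminant = flag(column_map$contaminant),
    only_by_site = flag(column_map$only_by_site)
  )
  for (ch in channels) {
    cell <- trimws(raw[[ch]])
    empty <- cell == "" | cell == "NA" | cell == "NaN"
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(val))
    if (length(bad)) {
      stopf("cysredox_format_error",
            "non-numeric intensity '%s' in column '%s', row %d",
            cell[bad[1]], ch, bad[1])
    }
    if (any(val < 0, na.rm = TRUE)) {
      stopf("cysredox_format_error",
            "negative intensity in column '%s'", ch)
    }
    val[empty | val == 0] <- NA_real_
    out[[ch]] <- val
  }
  attr(out, "channels") <- channels
  out
}

#' Read a protein FASTA database
#'
#' Accessions are parsed from the first whitespace-delimited token of each
#' header; UniProt-style `db|ACC|name` headers yield the central accession.
#' Wrapped sequence lines are concatenated and upper-cased.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `accession` and `sequence`.
#' @export
read_fasta_proteins <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  token <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  accession <- vapply(token, function(tk) {
    parts <- strsplit(tk, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) parts[2] else parts[1]
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(accession)) {
    stopf("cysredox_format_error", "duplicate accessions in FASTA: %s",
          paste(unique(accession[duplicated(accession)]), collapse = ", "))
  }
  tibble::tibble(accession = accession,
                 sequence = unname(toupper(as.character(aas))))
}

#' Write a protein table as FASTA
#'
#' @param proteins Tibble with `accession` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_proteins <- function(proteins, path) {
  aas <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                          proteins$accession))
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Read a cysteine-annotation table
#'
#' A tab-separated, UniProt-derived table with one row per annotated
#' cysteine: protein accession, 1-based residue position, and a label such
#' as `disulfide` or `s_nitrosylation`. Duplicate rows are collapsed.
#'
#' @param path TSV path with columns `accession`, `position`, `label`.
#' @return A tibble with those three columns, unique rows.
#' @export
read_annotations <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("accession", "position", "label")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stopf("cysredox_format_error",
          "annotation table is missing columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  pos <- suppressWarnings(as.numeric(raw$position))
  if (any(is.na(pos)) || any(pos != floor(pos))) {
    stopf("cysredox_format_error", "annotation positions must be integers")
  }
  if (any(pos < 1)) {
    stopf("cysredox_format_error",
          "annotation positions are 1-based and must be >= 1")
  }
  dplyr::distinct(tibble::tibble(
    accession = raw$accession,
    position = as.integer(pos),
    label = raw$label
  ))
}

#' Write a results table as TSV
#'
#' Numeric columns are rendered with 6 significant digits and missing values
#' as `"NA"`, which makes write-then-read lossless at the declared precision.
#'
#' @param results A data frame (e.g. a tidied differential-oxidation result).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- dplyr::mutate(tibble::as_tibble(results), dplyr::across(
    dplyr::where(is.numeric),
    function(x) {
      ifelse(is.na(x), NA_real_, signif(x, 6))
    }
  ))
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.list),
    function(x) vapply(x, function(e) paste(unlist(e), collapse = ";"),
                       character(1))
  ))
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}
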