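#' Map peptide cysteines to protein coordinates
#'
#' Locates each peptide as a substring of its leading protein and emits one
#' record per cysteine with its 1-based position in the protein. Peptides
#' that occur at more than one position are flagged `ambiguous` and emit no
#' sites (coordinates would be arbitrary); peptides whose protein is absent
#' from the database or that are not substrings of it are flagged
#' `unmapped`.
#'
#' @param peptides Tibble with columns `sequence` and `leading_protein`
#'   (one row per unique peptide; extra columns are preserved in `status`
#'   output).
#' @param proteins Tibble from [read_fasta_proteins()].
#' @return A list with `sites` (tibble: `sequence`, `leading_protein`,
#'   `start`, `pep_offset`, `position` — one row per mapped cysteine) and
#'   `status` (tibble: one row per peptide with `status` in
#'   `mapped`/`ambiguous`/`unmapped`).
#' @export
map_peptides_to_sites <- function(peptides, proteins) {
  peptides <- dplyr::distinct(peptides[, c("sequence", "leading_protein")])
  seq_lookup <- setNames(proteins$sequence, proteins$accession)

  recs <- purrr::map(seq_len(nrow(peptides)), function(i) {
    pep <- peptides$sequence[i]
    acc <- peptides$leading_protein[i]
    prot <- if (acc %in% names(seq_lookup)) seq_lookup[[acc]] else NULL
    if (is.null(prot) || is.na(prot)) {
      return(list(status = "unmapped", sites = NULL))
    }
    starts <- as.integer(
      gregexpr(pep, prot, fixed = TRUE)[[1]])
    starts <- starts[starts > 0]
    if (length(starts) == 0L) {
      return(list(status = "unmapped", sites = NULL))
    }
    if (length(starts) > 1L) {
      return(list(status = "ambiguous", sites = NULL))
    }
    offs <- which(strsplit(pep, "")[[1]] == "C")
    if (!length(offs)) {
      return(list(status = "mapped", sites = NULL))
    }
    list(status = "mapped",
         sites = tibble::tibble(
           sequence = pep, leading_protein = acc,
           start = starts, pep_offset = offs,
           position = starts + offs - 1L))
  })

  status <- dplyr::mutate(peptides,
                          status = vapply(recs, `[[`, character(1), "status"))
  sites <- purrr::map_dfr(recs, "sites")
  if (nrow(sites)) {
    # every mapped coordinate must point at a cysteine
    res <- substr(seq_lookup[sites$leading_protein], sites$position,
                  sites$position)
    stopifnot(all(res == "C"))
  }
  list(sites = sites, status = status)
}

#' Aggregate peptide-level oxidation to unique cysteine sites
#'
#' One record per (accession, position). A site's per-condition oxidation
#' summary is the median across its supporting peptides' condition means —
#' robust to a single outlying peptide. Multi-cysteine peptides contribute
#' their (shared) peptide-level value to each of their sites.
#'
#' @param results A `redox_diff` tibble (or any tibble with `sequence`,
#'   `leading_protein`, `mean_ox_A`, `mean_ox_B`).
#' @param mapping Output of [map_peptides_to_sites()].
#' @param stat Aggregation statistic, `"median"` (default) or `"mean"`.
#' @return A tibble with one row per site: `accession`, `position`,
#'   `n_supporting_peptides`, `supporting_peptides` (list column of peptide
#'   keys), `ox_A`, `ox_B`, `any_significant`.
#' @export
aggregate_to_sites <- function(results, mapping, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  fun <- if (stat == "median") {
    function(x) if (any(!is.na(x))) median(x, na.rm = TRUE) else NA_real_
  } else {
    function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_
  }
  joined <- dplyr::inner_join(mapping$sites, results,
                              by = c("sequence", "leading_protein"))
  has_sig <- "significant" %in% names(joined)
  dplyr::summarise(
    dplyr::group_by(joined, accession = .data$leading_protein,
                    .data$position),
    n_supporting_peptides = dplyr::n(),
    supporting_peptides = list(peptide_key(.data$sequence,
                                           .data$leading_protein)),
    ox_A = fun(.data$mean_ox_A),
    ox_B = fun(.data$mean_ox_B),
    any_significant = if (has_sig) any(.data$significant) else NA,
    .groups = "drop"
  )
}

#' Match cysteine annotations to sites and peptides
#'
#' Site records receive their exact annotation labels. A peptide receives a
#' label if at least one of its mapped cysteine sites carries it — the rule
#' used for assigning disulphide-bond annotations to multi-cysteine
#' peptides.
#'
#' @param mapping Output of [map_peptides_to_sites()].
#' @param annotations Tibble from [read_annotations()].
#' @return A list with `sites` (tibble: `accession`, `position`, `labels`
#'   list column, one row per annotated mapped site) and `peptides`
#'   (tibble: `sequence`, `leading_protein`, `labels` list column — every
#'   mapped peptide, empty character for unannotated).
#' @export
annotate_sites <- function(mapping, annotations) {
  sites <- dplyr::left_join(
    mapping$sites,
    dplyr::rename(annotations, leading_protein = "accession"),
    by = c("leading_protein", "position"),
    relationship = "many-to-many")

  site_labels <- dplyr::summarise(
    dplyr::group_by(sites, accession = .data$leading_protein,
                    .data$position),
    labels = list(sort(unique(stats::na.omit(.data$label)))),
    .groups = "drop")

  pep_labels <- dplyr::summarise(
    dplyr::group_by(sites, .data$sequence, .data$leading_protein),
    labels = list(sort(unique(stats::na.omit(.data$label)))),
    .groups = "drop")

  list(sites = site_labels, peptides = pep_labels)
}
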