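#' In-silico trypsin/P digestion
#'
#' Cleaves a protein sequence C-terminal to every lysine (K) and arginine (R).
#' Unlike plain trypsin, trypsin/P does not suppress cleavage before proline;
#' this matches the enzyme rule used by MaxQuant's "Trypsin/P" setting.
#' All fully specific peptides with up to `max_missed_cleavages` internal
#' cleavage sites are returned, each with its 1-based start coordinate in the
#' protein.
#'
#' @param sequence Upper-case amino-acid string (20-letter alphabet).
#' @param max_missed_cleavages Maximum number of internal K/R cleavage sites
#'   a reported peptide may span (0 = fully cleaved peptides only).
#' @param min_length,max_length Optional peptide length filter applied after
#'   digestion (defaults keep everything).
#'
#' @return A tibble with columns `peptide`, `start` (1-based), and
#'   `missed_cleavages`, ordered by start then peptide length.
#' @export
#' @examples
#' digest_trypsin_p("MKACRPK", 0)
#' digest_trypsin_p("MKACRPK", 1)
digest_trypsin_p <- function(sequence, max_missed_cleavages = 2,
                             min_length = 1L, max_length = Inf) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stopf("cysredox_input_error", "sequence must be a non-empty string")
  }
  if (max_missed_cleavages < 0) {
    stopf("cysredox_input_error", "max_missed_cleavages must be >= 0")
  }
  assert_aa(sequence)

  n <- nchar(sequence)
  res <- strsplit(sequence, "")[[1]]
  # cut points: boundary after position i for every K/R (and sequence ends)
  cuts <- which(res %in% c("K", "R"))
  cuts <- cuts[cuts < n]                  # a terminal K/R adds no boundary
  bounds <- c(0L, cuts, n)                # fragment boundaries

  n_frag <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(n_frag)) {
    for (mc in 0:min(max_missed_cleavages, n_frag - i)) {
      from <- bounds[i] + 1L
      to <- bounds[i + 1L + mc]
      out[[length(out) + 1L]] <- list(
        peptide = substr(sequence, from, to),
        start = from,
        missed_cleavages = mc
      )
    }
  }
  tbl <- purrr::map_dfr(out, tibble::as_tibble)
  tbl <- dplyr::filter(tbl,
                       nchar(.data$peptide) >= min_length,
                       nchar(.data$peptide) <= max_length)
  dplyr::arrange(tbl, .data$start, nchar(.data$peptide))
}
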