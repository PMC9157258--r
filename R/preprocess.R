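#' Filter a peptide table for quantifiable cysteine peptides
#'
#' Applies, in order: removal of contaminant rows, reverse (decoy) rows,
#' rows identified only by site, peptides without a cysteine, and rows with
#' no quantitative information at all (both the SH and the Sox channel
#' missing in every replicate of every condition). Each rule's removal count
#' is recorded in the `filter_report` attribute; counts sum to
#' `rows in - rows out`. The function is idempotent.
#'
#' @param table A tibble from [read_peptide_table()] (or the same shape).
#' @param design A [redox_design()] whose channels appear in `table`.
#' @return The filtered tibble, with attribute `filter_report`: a tibble of
#'   `rule` and `removed`.
#' @export
filter_records <- function(table, design) {
  chans <- design$channels$channel
  missing_ch <- setdiff(chans, names(table))
  if (length(missing_ch)) {
    stopf("cysredox_config_error",
          "design channels absent from table: %s",
          paste(missing_ch, collapse = ", "))
  }
  n0 <- nrow(table)
  counts <- c(contaminant = 0L, reverse = 0L, only_by_site = 0L,
              no_cysteine = 0L, all_channels_missing = 0L)

  keep <- !table$contaminant
  counts["contaminant"] <- sum(!keep)
  t1 <- table[keep, , drop = FALSE]

  keep <- !t1$reverse
  counts["reverse"] <- sum(!keep)
  t1 <- t1[keep, , drop = FALSE]

  keep <- !t1$only_by_site
  counts["only_by_site"] <- sum(!keep)
  t1 <- t1[keep, , drop = FALSE]

  keep <- grepl("C", t1$sequence, fixed = TRUE)
  counts["no_cysteine"] <- sum(!keep)
  t1 <- t1[keep, , drop = FALSE]

  intens <- as.matrix(t1[, chans, drop = FALSE])
  keep <- rowSums(!is.na(intens)) > 0L
  counts["all_channels_missing"] <- sum(!keep)
  t1 <- t1[keep, , drop = FALSE]

  stopifnot(sum(counts) == n0 - nrow(t1))
  attr(t1, "channels") <- attr(table, "channels") %||% chans
  attr(t1, "filter_report") <- tibble::tibble(
    rule = names(counts), removed = unname(counts))
  t1
}

#' Log2-transform reporter intensities
#'
#' Replaces every present intensity by its log2; missing stays missing.
#'
#' @param table A (filtered) peptide table.
#' @param design A [redox_design()] naming the channels.
#' @return The table with channel columns log2-transformed.
#' @export
log2_transform <- function(table, design) {
  for (ch in design$channels$channel) {
    x <- table[[ch]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      stopf("cysredox_data_error",
            "non-positive intensity in channel '%s', row %d", ch, bad[1])
    }
    table[[ch]] <- log2(x)
  }
  table
}

#' Median-of-medians channel normalization
#'
#' Channels are grouped by (condition, thiol state) — four groups in a
#' two-condition design. Within each group the target is the median, over
#' the group's channels, of each channel's median log2 intensity (computed
#' over present values). Each channel is then shifted additively so its
#' median equals its group's target. Missing cells are untouched. SH and Sox
#' channels are deliberately normalized to separate targets: forcing them to
#' a common level would systematically distort the oxidation ratio.
#'
#' The operation is idempotent.
#'
#' @param table A log2-transformed peptide table.
#' @param design A [redox_design()].
#' @return The normalized table, with attribute `normalization`: a tibble of
#'   per-channel medians, group targets and applied shifts.
#' @export
normalize_median_of_medians <- function(table, design) {
  cm <- design$channels
  med <- vapply(cm$channel, function(ch) {
    x <- table[[ch]]
    if (all(is.na(x))) {
      stopf("cysredox_data_error",
            "channel '%s' has no present values; cannot normalize", ch)
    }
    median(x, na.rm = TRUE)
  }, numeric(1))
  audit <- dplyr::mutate(cm, median_before = unname(med[cm$channel]))
  audit <- dplyr::group_by(audit, .data$condition, .data$thiol)
  audit <- dplyr::mutate(audit, target = median(.data$median_before))
  audit <- dplyr::ungroup(audit)
  audit <- dplyr::mutate(audit, shift = .data$target - .data$median_before)

  for (i in seq_len(nrow(audit))) {
    ch <- audit$channel[i]
    table[[ch]] <- table[[ch]] + audit$shift[i]
  }
  attr(table, "normalization") <- audit
  attr(table, "filter_report") <- attr(table, "filter_report")
  table
}

#' Compute percent oxidation per peptide, condition and replicate
#'
#' Back-transforms the normalized log2 intensities to the linear scale and
#' applies the oxidation formula per replicate pair: a missing SH intensity
#' is replaced by 0 (the peptide pool is fully oxidized as far as it is
#' measurable), a missing Sox intensity makes the oxidation level `NA`
#' (without the oxidized channel the ratio is undefined), and otherwise
#'
#'   `ox = 100 * Sox / (SH + Sox)`.
#'
#' @param table A normalized log2 peptide table (post [filter_records()]).
#' @param design A [redox_design()].
#' @return An `ox_profile`: a long tibble with one row per (peptide,
#'   condition, replicate) and columns `sequence`, `leading_protein`,
#'   `condition`, `replicate`, `sh_log2`, `sox_log2` (normalized log2
#'   intensities, NA when missing) and `ox` (percent, NA when Sox missing).
#'   The design is attached as attribute `design`.
#' @export
compute_oxidation <- function(table, design) {
  cm <- design$channels
  pairs <- tidyr::pivot_wider(cm, names_from = "thiol",
                              values_from = "channel")
  rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    sh <- table[[pairs$SH[i]]]
    sox <- table[[pairs$Sox[i]]]
    sh_lin <- ifelse(is.na(sh), 0, 2^sh)
    sox_lin <- 2^sox                     # NA propagates
    # ratio first: it is bounded by 1, so ox can never exceed 100 even in
    # floating point
    ox <- 100 * (sox_lin / (sh_lin + sox_lin))
    tibble::tibble(
      sequence = table$sequence,
      leading_protein = table$leading_protein,
      condition = pairs$condition[i],
      replicate = pairs$replicate[i],
      sh_log2 = sh,
      sox_log2 = sox,
      ox = ox
    )
  })
  rows <- dplyr::arrange(rows, .data$sequence, .data$leading_protein,
                         factor(.data$condition, levels = design$conditions),
                         .data$replicate)

  # rows whose oxidation is NA in every replicate of both conditions carry
  # no quantitative oxidation signal (Sox never observed); they are dropped
  # from the profile and reported via attribute
  valid <- dplyr::summarise(
    dplyr::group_by(rows, .data$sequence, .data$leading_protein),
    any_valid = any(!is.na(.data$ox)), .groups = "drop")
  dropped <- valid[!valid$any_valid, c("sequence", "leading_protein")]
  if (nrow(dropped)) {
    rows <- dplyr::anti_join(rows, dropped,
                             by = c("sequence", "leading_protein"))
  }
  structure(rows, class = c("ox_profile", class(rows)),
            design = design, dropped = dropped)
}

#' Summarise an oxidation profile per peptide and condition
#'
#' @param profile An `ox_profile` from [compute_oxidation()].
#' @return A tibble with one row per (peptide, condition): `n_valid`,
#'   `mean_ox`, `median_ox`, `n_sox_valid` (same as `n_valid`: a valid
#'   oxidation value requires the Sox channel).
#' @export
profile_summary <- function(profile) {
  dplyr::summarise(
    dplyr::group_by(profile, .data$sequence, .data$leading_protein,
                    .data$condition),
    n_valid = sum(!is.na(.data$ox)),
    mean_ox = if (any(!is.na(.data$ox))) mean(.data$ox, na.rm = TRUE) else NA_real_,
    median_ox = if (any(!is.na(.data$ox))) median(.data$ox, na.rm = TRUE) else NA_real_,
    .groups = "drop"
  )
}
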