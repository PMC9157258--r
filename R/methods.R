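#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-oxidation result
#'
#' @param x A `redox_diff` tibble from [diff_oxidation()].
#' @param ... Unused.
#' @return A plain tibble with the per-peptide statistics, classes and
#'   calls, plus `neg_log10_q` for volcano plots.
#' @method tidy redox_diff
#' @export
tidy.redox_diff <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$neg_log10_q <- ifelse(is.na(out$q_value), NA_real_,
                            -log10(pmax(out$q_value, .Machine$double.xmin)))
  out
}

#' One-line summary of a differential-oxidation result
#'
#' @param x A `redox_diff` tibble.
#' @param ... Unused.
#' @return A one-row tibble: peptide counts, tested/significant counts,
#'   direction split, only-in counts and the alpha used.
#' @method glance redox_diff
#' @export
glance.redox_diff <- function(x, ...) {
  design <- attr(x, "design")
  conds <- design$conditions
  tibble::tibble(
    n_peptides = nrow(x),
    n_tested = sum(!is.na(x$q_value)),
    n_significant = sum(x$significant),
    n_up_in_A = sum(x$direction == "up_in_A"),
    n_up_in_B = sum(x$direction == "up_in_B"),
    n_only_in_A = sum(x$only_in == conds[1]),
    n_only_in_B = sum(x$only_in == conds[2]),
    alpha = design$params$alpha
  )
}

#' @export
print.redox_diff <- function(x, ...) {
  design <- attr(x, "design")
  cat(sprintf("<redox_diff> %d peptides, %s vs %s\n", nrow(x),
              design$conditions[1], design$conditions[2]))
  g <- glance(x)
  cat(sprintf("  tested: %d, significant (q < %g): %d (%d up in %s, %d up in %s)\n",
              g$n_tested, g$alpha, g$n_significant, g$n_up_in_A,
              design$conditions[1], g$n_up_in_B, design$conditions[2]))
  cat(sprintf("  only in %s: %d, only in %s: %d\n", design$conditions[1],
              g$n_only_in_A, design$conditions[2], g$n_only_in_B))
  NextMethod()
}
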