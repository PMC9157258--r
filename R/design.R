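#' Describe a two-condition iodoTMT experiment
#'
#' A design maps every reporter channel of the peptide table to a
#' (condition, replicate, thiol state) triple and carries the analysis
#' parameters. The thiol state distinguishes the first iodoTMT label, which
#' blocks free thiols (`SH`), from the second label applied after reduction,
#' which marks reversibly oxidized thiols (`Sox`).
#'
#' By default channels follow the MaxQuant naming convention
#' `"Reporter intensity corrected <i> <condition>"` with channels 1..r
#' holding SH and r+1..2r holding Sox for the r replicates of each condition.
#'
#' @param conditions Character vector of length 2; the first condition is the
#'   reference for the direction of reported changes (`delta_ox = A - B`,
#'   `log2_ratio = log2(A/B)`).
#' @param replicates Number of biological replicates per condition.
#' @param channel_map Optional tibble with columns `condition`, `replicate`,
#'   `thiol` (`"SH"` or `"Sox"`) and `channel` (the reporter column name).
#'   When `NULL`, the MaxQuant-style default described above is built.
#' @param alpha Significance threshold on the permutation-based q-value
#'   (strict inequality, `q < alpha`).
#' @param min_valid Minimum number of valid (non-missing) oxidation values
#'   required in each condition for a peptide to be tested.
#' @param only_in_required Number of valid Sox values required in one
#'   condition (with zero in the other) to call a peptide oxidized only in
#'   that condition. Defaults to `replicates`, i.e. the 3:0 rule in a
#'   three-replicate design.
#' @param class_bounds Two percentages delimiting the low/mid/high oxidation
#'   classes; values below the first bound are `low`, values above the second
#'   are `high`, the closed interval in between is `mid`.
#' @param n_permutations Number of label permutations for the FDR estimate.
#'   `NULL` (default) uses exhaustive enumeration whenever the design admits
#'   at most 1000 distinct assignments (a 3 vs 3 design has 20), otherwise
#'   250 sampled permutations.
#' @param s0 SAM-style fudge factor added to the per-peptide standard error
#'   when ranking peptides for the permutation FDR; 0 gives the plain
#'   t-statistic.
#' @param delta_eps Numerical guard for zero-variance peptides: a mean
#'   oxidation difference at or below this many percentage points counts as
#'   no difference instead of an infinite statistic.
#' @param seed Integer seed used when permutations must be sampled.
#'
#' @return An object of class `redox_design`: a list with elements
#'   `conditions`, `replicates`, `channels` (the channel-map tibble) and
#'   `params`.
#' @export
#' @examples
#' d <- redox_design(c("FL", "ABM"), replicates = 3)
#' d$channels
redox_design <- function(conditions = c("A", "B"),
                         replicates = 3,
                         channel_map = NULL,
                         alpha = 0.05,
                         min_valid = 2,
                         only_in_required = replicates,
                         class_bounds = c(20, 80),
                         n_permutations = NULL,
                         s0 = 0,
                         delta_eps = 1e-9,
                         seed = 1L) {
  if (length(conditions) != 2L || anyDuplicated(conditions)) {
    stopf("cysredox_config_error",
          "a design needs exactly two distinct conditions")
  }
  if (replicates < 1) {
    stopf("cysredox_config_error", "replicates must be >= 1")
  }
  if (only_in_required > replicates) {
    stopf("cysredox_config_error",
          "only_in_required (%d) cannot exceed replicates (%d)",
          only_in_required, replicates)
  }
  if (length(class_bounds) != 2L || class_bounds[1] >= class_bounds[2] ||
      class_bounds[1] < 0 || class_bounds[2] > 100) {
    stopf("cysredox_config_error",
          "class_bounds must be two increasing percentages within [0, 100]")
  }
  if (alpha <= 0 || alpha >= 1) {
    stopf("cysredox_config_error", "alpha must lie in (0, 1)")
  }

  if (is.null(channel_map)) {
    channel_map <- default_channel_map(conditions, replicates)
  }
  channel_map <- tibble::as_tibble(channel_map)
  needed <- c("condition", "replicate", "thiol", "channel")
  if (!all(needed %in% names(channel_map))) {
    stopf("cysredox_config_error",
          "channel_map must have columns %s", paste(needed, collapse = ", "))
  }
  if (!all(channel_map$thiol %in% c("SH", "Sox"))) {
    stopf("cysredox_config_error", "thiol states must be 'SH' or 'Sox'")
  }
  if (anyDuplicated(channel_map$channel)) {
    stopf("cysredox_config_error", "channel labels must be unique")
  }
  combos <- dplyr::count(channel_map, .data$condition, .data$replicate,
                         .data$thiol)
  expected <- 2L * length(conditions) * replicates
  if (nrow(combos) != expected || any(combos$n != 1L)) {
    stopf("cysredox_config_error",
          "every (condition, replicate) needs exactly one SH and one Sox channel")
  }

  structure(
    list(
      conditions = as.character(conditions),
      replicates = as.integer(replicates),
      channels = channel_map,
      params = list(
        alpha = alpha,
        min_valid = as.integer(min_valid),
        only_in_required = as.integer(only_in_required),
        class_bounds = as.numeric(class_bounds),
        n_permutations = n_permutations,
        s0 = s0,
        delta_eps = delta_eps,
        seed = as.integer(seed)
      )
    ),
    class = "redox_design"
  )
}

default_channel_map <- function(conditions, replicates) {
  purrr::map_dfr(conditions, function(cond) {
    tibble::tibble(
      condition = cond,
      replicate = rep(seq_len(replicates), 2L),
      thiol = rep(c("SH", "Sox"), each = replicates),
      channel = sprintf("Reporter intensity corrected %d %s",
                        seq_len(2L * replicates), cond)
    )
  })
}

#' @export
print.redox_design <- function(x, ...) {
  cat(sprintf("<redox_design> %s vs %s, %d replicates\n",
              x$conditions[1], x$conditions[2], x$replicates))
  cat(sprintf("  alpha=%g, min_valid=%d, only-in rule %d:0, classes <%g / >%g\n",
              x$params$alpha, x$params$min_valid, x$params$only_in_required,
              x$params$class_bounds[1], x$params$class_bounds[2]))
  invisible(x)
}

#' Write / read an experiment design as YAML
#'
#' @param design A [redox_design()] object.
#' @param path File path.
#' @return `read_design` returns a `redox_design`; `write_design` returns
#'   `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "redox_design"))
  obj <- list(
    conditions = design$conditions,
    replicates = design$replicates,
    channels = lapply(seq_len(nrow(design$channels)), function(i) {
      as.list(design$channels[i, ])
    }),
    params = design$params
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- yaml::read_yaml(path)
  cm <- purrr::map_dfr(obj$channels, tibble::as_tibble)
  p <- obj$params
  redox_design(
    conditions = obj$conditions,
    replicates = obj$replicates,
    channel_map = cm,
    alpha = p$alpha,
    min_valid = p$min_valid,
    only_in_required = p$only_in_required,
    class_bounds = unlist(p$class_bounds),
    n_permutations = p$n_permutations,
    s0 = p$s0,
    delta_eps = p$delta_eps %||% 1e-9,
    seed = p$seed
  )
}

# Channels of one thiol state, ordered by condition then replicate.
channels_for <- function(design, condition, thiol) {
  ch <- dplyr::filter(design$channels, .data$condition == !!condition,
                      .data$thiol == !!thiol)
  ch <- dplyr::arrange(ch, .data$replicate)
  ch$channel
}
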