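#' Two-sample pooled-variance t-test on oxidation values
#'
#' Two-sided Student's t-test with pooled variance; the p-value comes from
#' the t distribution with `n_A + n_B - 2` degrees of freedom. With zero
#' pooled variance, equal means give `t = 0, p = 1`; unequal means give an
#' infinite statistic and `p = 0`.
#'
#' @param values_a,values_b Numeric vectors of percent oxidation (NA allowed;
#'   dropped). At least two valid values per group are required.
#' @param delta_eps Numerical guard: with zero pooled variance, a mean
#'   difference at or below this tolerance (in percentage points) is treated
#'   as zero rather than as an infinite statistic. Differences of this size
#'   arise from floating-point rounding, not biology.
#' @return A named list with `t_stat`, `p_value` and `df`.
#' @export
#' @examples
#' two_sample_t(c(10, 12, 11), c(20, 22, 21))
two_sample_t <- function(values_a, values_b, delta_eps = 1e-9) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    stopf("cysredox_input_error",
          "two_sample_t needs at least 2 valid values per group")
  }
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  delta <- mean(a) - mean(b)
  if (se == 0) {
    if (abs(delta) <= delta_eps) {
      return(list(t_stat = 0, p_value = 1, df = df))
    }
    return(list(t_stat = sign(delta) * Inf, p_value = 0, df = df))
  }
  t_stat <- delta / se
  list(t_stat = t_stat, p_value = 2 * pt(-abs(t_stat), df), df = df)
}

# Vectorised per-row moderated statistics on an oxidation matrix.
# mat: rows = peptides, columns = replicate measurements.
# Returns d (SAM statistic with fudge factor s0), t (plain t), p, and the
# per-group valid counts. Rows with < min_valid per group get NA.
.row_stats <- function(mat, idx_a, idx_b, min_valid, s0 = 0,
                       delta_eps = 1e-9) {
  ma <- mat[, idx_a, drop = FALSE]
  mb <- mat[, idx_b, drop = FALSE]
  na <- rowSums(!is.na(ma))
  nb <- rowSums(!is.na(mb))
  mean_a <- rowMeans(ma, na.rm = TRUE)
  mean_b <- rowMeans(mb, na.rm = TRUE)
  ssa <- rowSums((ma - mean_a)^2, na.rm = TRUE)
  ssb <- rowSums((mb - mean_b)^2, na.rm = TRUE)
  df <- na + nb - 2
  sp2 <- ifelse(df > 0, (ssa + ssb) / df, NA_real_)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  delta <- mean_a - mean_b

  testable <- na >= min_valid & nb >= min_valid
  d <- t_plain <- p <- rep(NA_real_, nrow(mat))

  denom <- se + s0
  zero_se <- testable & se == 0
  pos <- testable & se > 0
  d[pos] <- delta[pos] / denom[pos]
  t_plain[pos] <- delta[pos] / se[pos]
  p[pos] <- 2 * pt(-abs(t_plain[pos]), df[pos])
  # degenerate rows: zero pooled variance. A |delta| at or below delta_eps
  # is floating-point rounding, not signal; without the guard, replicate
  # values that differ by one ulp would yield infinite null statistics.
  null_delta <- abs(delta) <= delta_eps
  d[zero_se & null_delta] <- 0
  t_plain[zero_se & null_delta] <- 0
  p[zero_se & null_delta] <- 1
  inf_rows <- zero_se & !null_delta
  d[inf_rows] <- sign(delta[inf_rows]) * Inf
  t_plain[inf_rows] <- sign(delta[inf_rows]) * Inf
  p[inf_rows] <- 0

  list(d = d, t = t_plain, p = p, delta = delta,
       mean_a = mean_a, mean_b = mean_b, n_a = na, n_b = nb,
       testable = testable)
}

# All (or sampled) assignments of the 2r replicate columns to group A.
# Assignments that reproduce the observed grouping (the identity and, for
# balanced designs, its mirror) are excluded from the null ensemble: they
# regenerate the observed statistics, not null ones, and with a small
# exhaustive set (20 assignments at 3 vs 3) their inclusion would floor
# every q-value at 0.1.
.permutation_sets <- function(n_cols, n_a, n_permutations, seed) {
  observed <- seq_len(n_a)
  mirror <- if (n_cols - n_a == n_a) (n_a + 1L):n_cols else integer(0)
  degenerate <- function(s) {
    identical(s, observed) || identical(s, mirror)
  }
  total <- choose(n_cols, n_a)
  exhaustive <- is.null(n_permutations) && total <= 1000 ||
    (!is.null(n_permutations) && n_permutations >= total)
  if (exhaustive) {
    sets <- combn(n_cols, n_a, simplify = FALSE)
    sets <- sets[!vapply(sets, degenerate, logical(1))]
  } else {
    n_perm <- n_permutations %||% 250L
    sets <- with_seed(seed, {
      out <- vector("list", n_perm)
      i <- 1L
      while (i <= n_perm) {
        s <- sort(sample(n_cols, n_a))
        if (!degenerate(s)) {
          out[[i]] <- s
          i <- i + 1L
        }
      }
      out
    })
  }
  sets
}

#' Permutation-based FDR for differential oxidation
#'
#' SAM-style procedure: the ranking statistic is
#' `d = (mean_A - mean_B) / (s + s0)` with `s` the pooled-t standard error.
#' Replicate labels are shuffled across the two conditions (the same
#' permutation applied to all peptides); for each peptide the q-value is the
#' mean, over permutations, of the number of null `|d|` values at or above
#' its observed `|d|`, divided by the number of observed `|d|` values at or
#' above it, clipped to `[0, 1]` and monotonized so q never decreases as
#' `|d|` decreases. For a 3 vs 3 design all 20 distinct label assignments
#' are enumerated, making the estimate exact.
#'
#' @param profile An `ox_profile` from [compute_oxidation()].
#' @param design A [redox_design()]; defaults to the profile's design.
#' @return A tibble with one row per peptide: `sequence`, `leading_protein`,
#'   `delta_ox`, `t_stat`, `p_value`, `d_stat`, `q_value`, `n_valid_A`,
#'   `n_valid_B`. Untestable rows (fewer than `min_valid` valid values in a
#'   group) carry NA statistics.
#' @export
permutation_fdr <- function(profile, design = attr(profile, "design")) {
  wide <- ox_matrix(profile, design)
  mat <- wide$mat
  min_valid <- design$params$min_valid
  s0 <- design$params$s0

  delta_eps <- design$params$delta_eps %||% 1e-9
  obs <- .row_stats(mat, wide$idx_a, wide$idx_b, min_valid, s0, delta_eps)
  sets <- .permutation_sets(ncol(mat), length(wide$idx_a),
                            design$params$n_permutations,
                            design$params$seed)

  abs_obs <- abs(obs$d)
  testable_abs <- abs_obs[!is.na(abs_obs)]
  ord <- sort(testable_abs)             # ascending
  n_obs_ge <- function(x) length(ord) - findInterval(x, ord, left.open = TRUE)

  null_ge_total <- numeric(length(abs_obs))
  for (set in sets) {
    idx_a <- set
    idx_b <- setdiff(seq_len(ncol(mat)), set)
    perm <- .row_stats(mat, idx_a, idx_b, min_valid, s0, delta_eps)
    nd <- abs(perm$d)
    nd <- sort(nd[!is.na(nd)])
    if (length(nd)) {
      cnt <- length(nd) - findInterval(abs_obs, nd, left.open = TRUE)
      cnt[is.na(abs_obs)] <- 0
      null_ge_total <- null_ge_total + cnt
    }
  }
  mean_null <- null_ge_total / length(sets)
  obs_cnt <- vapply(abs_obs, function(x) {
    if (is.na(x)) NA_integer_ else n_obs_ge(x)
  }, integer(1))
  q <- pmin(pmax(mean_null / obs_cnt, 0), 1)

  # q-value convention: each peptide may use any threshold at or below its
  # own |d|, so q is the running minimum of the FDR estimate over
  # increasingly extreme thresholds; q is then non-increasing in |d|
  idx <- order(abs_obs, decreasing = FALSE, na.last = TRUE)
  qs <- q[idx]
  ok <- !is.na(qs)
  qs[ok] <- cummin(qs[ok])
  q[idx] <- qs

  tibble::tibble(
    sequence = wide$keys$sequence,
    leading_protein = wide$keys$leading_protein,
    delta_ox = ifelse(obs$testable, obs$delta, NA_real_),
    mean_ox_A = ifelse(obs$n_a > 0, obs$mean_a, NA_real_),
    mean_ox_B = ifelse(obs$n_b > 0, obs$mean_b, NA_real_),
    t_stat = obs$t,
    p_value = obs$p,
    d_stat = obs$d,
    q_value = q,
    n_valid_A = obs$n_a,
    n_valid_B = obs$n_b
  )
}

# Pivot a long profile into a peptides x (condition:replicate) matrix.
ox_matrix <- function(profile, design) {
  conds <- design$conditions
  wide <- tidyr::pivot_wider(
    dplyr::mutate(profile, col = paste(.data$condition, .data$replicate,
                                       sep = "_")),
    id_cols = c("sequence", "leading_protein"),
    names_from = "col", values_from = "ox")
  col_a <- paste(conds[1], seq_len(design$replicates), sep = "_")
  col_b <- paste(conds[2], seq_len(design$replicates), sep = "_")
  for (cc in setdiff(c(col_a, col_b), names(wide))) wide[[cc]] <- NA_real_
  mat <- as.matrix(wide[, c(col_a, col_b)])
  list(mat = mat,
       keys = wide[, c("sequence", "leading_protein")],
       idx_a = seq_along(col_a),
       idx_b = length(col_a) + seq_along(col_b))
}

#' Assign oxidation classes
#'
#' Bins percent-oxidation values into three classes: `low` below the first
#' bound, `high` above the second, `mid` on the closed interval in between
#' (the bounds themselves are `mid`). Defaults are 20 and 80, matching the
#' <20 % / 20-80 % / >80 % classification of quantified peptides.
#'
#' @param ox Numeric vector of percent oxidation in `[0, 100]` (NA allowed).
#' @param bounds Two class bounds.
#' @return A factor with levels `low`, `mid`, `high` (NA stays NA).
#' @export
#' @examples
#' assign_oxidation_class(c(9.33, 50, 83.98, 20, 80))
assign_oxidation_class <- function(ox, bounds = c(20, 80)) {
  bad <- which(!is.na(ox) & (ox < 0 | ox > 100))
  if (length(bad)) {
    stopf("cysredox_data_error",
          "oxidation value outside [0, 100] at position %d: %g",
          bad[1], ox[bad[1]])
  }
  out <- ifelse(is.na(ox), NA_character_,
                ifelse(ox < bounds[1], "low",
                       ifelse(ox > bounds[2], "high", "mid")))
  factor(out, levels = c("low", "mid", "high"))
}

#' Call significantly differentially oxidized peptides
#'
#' A peptide is differential when its permutation q-value is strictly below
#' `alpha`; direction follows the sign of `delta_ox` (condition A minus
#' condition B).
#'
#' @param results Tibble with `q_value` and `delta_ox` columns.
#' @param alpha Significance threshold (default 0.05).
#' @return `results` with added `significant` (logical) and `direction`
#'   (`up_in_A` / `up_in_B` / `none`).
#' @export
call_significant <- function(results, alpha = 0.05) {
  dplyr::mutate(
    results,
    significant = !is.na(.data$q_value) & .data$q_value < alpha,
    direction = dplyr::case_when(
      .data$significant & .data$delta_ox > 0 ~ "up_in_A",
      .data$significant & .data$delta_ox < 0 ~ "up_in_B",
      TRUE ~ "none"
    )
  )
}

#' Call peptides oxidized in one condition only
#'
#' A peptide is oxidized only in condition A when it has `required` valid
#' Sox measurements (equivalently, valid oxidation values) in A and none in
#' B — the 3:0 rule in a three-replicate design — and symmetrically for B.
#'
#' @param profile An `ox_profile`.
#' @param design A [redox_design()].
#' @param required Number of valid values required in the oxidized
#'   condition; defaults to the design's `only_in_required`.
#' @return A tibble `sequence`, `leading_protein`, `only_in` (`"A"`, `"B"`
#'   or `"none"`, using the design's condition names).
#' @export
call_only_in_condition <- function(profile,
                                   design = attr(profile, "design"),
                                   required = design$params$only_in_required) {
  if (required > design$replicates) {
    stopf("cysredox_config_error",
          "required (%d) exceeds replicates (%d)", required,
          design$replicates)
  }
  conds <- design$conditions
  s <- profile_summary(profile)
  wide <- tidyr::pivot_wider(s[, c("sequence", "leading_protein",
                                   "condition", "n_valid")],
                             names_from = "condition",
                             values_from = "n_valid", values_fill = 0L)
  na <- wide[[conds[1]]]
  nb <- wide[[conds[2]]]
  wide$only_in <- dplyr::case_when(
    na == required & nb == 0L ~ conds[1],
    nb == required & na == 0L ~ conds[2],
    TRUE ~ "none"
  )
  wide[, c("sequence", "leading_protein", "only_in")]
}

#' Full differential-oxidation analysis of an oxidation profile
#'
#' Runs the pooled-variance t-test and permutation FDR, calls significance
#' (q < alpha) and direction, applies the only-in-one-condition rule, and
#' bins per-condition mean oxidation into classes.
#'
#' @param profile An `ox_profile` from [compute_oxidation()].
#' @param design A [redox_design()]; defaults to the profile's design.
#' @return A `redox_diff` tibble with one row per peptide: the test columns
#'   of [permutation_fdr()] plus `log2_ratio`, `significant`, `direction`,
#'   `only_in`, `ox_class_A`, `ox_class_B` and per-condition medians.
#' @export
diff_oxidation <- function(profile, design = attr(profile, "design")) {
  res <- permutation_fdr(profile, design)
  res <- call_significant(res, design$params$alpha)
  only <- call_only_in_condition(profile, design)
  res <- dplyr::left_join(res, only, by = c("sequence", "leading_protein"))

  s <- profile_summary(profile)
  med <- tidyr::pivot_wider(
    s[, c("sequence", "leading_protein", "condition", "median_ox")],
    names_from = "condition", values_from = "median_ox",
    names_prefix = "median_ox_")
  names(med) <- sub(paste0("^median_ox_", design$conditions[1], "$"),
                    "median_ox_A", names(med))
  names(med) <- sub(paste0("^median_ox_", design$conditions[2], "$"),
                    "median_ox_B", names(med))
  res <- dplyr::left_join(res, med, by = c("sequence", "leading_protein"))

  bounds <- design$params$class_bounds
  res$log2_ratio <- ifelse(
    !is.na(res$mean_ox_A) & !is.na(res$mean_ox_B) &
      res$mean_ox_A > 0 & res$mean_ox_B > 0,
    log2(res$mean_ox_A / res$mean_ox_B), NA_real_)
  res$ox_class_A <- assign_oxidation_class(res$mean_ox_A, bounds)
  res$ox_class_B <- assign_oxidation_class(res$mean_ox_B, bounds)

  structure(res, class = c("redox_diff", class(res)), design = design)
}

#' Condition-level oxidation summaries
#'
#' Mean and median percent oxidation per condition over all valid
#' (peptide, replicate) cells, optionally restricted to a peptide subset
#' (e.g. the significantly differential peptides). Per-peptide condition
#' averages are returned alongside.
#'
#' @param profile An `ox_profile`.
#' @param design A [redox_design()].
#' @param keys Optional tibble with `sequence` and `leading_protein` to
#'   restrict the summary.
#' @return A list with `conditions` (tibble: condition, n_valid, mean_ox,
#'   median_ox) and `peptides` (per-peptide per-condition summary).
#' @export
summarize_condition <- function(profile, design = attr(profile, "design"),
                                keys = NULL) {
  if (!is.null(keys)) {
    profile <- dplyr::semi_join(profile, keys,
                                by = c("sequence", "leading_protein"))
  }
  valid <- profile[!is.na(profile$ox), ]
  if (!nrow(valid)) {
    warn("no valid oxidation values in the requested subset")
    conds <- tibble::tibble(condition = design$conditions, n_valid = 0L,
                            mean_ox = NA_real_, median_ox = NA_real_)
  } else {
    conds <- dplyr::summarise(
      dplyr::group_by(valid, .data$condition),
      n_valid = dplyr::n(),
      mean_ox = mean(.data$ox),
      median_ox = median(.data$ox),
      .groups = "drop")
  }
  list(conditions = conds, peptides = profile_summary(profile))
}

#' Overlap of two differential-oxidation result sets
#'
#' Partitions the significant peptide keys of two experiments into
#' exclusive and shared sets, and reports direction concordance for shared
#' keys.
#'
#' @param results_1,results_2 `redox_diff` tibbles (or any tibble with
#'   `sequence`, `leading_protein`, `significant`, `direction`).
#' @param significant_only Use only significant rows (default) or all keys.
#' @return A list of class `redox_overlap` with `keys_1_only`,
#'   `keys_2_only`, `keys_shared` (tibbles), counts `n_1_only`, `n_2_only`,
#'   `n_shared`, and `concordance` (shared keys with both directions and a
#'   `concordant` flag).
#' @export
overlap_differential <- function(results_1, results_2,
                                 significant_only = TRUE) {
  pick <- function(res) {
    if (significant_only) res <- res[res$significant, , drop = FALSE]
    keys <- res[, c("sequence", "leading_protein", "direction")]
    if (anyDuplicated(peptide_key(keys$sequence, keys$leading_protein))) {
      stopf("cysredox_data_error",
            "duplicate peptide keys within one result set")
    }
    keys
  }
  k1 <- pick(results_1)
  k2 <- pick(results_2)
  by_key <- c("sequence", "leading_protein")
  shared <- dplyr::inner_join(k1, k2, by = by_key,
                              suffix = c("_1", "_2"))
  shared$concordant <- shared$direction_1 == shared$direction_2
  structure(
    list(
      keys_1_only = dplyr::anti_join(k1, k2, by = by_key)[by_key],
      keys_2_only = dplyr::anti_join(k2, k1, by = by_key)[by_key],
      keys_shared = shared[by_key],
      n_1_only = nrow(k1) - nrow(shared),
      n_2_only = nrow(k2) - nrow(shared),
      n_shared = nrow(shared),
      concordance = shared
    ),
    class = "redox_overlap"
  )
}

#' @export
print.redox_overlap <- function(x, ...) {
  cat(sprintf("<redox_overlap> %d shared, %d only in set 1, %d only in set 2\n",
              x$n_shared, x$n_1_only, x$n_2_only))
  if (x$n_shared) {
    cat(sprintf("  direction concordant for %d of %d shared peptides\n",
                sum(x$concordance$concordant), x$n_shared))
  }
  invisible(x)
}
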