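test_that("pooled t-test matches the closed form and its degenerate cases", {
  # identical groups: no evidence
  expect_equal(two_sample_t(c(10, 10, 10), c(10, 10, 10)),
               list(t_stat = 0, p_value = 1, df = 4))
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # hand-computed pooled-variance t for A=(10,12,11), B=(20,22,21):
  # means 11 and 21, each SS = 2, sp2 = 4/4 = 1, se = sqrt(2/3),
  # t = -10 / sqrt(2/3), p = 2*pt(t, 4)
  got <- two_sample_t(c(10, 12, 11), c(20, 22, 21))
  t_want <- -10 / sqrt(2 / 3)
  expect_equal(got$t_stat, t_want, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(t_want, 4), tolerance = 1e-12)

  # agreement with stats::t.test(var.equal = TRUE) on random data
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1), 10, 3)
    b <- rnorm(sample(2:6, 1), 12, 3)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    got <- two_sample_t(a, b)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }

  # zero pooled variance with unequal means: infinite statistic convention
  deg <- two_sample_t(c(5, 5), c(9, 9))
  expect_equal(deg$t_stat, -Inf)
  expect_equal(deg$p_value, 0)

  expect_error(two_sample_t(c(1), c(1, 2)), class = "cysredox_input_error")
})

make_profile <- function(mat, design) {
  # build an ox_profile directly from a matrix of oxidation percentages
  # (columns: A1..A3, B1..B3)
  n <- nrow(mat)
  rows <- tidyr::expand_grid(
    i = seq_len(n),
    condition = design$conditions,
    replicate = seq_len(design$replicates))
  rows$sequence <- sprintf("PEPC%dK", rows$i)
  rows$leading_protein <- sprintf("P%d", rows$i)
  col <- ifelse(rows$condition == design$conditions[1], 0L,
                design$replicates) + rows$replicate
  rows$ox <- mat[cbind(rows$i, col)]
  rows$sh_log2 <- NA_real_
  rows$sox_log2 <- ifelse(is.na(rows$ox), NA_real_, 1)
  rows$i <- NULL
  structure(rows, class = c("ox_profile", class(rows)), design = design)
}

test_that("exhaustive permutation q-values match the brute-force oracle", {
  d <- test_design()
  set.seed(21)
  for (trial in 1:12) {
    n <- sample(1:8, 1)
    mat <- matrix(round(runif(n * 6, 0, 100), 1), nrow = n)
    # sprinkle missing values on some trials
    if (trial > 6) mat[sample(length(mat), min(3, length(mat)))] <- NA
    prof <- make_profile(mat, d)
    got <- permutation_fdr(prof, d)
    got <- got[order(as.integer(sub("P", "", got$leading_protein))), ]
    want <- oracle_perm_q(mat, 3)
    expect_equal(got$q_value, want, tolerance = 1e-12,
                 info = sprintf("trial %d (n=%d)", trial, n))
  }
})

test_that("a single 3v3 row of identical values gets q = 1", {
  d <- test_design()
  prof <- make_profile(matrix(rep(50, 6), nrow = 1), d)
  res <- permutation_fdr(prof, d)
  expect_equal(res$q_value, 1)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
})

test_that("q is monotone non-increasing in |d|", {
  d <- test_design()
  set.seed(5)
  mat <- matrix(runif(40 * 6, 0, 100), nrow = 40)
  mat[1:5, 1:3] <- mat[1:5, 1:3] + 60     # strong injected rows
  res <- permutation_fdr(make_profile(mat, d), d)
  ord <- order(abs(res$d_stat), decreasing = TRUE)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
})

test_that("rows with too few valid values are excluded from testing", {
  d <- test_design()
  mat <- matrix(c(10, 20, 30, 40, 50, 60,
                  10, NA, NA, 40, 50, 60), nrow = 2, byrow = TRUE)
  res <- permutation_fdr(make_profile(mat, d), d)
  res <- res[order(res$leading_protein), ]
  expect_false(is.na(res$q_value[1]))
  expect_true(is.na(res$q_value[2]))
  expect_true(is.na(res$p_value[2]))
})

test_that("significance calls use strict q < alpha and delta direction", {
  res <- tibble::tibble(
    q_value = c(0.015, 0.058, 0.05, NA, 0.001),
    delta_ox = c(8.14, -48.06, 3, 2, -5))
  out <- call_significant(res, alpha = 0.05)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$direction,
               c("up_in_A", "none", "none", "none", "up_in_B"))
})

test_that("oxidation classes partition [0, 100] with closed mid bounds", {
  x <- c(0, 9.33, 19.999, 20, 50, 80, 80.001, 83.98, 100, NA)
  cls <- assign_oxidation_class(x)
  expect_equal(as.character(cls),
               c("low", "low", "low", "mid", "mid", "mid", "high", "high",
                 "high", NA))
  # every non-NA value gets exactly one class
  grid <- seq(0, 100, by = 0.25)
  expect_false(any(is.na(assign_oxidation_class(grid))))
  expect_error(assign_oxidation_class(101), class = "cysredox_data_error")
  expect_error(assign_oxidation_class(-1), class = "cysredox_data_error")
})

test_that("only-in-condition calls follow the 3:0 Sox validity rule", {
  d <- test_design()
  mat <- rbind(
    c(10, 12, 14, NA, NA, NA),   # FL 3 valid, ABM 0 -> only in FL
    c(10, 12, NA, NA, NA, NA),   # 2 valid -> none
    c(10, 12, 14, 5, NA, NA),    # ABM has a valid value -> none
    c(NA, NA, NA, 4, 5, 6))      # symmetric: only in ABM
  prof <- make_profile(mat, d)
  out <- call_only_in_condition(prof, d, required = 3)
  out <- out[order(as.integer(sub("P", "", out$leading_protein))), ]
  expect_equal(out$only_in, c("FL", "none", "none", "ABM"))
  expect_error(call_only_in_condition(prof, d, required = 4),
               class = "cysredox_config_error")
})

test_that("condition summaries cover means, medians and subsets", {
  d <- test_design()
  mat <- rbind(c(10, 20, 30, 1, 2, 3),
               c(40, 50, 60, NA, NA, NA))
  prof <- make_profile(mat, d)
  s <- summarize_condition(prof, d)
  fl <- s$conditions[s$conditions$condition == "FL", ]
  expect_equal(fl$median_ox, 35)
  expect_equal(fl$mean_ox, 35)
  abm <- s$conditions[s$conditions$condition == "ABM", ]
  expect_equal(abm$median_ox, 2)

  sub <- summarize_condition(prof, d,
                             keys = tibble::tibble(sequence = "PEPC1K",
                                                   leading_protein = "P1"))
  expect_equal(sub$conditions$median_ox[sub$conditions$condition == "FL"], 20)

  empty <- suppressWarnings(
    summarize_condition(prof[0, ], d))
  expect_true(all(is.na(empty$conditions$median_ox)))
})

test_that("overlap partitions keys and reports direction concordance", {
  r1 <- tibble::tibble(sequence = c("A", "B", "C"),
                       leading_protein = "P",
                       significant = TRUE,
                       direction = c("up_in_A", "up_in_A", "up_in_B"))
  r2 <- tibble::tibble(sequence = c("B", "C", "D"),
                       leading_protein = "P",
                       significant = TRUE,
                       direction = c("up_in_A", "up_in_A", "up_in_B"))
  ov <- overlap_differential(r1, r2)
  expect_equal(ov$n_shared, 2)
  expect_equal(ov$n_1_only, 1)
  expect_equal(ov$n_2_only, 1)
  expect_equal(sum(ov$concordance$concordant), 1)

  # disjoint sets share nothing
  ov2 <- overlap_differential(r1, dplyr::mutate(r2, sequence = paste0("X", sequence)))
  expect_equal(ov2$n_shared, 0)

  dup <- dplyr::bind_rows(r1, r1[1, ])
  expect_error(overlap_differential(dup, r2),
               class = "cysredox_data_error")
})

test_that("diff_oxidation assembles calls, classes and ratios coherently", {
  d <- test_design()
  set.seed(77)
  n <- 30
  mat <- matrix(pmin(pmax(rnorm(n * 6, 30, 5), 0), 100), nrow = n)
  mat[1:4, 1:3] <- pmin(mat[1:4, 1:3] + 55, 100)  # strong FL effects
  mat[5, ] <- c(85, 90, 88, NA, NA, NA)           # FL-only row
  prof <- make_profile(mat, d)
  res <- diff_oxidation(prof, d)
  expect_s3_class(res, "redox_diff")
  expect_true(all(res$significant == (!is.na(res$q_value) &
                                        res$q_value < 0.05)))
  sig <- res[res$significant, ]
  expect_true(all(sig$direction != "none"))
  only <- res[res$only_in == "FL", ]
  expect_equal(nrow(only), 1)
  expect_true(is.na(only$q_value))
  # log2 ratio agrees with the means where defined
  ok <- !is.na(res$log2_ratio)
  expect_equal(res$log2_ratio[ok],
               log2(res$mean_ox_A[ok] / res$mean_ox_B[ok]))
  # classes agree with the bounds
  expect_equal(as.character(res$ox_class_A),
               as.character(assign_oxidation_class(res$mean_ox_A)))

  g <- glance(res)
  expect_equal(g$n_significant, sum(res$significant))
  td <- tidy(res)
  expect_true("neg_log10_q" %in% names(td))
})
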