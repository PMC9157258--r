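design <- test_design()
chans <- design$channels$channel

test_that("filtering applies each removal rule and counts it", {
  d <- design
  vals <- setNames(rep(list(rep(100, 6)), 12), chans)
  tbl <- make_table(
    sequences = c("ACK", "CCK", "AAK", "CGK", "CLK", "CMK"),
    proteins = c("P1", "P2", "P3", "P4", "P5", "P6"),
    values = vals, design = d)
  tbl$contaminant[2] <- TRUE
  tbl$reverse[5] <- TRUE
  # row 3 has no Cys; row 6 loses every intensity
  for (ch in chans) tbl[[ch]][6] <- NA_real_

  out <- filter_records(tbl, d)
  rep_tbl <- attr(out, "filter_report")
  expect_equal(nrow(out), 2)
  expect_equal(sum(rep_tbl$removed), nrow(tbl) - nrow(out))
  expect_equal(rep_tbl$removed[rep_tbl$rule == "contaminant"], 1L)
  expect_equal(rep_tbl$removed[rep_tbl$rule == "reverse"], 1L)
  expect_equal(rep_tbl$removed[rep_tbl$rule == "no_cysteine"], 1L)
  expect_equal(rep_tbl$removed[rep_tbl$rule == "all_channels_missing"], 1L)

  # idempotent
  out2 <- filter_records(out, d)
  expect_equal(nrow(out2), nrow(out))
  expect_equal(sum(attr(out2, "filter_report")$removed), 0L)
})

test_that("spec toy table: 6 rows with one violation each leave 2 clean rows", {
  d <- design
  vals <- setNames(rep(list(rep(64, 6)), 12), chans)
  tbl <- make_table(
    sequences = c("ACK", "CCK", "AAK", "CGK", "CLK", "CMK"),
    proteins = paste0("P", 1:6), values = vals, design = d)
  tbl$contaminant[1] <- TRUE
  tbl$reverse[2] <- TRUE
  # row 3 is the no-Cys row ("AAK"); row 4 all-missing
  for (ch in chans) tbl[[ch]][4] <- NA_real_
  out <- filter_records(tbl, d)
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$sequence), c("CLK", "CMK"))
})

test_that("log2 transform maps values and preserves missingness", {
  d <- design
  vals <- setNames(rep(list(c(8, NA, 1)), 12), chans)
  tbl <- make_table(c("ACK", "CCK", "CGK"), paste0("P", 1:3), vals, d)
  out <- log2_transform(tbl, d)
  expect_equal(out[[chans[1]]], c(3, NA, 0))

  tbl[[chans[2]]][1] <- -4
  expect_error(log2_transform(tbl, d), class = "cysredox_data_error")
})

test_that("normalization brings every channel median onto its group target", {
  set.seed(31)
  d <- design
  n <- 50
  base <- rnorm(n, 15, 2)
  vals <- list()
  for (ch in chans) vals[[ch]] <- 2^(base + rnorm(1, 0, 1) + rnorm(n, 0, 0.1))
  tbl <- make_table(sprintf("C%sK", strrep("A", seq_len(n))),
                    sprintf("P%d", seq_len(n)), vals, d)
  lg <- log2_transform(tbl, d)
  norm <- normalize_median_of_medians(lg, d)
  audit <- attr(norm, "normalization")

  for (i in seq_len(nrow(audit))) {
    ch <- audit$channel[i]
    expect_lt(abs(median(norm[[ch]], na.rm = TRUE) - audit$target[i]), 1e-9)
  }
  # groups are (condition x thiol): 4 distinct targets allowed
  expect_equal(nrow(dplyr::distinct(audit[, c("condition", "thiol")])), 4)

  # idempotent: renormalizing changes nothing
  norm2 <- normalize_median_of_medians(norm, d)
  for (ch in chans) expect_equal(norm2[[ch]], norm[[ch]], tolerance = 1e-12)

  # an offset channel is pulled exactly onto the group target
  lg2 <- lg
  lg2[[chans[1]]] <- lg[[chans[1]]] + 3
  norm3 <- normalize_median_of_medians(lg2, d)
  a3 <- attr(norm3, "normalization")
  expect_lt(abs(median(norm3[[chans[1]]]) -
                  a3$target[a3$channel == chans[1]]), 1e-9)
})

test_that("channels with no data are rejected during normalization", {
  d <- design
  vals <- setNames(rep(list(c(4, 8)), 12), chans)
  vals[[chans[2]]] <- c(NA_real_, NA_real_)
  tbl <- make_table(c("ACK", "CCK"), c("P1", "P2"), vals, d)
  expect_error(normalize_median_of_medians(log2_transform(tbl, d), d),
               class = "cysredox_data_error")
})

test_that("oxidation formula handles the missingness rules", {
  d <- design
  sh_fl <- cysredox:::channels_for(d, "FL", "SH")
  sox_fl <- cysredox:::channels_for(d, "FL", "Sox")
  vals <- list()
  # replicate 1: SH=25, Sox=75 -> 75 %; replicate 2: SH missing, Sox=5 ->
  # 100 %; replicate 3: SH=10, Sox missing -> NA
  vals[[sh_fl[1]]] <- 25; vals[[sox_fl[1]]] <- 75
  vals[[sh_fl[2]]] <- NA_real_; vals[[sox_fl[2]]] <- 5
  vals[[sh_fl[3]]] <- 10; vals[[sox_fl[3]]] <- NA_real_
  # ABM gets complete data so the row survives
  for (ch in cysredox:::channels_for(d, "ABM", "SH")) vals[[ch]] <- 50
  for (ch in cysredox:::channels_for(d, "ABM", "Sox")) vals[[ch]] <- 50
  tbl <- make_table("ACK", "P1", vals, d)
  prof <- compute_oxidation(log2_transform(tbl, d), d)
  fl <- prof[prof$condition == "FL", ]
  expect_equal(fl$ox[fl$replicate == 1], 75)
  expect_equal(fl$ox[fl$replicate == 2], 100)
  expect_true(is.na(fl$ox[fl$replicate == 3]))
  expect_equal(prof$ox[prof$condition == "ABM"], rep(50, 3))
})

test_that("oxidation is scale-invariant within a replicate pair", {
  d <- design
  vals <- list()
  for (cond in c("FL", "ABM")) {
    sh <- cysredox:::channels_for(d, cond, "SH")
    sox <- cysredox:::channels_for(d, cond, "Sox")
    for (r in 1:3) {
      k <- if (cond == "FL" && r == 2) 1000 else 1  # common factor
      vals[[sh[r]]] <- 30 * k
      vals[[sox[r]]] <- 70 * k
    }
  }
  tbl <- make_table("ACK", "P1", vals, d)
  prof <- compute_oxidation(log2_transform(tbl, d), d)
  expect_equal(prof$ox, rep(70, 6), tolerance = 1e-12)
})

test_that("oxidation values stay within [0, 100] and respond monotonically", {
  d <- design
  sh_fl <- cysredox:::channels_for(d, "FL", "SH")
  sox_fl <- cysredox:::channels_for(d, "FL", "Sox")
  sox_grid <- c(1, 10, 100, 1000)
  vals <- list()
  vals[[sh_fl[1]]] <- rep(50, 4)
  vals[[sox_fl[1]]] <- sox_grid
  for (ch in cysredox:::channels_for(d, "ABM", "SH")) vals[[ch]] <- rep(50, 4)
  for (ch in cysredox:::channels_for(d, "ABM", "Sox")) vals[[ch]] <- rep(50, 4)
  tbl <- make_table(sprintf("AC%sK", c("A", "D", "E", "F")),
                    paste0("P", 1:4), vals, d)
  prof <- compute_oxidation(log2_transform(tbl, d), d)
  fl1 <- prof[prof$condition == "FL" & prof$replicate == 1, ]
  fl1 <- fl1[order(match(fl1$leading_protein, paste0("P", 1:4))), ]
  expect_true(all(diff(fl1$ox) > 0))          # increasing in Sox
  expect_true(all(fl1$ox >= 0 & fl1$ox <= 100))
})

test_that("SH-only rows (Sox never observed) are dropped with a record", {
  d <- design
  vals <- list()
  for (ch in c(cysredox:::channels_for(d, "FL", "SH"),
               cysredox:::channels_for(d, "ABM", "SH"))) {
    vals[[ch]] <- c(100, 100)
  }
  for (ch in c(cysredox:::channels_for(d, "FL", "Sox"),
               cysredox:::channels_for(d, "ABM", "Sox"))) {
    vals[[ch]] <- c(NA_real_, 40)
  }
  tbl <- make_table(c("ACK", "CCK"), c("P1", "P2"), vals, d)
  prof <- compute_oxidation(log2_transform(tbl, d), d)
  expect_equal(unique(prof$sequence), "CCK")
  expect_equal(attr(prof, "dropped")$sequence, "ACK")
})
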