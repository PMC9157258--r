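#' Configuration for the synthetic redox-proteomics generator
#'
#' The generator emulates the data structure the analysis assumes: a
#' two-condition experiment with paired SH/Sox reporter channels per
#' replicate, per-site true oxidation fractions with condition-specific
#' distributions (the bulk of condition-A sites around 9-16 % oxidation, the
#' bulk of condition-B sites below 9 %, plus a high-oxidation component
#' above 80 % that is heavier in condition B), multiplicative lognormal
#' reporter noise, intensity-dependent dropout, and decoy/contaminant rows
#' for exercising the filter stage.
#'
#' @param n_proteins Number of proteins to simulate.
#' @param length_range Two integers; protein lengths are drawn uniformly
#'   from this interval.
#' @param cys_rate Per-residue probability of a cysteine.
#' @param conditions Two condition names (condition A first).
#' @param n_replicates Replicates per condition.
#' @param noise_sigma Standard deviation (log2 scale) of the multiplicative
#'   lognormal noise applied independently to every reporter intensity.
#' @param missing_threshold Log2 intensity below which dropout becomes
#'   likely; 0 disables dropout entirely.
#' @param missing_steepness Steepness of the logistic dropout curve in
#'   log2-intensity units.
#' @param frac_differential Fraction of cysteine sites receiving an injected
#'   oxidation difference of `effect_size` between conditions.
#' @param effect_size Injected absolute difference in oxidation fraction
#'   (0.4 = 40 percentage points).
#' @param frac_up_in_A Among differential sites, the fraction oxidized higher
#'   in condition A (the remainder are higher in B).
#' @param frac_only_in_A Fraction of single-cysteine-peptide sites whose Sox
#'   signal exists only in condition A (true fraction 0 in B), emulating
#'   peptides oxidized in one condition only.
#' @param frac_decoy_rows Decoy/contaminant/only-by-site rows appended to the
#'   reporter table, as a fraction of genuine rows.
#' @param shared_baseline When `TRUE`, each non-differential site uses one
#'   baseline fraction for both conditions (a global null, useful for
#'   error-rate calibration); when `FALSE` (default) baselines are drawn from
#'   each condition's own distribution, emulating the global oxidation shift
#'   between conditions.
#' @param bulk_mode_A,bulk_mode_B Modes of the bulk (low-oxidation) beta
#'   component per condition, as fractions.
#' @param bulk_concentration Beta concentration parameter of the bulk
#'   components (larger = tighter).
#' @param frac_high_A,frac_high_B Weight of the high-oxidation component per
#'   condition.
#' @param high_mode Mode of the high-oxidation beta component.
#' @param peptide_length Two integers; peptides outside this length range are
#'   dropped from the simulated table (MS-observable range).
#' @param max_missed_cleavages Missed cleavages allowed when digesting the
#'   simulated proteome.
#' @param abundance_log2_mean,abundance_log2_sd Location and spread of the
#'   per-(peptide, condition) true total intensity, log2 scale.
#' @param channel_shift_sd Log2-scale spread of the per-replicate loading
#'   factor shared by the SH and Sox channels of one replicate (sample
#'   amount / labelling-yield differences); this is the systematic effect
#'   that median-of-medians normalization removes.
#' @param seed Integer seed; the seed fully determines all outputs.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 300,
                       length_range = c(100, 300),
                       cys_rate = 0.03,
                       conditions = c("FL", "ABM"),
                       n_replicates = 3,
                       noise_sigma = 0.3,
                       missing_threshold = 12,
                       missing_steepness = 1,
                       frac_differential = 0.05,
                       effect_size = 0.4,
                       frac_up_in_A = 0.85,
                       frac_only_in_A = 0.01,
                       frac_decoy_rows = 0.05,
                       shared_baseline = FALSE,
                       bulk_mode_A = 0.12,
                       bulk_mode_B = 0.04,
                       bulk_concentration = 30,
                       frac_high_A = 0.05,
                       frac_high_B = 0.12,
                       high_mode = 0.9,
                       peptide_length = c(6, 40),
                       max_missed_cleavages = 0,
                       abundance_log2_mean = 20,
                       abundance_log2_sd = 2,
                       channel_shift_sd = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(cys_rate = cys_rate, frac_differential = frac_differential,
             frac_up_in_A = frac_up_in_A, frac_only_in_A = frac_only_in_A,
             frac_decoy_rows = frac_decoy_rows, frac_high_A = frac_high_A,
             frac_high_B = frac_high_B)
  bad <- rates[rates < 0 | rates > 1]
  if (length(bad)) {
    stopf("cysredox_config_error", "rates outside [0, 1]: %s",
          paste(names(bad), collapse = ", "))
  }
  if (n_proteins < 0) {
    stopf("cysredox_config_error", "n_proteins must be >= 0")
  }
  if (effect_size < 0 || effect_size > 1) {
    stopf("cysredox_config_error", "effect_size must lie in [0, 1]")
  }
  if (noise_sigma < 0) {
    stopf("cysredox_config_error", "noise_sigma must be >= 0")
  }
  if (length(conditions) != 2L) {
    stopf("cysredox_config_error", "exactly two conditions are required")
  }
  structure(cfg, class = "sim_config")
}

# Background residue frequencies for the 19 non-Cys residues (uniform).
.sample_protein <- function(len, cys_rate) {
  other <- setdiff(AA_ALPHABET_20, "C")
  is_cys <- runif(len) < cys_rate
  res <- character(len)
  res[is_cys] <- "C"
  res[!is_cys] <- sample(other, sum(!is_cys), replace = TRUE)
  paste(res, collapse = "")
}

#' Generate a synthetic proteome
#'
#' Draws `n_proteins` random amino-acid sequences. Cysteines appear with
#' per-residue probability `cys_rate`; the remaining residues are uniform
#' over the other 19 standard amino acids, which yields a combined K/R
#' frequency of roughly 10 % so tryptic digestion produces realistic peptide
#' lengths. Every sequence is guaranteed to contain at least one K or R.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `accession` and `sequence`.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_proteins
    lens <- if (n > 0) {
      sample(seq(config$length_range[1], config$length_range[2]), n,
             replace = TRUE)
    } else {
      integer(0)
    }
    seqs <- vapply(lens, function(len) {
      s <- .sample_protein(len, config$cys_rate)
      # guarantee a cleavage site so digestion yields > 1 peptide
      if (!grepl("[KR]", s)) {
        pos <- sample(len, 1L)
        substr(s, pos, pos) <- "K"
      }
      s
    }, character(1))
    tibble::tibble(
      accession = sprintf("SIMP%04d", seq_len(n)),
      sequence = seqs
    )
  })
}

# Digest a proteome into unique cysteine peptides with site coordinates.
# Returns one row per (accession, peptide) with the peptide's Cys positions
# in protein coordinates.
cys_peptides <- function(proteome, config) {
  empty <- tibble::tibble(peptide = character(), start = integer(),
                          missed_cleavages = integer(),
                          accession = character(), cys_sites = list())
  if (!nrow(proteome)) return(empty)
  out <- purrr::map_dfr(seq_len(nrow(proteome)), function(i) {
    acc <- proteome$accession[i]
    dig <- digest_trypsin_p(proteome$sequence[i],
                            max_missed_cleavages = config$max_missed_cleavages,
                            min_length = config$peptide_length[1],
                            max_length = config$peptide_length[2])
    dig <- dig[grepl("C", dig$peptide, fixed = TRUE), , drop = FALSE]
    if (!nrow(dig)) return(NULL)
    dig$accession <- acc
    dig$cys_sites <- purrr::map2(dig$peptide, dig$start, function(p, s) {
      offs <- which(strsplit(p, "")[[1]] == "C")
      s + offs - 1L
    })
    dig
  })
  if (!nrow(out)) empty else out
}

# Draw one baseline oxidation fraction from a condition's mixture.
.draw_baseline <- function(n, bulk_mode, frac_high, high_mode, conc) {
  shape <- function(mode) {
    a <- mode * (conc - 2) + 1
    b <- (1 - mode) * (conc - 2) + 1
    c(a, b)
  }
  bulk <- shape(bulk_mode)
  high <- shape(high_mode)
  use_high <- runif(n) < frac_high
  out <- numeric(n)
  out[!use_high] <- rbeta(sum(!use_high), bulk[1], bulk[2])
  out[use_high] <- rbeta(sum(use_high), high[1], high[2])
  out
}

#' Simulate ground-truth oxidation states
#'
#' Assigns every cysteine site of every peptide a true oxidation fraction per
#' condition and a differential label, and every (peptide, condition,
#' replicate) a true total reporter intensity.
#'
#' Baselines are beta-mixture draws: a bulk component whose mode is
#' `bulk_mode_A` (default 12 %, within the 9-16 % band characteristic of
#' fetal HSPC peptides) or `bulk_mode_B` (default 4 %, below 9 % as in adult
#' HSPCs), plus a high-oxidation component (mode 90 %) with more weight in
#' condition B. A fraction `frac_differential` of sites receives an exact
#' injected difference of `effect_size` between conditions; a fraction
#' `frac_only_in_A` of single-Cys-peptide sites is set to zero oxidation in
#' condition B, so their Sox signal never appears there.
#'
#' @param peptides Tibble from the internal digestion step (one row per
#'   cysteine peptide with `accession`, `peptide`, `start`, `cys_sites`).
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` with tibbles `sites` (accession,
#'   position, condition, fraction, label) and `abundance` (accession,
#'   peptide, condition, replicate, total_intensity), plus the peptide table.
#' @export
simulate_truth <- function(peptides, config) {
  stopifnot(inherits(config, "sim_config"))
  conds <- config$conditions
  if (!nrow(peptides)) {
    return(structure(
      list(sites = tibble::tibble(accession = character(),
                                  position = integer(),
                                  condition = character(),
                                  fraction = numeric(),
                                  label = character()),
           abundance = tibble::tibble(accession = character(),
                                      peptide = character(),
                                      condition = character(),
                                      replicate = integer(),
                                      total_intensity = numeric()),
           peptides = peptides, config = config),
      class = "sim_truth"))
  }
  with_seed(config$seed + 1L, {
    site_tbl <- tidyr::unnest(
      dplyr::mutate(peptides[, c("accession", "peptide", "start", "cys_sites")],
                    n_cys = lengths(.data$cys_sites)),
      "cys_sites"
    )
    site_tbl <- dplyr::rename(site_tbl, position = "cys_sites")
    # a site shared by several peptides (missed cleavages) gets one truth row
    sites <- dplyr::distinct(
      dplyr::summarise(dplyr::group_by(site_tbl, .data$accession,
                                       .data$position),
                       single_cys = all(.data$n_cys == 1L), .groups = "drop")
    )
    n <- nrow(sites)

    fA <- .draw_baseline(n, config$bulk_mode_A, config$frac_high_A,
                         config$high_mode, config$bulk_concentration)
    fB <- if (config$shared_baseline) {
      fA
    } else {
      .draw_baseline(n, config$bulk_mode_B, config$frac_high_B,
                     config$high_mode, config$bulk_concentration)
    }
    label <- rep("null", n)

    # labels are assigned per peptide and applied to all of the peptide's
    # sites: the measured quantity is peptide-level (the mean over sites),
    # so injecting a site-level effect into only part of a multi-cysteine
    # peptide would dilute the peptide-level difference below effect_size
    site_key <- paste(sites$accession, sites$position)
    pep_sites <- purrr::map2(peptides$accession, peptides$cys_sites,
                             function(acc, pos) {
                               match(paste(acc, pos), site_key)
                             })
    pep_order <- sample(length(pep_sites))

    take_peptides <- function(order, n_sites_wanted, occupied) {
      chosen <- integer(0)
      covered <- integer(0)
      for (j in order) {
        if (length(covered) >= n_sites_wanted) break
        s <- pep_sites[[j]]
        if (any(s %in% occupied) || any(s %in% covered)) next
        chosen <- c(chosen, j)
        covered <- c(covered, s)
      }
      list(peptides = chosen, sites = covered)
    }

    # condition-specific (only-in-A) peptides: all sites unoxidized in B,
    # so the peptide's Sox signal truly vanishes there
    only <- take_peptides(pep_order, round(config$frac_only_in_A * n),
                          integer(0))
    if (length(only$sites)) {
      label[only$sites] <- "only_in_A"
      fB[only$sites] <- 0
      # keep A clearly measurable
      fA[only$sites] <- pmax(fA[only$sites], 0.05)
    }

    # injected differential peptides with an exact |effect_size| difference
    # at every site (hence also at peptide level)
    diff <- take_peptides(pep_order, round(config$frac_differential * n),
                          only$sites)
    for (j in diff$peptides) {
      s <- pep_sites[[j]]
      up_a <- runif(1) < config$frac_up_in_A
      base <- pmin(fB[s], 1 - config$effect_size)
      fA[s] <- if (up_a) base + config$effect_size else base
      fB[s] <- if (up_a) base else base + config$effect_size
      label[s] <- if (up_a) "up_in_A" else "up_in_B"
    }

    truth_sites <- tibble::tibble(
      accession = rep(sites$accession, 2L),
      position = rep(sites$position, 2L),
      condition = rep(conds, each = n),
      fraction = c(fA, fB),
      label = rep(label, 2L)
    )

    # total intensity decomposes into a per-(peptide, condition) abundance
    # and a per-replicate loading factor shared by the SH and Sox channels
    # of that replicate; normalization is expected to remove the latter
    base <- tidyr::expand_grid(
      peptides[, c("accession", "peptide")],
      condition = conds
    )
    base$abundance <- 2^rnorm(nrow(base), config$abundance_log2_mean,
                              config$abundance_log2_sd)
    load <- tidyr::expand_grid(condition = conds,
                               replicate = seq_len(config$n_replicates))
    load$loading <- 2^rnorm(nrow(load), 0, config$channel_shift_sd)
    ab <- dplyr::inner_join(base, load, by = "condition",
                            relationship = "many-to-many")
    ab$total_intensity <- ab$abundance * ab$loading
    ab <- ab[, c("accession", "peptide", "condition", "replicate",
                 "total_intensity")]

    structure(
      list(sites = truth_sites, abundance = ab, peptides = peptides,
           config = config),
      class = "sim_truth"
    )
  })
}

#' Simulate a MaxQuant-style reporter-intensity table
#'
#' Inverts the percent-oxidation computation: for every peptide, condition
#' and replicate the true total intensity `T` is split into
#' `Sox = T * f * e1` and `SH = T * (1 - f) * e2`, where `f` is the mean true
#' oxidation fraction over the peptide's cysteine sites and `e1`, `e2` are
#' independent lognormal noise factors with log2-scale standard deviation
#' `noise_sigma`. Intensities of exactly zero (fully reduced or fully
#' oxidized peptides) are recorded as missing, and low intensities drop out
#' with logistic probability below `missing_threshold`. Decoy (REV__),
#' contaminant (CON__) and only-by-site rows are appended for the filter
#' stage.
#'
#' @param truth A [simulate_truth()] result.
#' @param config A [sim_config()]; defaults to the one stored in `truth`.
#' @return A list of class `sim_dataset` with elements `table` (the
#'   MaxQuant-dialect tibble), `design` (the matching [redox_design()]) and
#'   `truth`.
#' @export
simulate_reporter_table <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  conds <- config$conditions
  design <- redox_design(conditions = conds,
                         replicates = config$n_replicates,
                         seed = config$seed)
  if (!nrow(truth$peptides)) {
    tbl <- tibble::tibble(
      Sequence = character(), Proteins = character(), Reverse = character(),
      `Potential contaminant` = character(),
      `Only identified by site` = character())
    for (ch in design$channels$channel) tbl[[ch]] <- numeric()
    return(structure(list(table = tbl, design = design, truth = truth),
                     class = "sim_dataset"))
  }
  with_seed(config$seed + 2L, {
    peptides <- truth$peptides
    # peptide-level true fraction per condition: mean over its Cys sites
    site_long <- tidyr::unnest(
      peptides[, c("accession", "peptide", "cys_sites")], "cys_sites")
    site_long <- dplyr::rename(site_long, position = "cys_sites")
    pf <- dplyr::inner_join(site_long, truth$sites,
                            by = c("accession", "position"))
    pf <- dplyr::summarise(
      dplyr::group_by(pf, .data$accession, .data$peptide, .data$condition),
      f = mean(.data$fraction), .groups = "drop")

    cells <- dplyr::inner_join(truth$abundance, pf,
                               by = c("accession", "peptide", "condition"))
    n <- nrow(cells)
    e1 <- 2^rnorm(n, 0, config$noise_sigma)
    e2 <- 2^rnorm(n, 0, config$noise_sigma)
    cells$sox <- cells$total_intensity * cells$f * e1
    cells$sh <- cells$total_intensity * (1 - cells$f) * e2

    dropout <- function(x) {
      miss <- x <= 0
      if (config$missing_threshold > 0) {
        p <- plogis(config$missing_steepness *
                      (config$missing_threshold - log2(pmax(x, .Machine$double.xmin))))
        miss <- miss | (runif(length(x)) < p)
      }
      ifelse(miss, NA_real_, x)
    }
    cells$sox <- dropout(cells$sox)
    cells$sh <- dropout(cells$sh)

    long <- tidyr::pivot_longer(cells, c("sh", "sox"), names_to = "thiol",
                                values_to = "intensity")
    long$thiol <- ifelse(long$thiol == "sh", "SH", "Sox")
    long <- dplyr::inner_join(long, design$channels,
                              by = c("condition", "replicate", "thiol"))
    wide <- tidyr::pivot_wider(
      long[, c("accession", "peptide", "channel", "intensity")],
      names_from = "channel", values_from = "intensity")

    tbl <- tibble::tibble(
      Sequence = wide$peptide,
      Proteins = wide$accession,
      Reverse = "",
      `Potential contaminant` = "",
      `Only identified by site` = ""
    )
    tbl <- dplyr::bind_cols(tbl, wide[, design$channels$channel])

    # decoy / contaminant / only-by-site rows for the filter stage
    n_decoy <- round(config$frac_decoy_rows * nrow(tbl))
    if (n_decoy > 0) {
      kinds <- rep(c("rev", "con", "obs"), length.out = n_decoy)
      dseq <- vapply(seq_len(n_decoy), function(i) {
        s <- .sample_protein(sample(8:20, 1L), 0.1)
        if (!grepl("C", s, fixed = TRUE)) substr(s, 1, 1) <- "C"
        s
      }, character(1))
      dint <- matrix(2^rnorm(n_decoy * nrow(design$channels),
                             config$abundance_log2_mean - 1,
                             config$abundance_log2_sd),
                     nrow = n_decoy)
      colnames(dint) <- design$channels$channel
      dec <- tibble::tibble(
        Sequence = dseq,
        Proteins = dplyr::case_when(
          kinds == "rev" ~ sprintf("REV__SIMD%03d", seq_len(n_decoy)),
          kinds == "con" ~ sprintf("CON__SIMD%03d", seq_len(n_decoy)),
          TRUE ~ sprintf("SIMD%03d", seq_len(n_decoy))
        ),
        Reverse = ifelse(kinds == "rev", "+", ""),
        `Potential contaminant` = ifelse(kinds == "con", "+", ""),
        `Only identified by site` = ifelse(kinds == "obs", "+", "")
      )
      dec <- dplyr::bind_cols(dec, tibble::as_tibble(dint))
      tbl <- dplyr::bind_rows(tbl, dec)
    }

    structure(list(table = tbl, design = design, truth = truth),
              class = "sim_dataset")
  })
}

#' Run the full generator and write its outputs to disk
#'
#' Writes the protein database (FASTA), the MaxQuant-dialect peptide table
#' (TSV), the ground-truth site table (TSV) and the experiment design (YAML)
#' into `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the file paths and the `sim_dataset`.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proteome <- generate_proteome(config)
  peptides <- cys_peptides(proteome, config)
  truth <- simulate_truth(peptides, config)
  ds <- simulate_reporter_table(truth, config)

  paths <- list(
    fasta = file.path(out_dir, "proteome.fasta"),
    peptides = file.path(out_dir, "peptides.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    design = file.path(out_dir, "design.yaml")
  )
  write_fasta_proteins(proteome, paths$fasta)
  readr::write_tsv(ds$table, paths$peptides, na = "")
  readr::write_tsv(truth$sites, paths$truth)
  write_design(ds$design, paths$design)
  invisible(c(paths, list(dataset = ds, proteome = proteome)))
}
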