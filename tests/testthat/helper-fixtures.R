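# Shared fixtures and independent oracles, all built in code.

# ---- brute-force trypsin/P oracle -----------------------------------------
# Enumerates every K/R cleavage boundary and every window spanning at most
# `mc` internal cleavage sites. Deliberately naive; independent of the
# implementation in R/digest.R.
oracle_digest <- function(sequence, mc) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  bounds <- c(0L, which(res %in% c("K", "R")), n)
  bounds <- sort(unique(bounds[bounds <= n]))
  bounds <- bounds[bounds < n | bounds == n]
  if (bounds[length(bounds)] != n) bounds <- c(bounds, n)
  out <- list()
  nb <- length(bounds)
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) {
      internal <- j - i - 1L
      if (internal > mc) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(sequence, bounds[i] + 1L, bounds[j]),
        start = bounds[i] + 1L,
        missed_cleavages = internal
      )
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, nchar(df$peptide)), , drop = FALSE]
}

# ---- exhaustive permutation-FDR oracle ------------------------------------
# Independent re-implementation on a plain matrix: plain loops, no shared
# helper code. mat has 2r columns, first r = condition A.
oracle_perm_q <- function(mat, n_a, min_valid = 2, s0 = 0) {
  n_cols <- ncol(mat)
  d_of <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < min_valid || length(b) < min_valid) return(NA_real_)
    va <- sum((a - mean(a))^2); vb <- sum((b - mean(b))^2)
    sp2 <- (va + vb) / (length(a) + length(b) - 2)
    se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    delta <- mean(a) - mean(b)
    if (se + s0 == 0) {
      if (abs(delta) <= 1e-9) return(0)
      return(sign(delta) * Inf)
    }
    delta / (se + s0)
  }
  row_d <- function(idx_a) {
    idx_b <- setdiff(seq_len(n_cols), idx_a)
    apply(mat, 1, function(r) d_of(r[idx_a], r[idx_b]))
  }
  obs <- row_d(seq_len(n_a))
  sets <- combn(n_cols, n_a, simplify = FALSE)
  observed_set <- seq_len(n_a)
  mirror_set <- if (n_cols - n_a == n_a) (n_a + 1L):n_cols else integer(0)
  sets <- Filter(function(s) !identical(s, observed_set) &&
                   !identical(s, mirror_set), sets)
  null_d <- unlist(lapply(sets, row_d))
  null_d <- null_d[!is.na(null_d)]
  q <- vapply(obs, function(di) {
    if (is.na(di)) return(NA_real_)
    nn <- sum(abs(null_d) >= abs(di)) / length(sets)
    no <- sum(abs(obs) >= abs(di), na.rm = TRUE)
    min(max(nn / no, 0), 1)
  }, numeric(1))
  # q = running min of the FDR estimate over thresholds <= own |d|
  ord <- order(abs(obs), decreasing = FALSE, na.last = TRUE)
  qs <- q[ord]
  ok <- !is.na(qs)
  qs[ok] <- cummin(qs[ok])
  q[ord] <- qs
  q
}

# ---- in-memory peptide-table coercion -------------------------------------
# Turn a simulated MaxQuant-dialect tibble into the reader's output shape
# without touching disk.
as_read_table <- function(tbl) {
  out <- tibble::tibble(
    sequence = tbl$Sequence,
    proteins = tbl$Proteins,
    leading_protein = vapply(strsplit(tbl$Proteins, ";"), `[`,
                             character(1), 1),
    reverse = tbl$Reverse == "+",
    contaminant = tbl$`Potential contaminant` == "+",
    only_by_site = tbl$`Only identified by site` == "+"
  )
  chans <- setdiff(names(tbl), c("Sequence", "Proteins", "Reverse",
                                 "Potential contaminant",
                                 "Only identified by site"))
  for (ch in chans) out[[ch]] <- tbl[[ch]]
  attr(out, "channels") <- chans
  out
}

# Full pipeline from a simulated dataset to an oxidation profile.
sim_to_profile <- function(ds) {
  d <- ds$design
  tbl <- as_read_table(ds$table)
  filtered <- filter_records(tbl, d)
  normalized <- normalize_median_of_medians(log2_transform(filtered, d), d)
  compute_oxidation(normalized, d)
}

# Peptide-level truth: mean site fraction per condition plus labels.
truth_peptide_table <- function(truth) {
  site_long <- tidyr::unnest(
    truth$peptides[, c("accession", "peptide", "cys_sites")], "cys_sites")
  site_long <- dplyr::rename(site_long, position = "cys_sites")
  joined <- dplyr::inner_join(site_long, truth$sites,
                              by = c("accession", "position"))
  dplyr::summarise(
    dplyr::group_by(joined, accession, peptide, condition),
    f = mean(fraction),
    all_injected = all(label %in% c("up_in_A", "up_in_B")),
    any_only_in_A = any(label == "only_in_A"),
    .groups = "drop")
}

# A compact design used by unit tests: 2 conditions x 3 replicates with
# short channel names "Reporter intensity corrected <i> <cond>".
test_design <- function(...) {
  redox_design(conditions = c("FL", "ABM"), replicates = 3, ...)
}

# Build a minimal peptide table from an ox specification. `values` is a list
# keyed by channel name -> numeric vector (raw linear intensities, NA = missing).
make_table <- function(sequences, proteins, values, design) {
  out <- tibble::tibble(
    sequence = sequences,
    proteins = proteins,
    leading_protein = vapply(strsplit(proteins, ";"), `[`, character(1), 1),
    reverse = FALSE, contaminant = FALSE, only_by_site = FALSE
  )
  for (ch in design$channels$channel) {
    out[[ch]] <- if (!is.null(values[[ch]])) values[[ch]] else rep(NA_real_, length(sequences))
  }
  attr(out, "channels") <- design$channels$channel
  out
}

# Synthetic stand-in for the Denr protein: a random backbone carrying the
# three observed Denr peptides at the protein coordinates of their cysteines
# (Cys13; Cys34/37/44; Cys132). The inter-peptide filler is synthetic; only
# the placed peptides and their coordinates are meaningful.
synthetic_denr <- function() {
  pep1 <- "ATDISESSGADCK"           # Cys at protein position 13 (start 2)
  pep2 <- "VLYCGVCSLPTEYCEYMPDVAK"  # Cys at 34, 37, 44 (start 31)
  pep3 <- "VCGLATFEIDLK"            # Cys at 132 (start 131)
  filler <- function(n) paste(rep("A", n), collapse = "")
  seqn <- paste0("M", pep1,                    # 1 + 13 = 14
                 filler(30 - 14), pep2,        # pep2 starts at 31, ends 52
                 filler(130 - 52), pep3,       # pep3 starts at 131, ends 142
                 "GGR")
  stopifnot(substr(seqn, 13, 13) == "C", substr(seqn, 34, 34) == "C",
            substr(seqn, 37, 37) == "C", substr(seqn, 44, 44) == "C",
            substr(seqn, 132, 132) == "C")
  tibble::tibble(accession = "Q9CQJ6_SYNTHETIC", sequence = seqn)
}
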