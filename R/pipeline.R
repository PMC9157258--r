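#' Run the full redox-proteomics analysis
#'
#' Orchestrates read, filter, log2 transform, median-of-medians
#' normalization, percent-oxidation computation, differential testing with
#' permutation FDR, oxidation-class binning, site mapping and annotation
#' matching, and writes all result tables into `out_dir`:
#'
#' * `results_peptides.tsv` — peptide-level results (per-replicate oxidation,
#'   condition summaries, t/p/q, calls, classes, annotation labels)
#' * `results_sites.tsv` — unique cysteine sites with aggregated oxidation
#' * `filter_report.tsv` — removal count per filtering rule
#' * `normalization_audit.tsv` — per-channel medians, targets and shifts
#' * `run_log.txt` — package version, parameters and row counts
#'
#' @param peptides_path MaxQuant-dialect peptide table (TSV).
#' @param fasta_path Protein database (FASTA).
#' @param design A [redox_design()], or path to a design YAML.
#' @param annotations_path Optional cysteine annotation TSV.
#' @param out_dir Output directory (created if missing).
#' @param column_map A [mq_column_map()].
#' @return Invisibly, a list with `results` (the `redox_diff` tibble),
#'   `profile`, `sites`, `mapping`, `summary` and the output paths.
#' @export
run_analysis <- function(peptides_path, fasta_path, design,
                         annotations_path = NULL,
                         out_dir = ".",
                         column_map = mq_column_map()) {
  if (is.character(design)) design <- read_design(design)
  stopifnot(inherits(design, "redox_design"))
  for (p in c(peptides_path, fasta_path, annotations_path)) {
    if (!file.exists(p)) {
      stopf("cysredox_config_error", "input file not found: %s", p)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("cysredox %s", as.character(utils::packageVersion("cysredox"))),
    sprintf("peptides: %s", peptides_path),
    sprintf("fasta: %s", fasta_path),
    sprintf("annotations: %s", annotations_path %||% "(none)"),
    sprintf("conditions: %s vs %s", design$conditions[1],
            design$conditions[2]),
    sprintf("alpha=%g min_valid=%d only_in=%d:0 class_bounds=%g/%g s0=%g seed=%d",
            design$params$alpha, design$params$min_valid,
            design$params$only_in_required, design$params$class_bounds[1],
            design$params$class_bounds[2], design$params$s0,
            design$params$seed)
  )

  table <- read_peptide_table(peptides_path, column_map)
  log_lines <- c(log_lines, sprintf("rows read: %d", nrow(table)))
  proteins <- read_fasta_proteins(fasta_path)

  filtered <- filter_records(table, design)
  report <- attr(filtered, "filter_report")
  log_lines <- c(log_lines,
                 sprintf("filter %s: removed %d", report$rule,
                         report$removed),
                 sprintf("rows after filtering: %d", nrow(filtered)))

  normalized <- normalize_median_of_medians(log2_transform(filtered, design),
                                            design)
  profile <- compute_oxidation(normalized, design)
  dropped <- attr(profile, "dropped")
  if (nrow(dropped)) {
    log_lines <- c(log_lines,
                   sprintf("peptides without any valid oxidation value: %d",
                           nrow(dropped)))
  }

  results <- diff_oxidation(profile, design)
  log_lines <- c(log_lines,
                 sprintf("peptides quantified: %d", nrow(results)),
                 sprintf("significant (q < %g): %d", design$params$alpha,
                         sum(results$significant)),
                 sprintf("only in %s: %d / only in %s: %d",
                         design$conditions[1],
                         sum(results$only_in == design$conditions[1]),
                         design$conditions[2],
                         sum(results$only_in == design$conditions[2])))

  mapping <- map_peptides_to_sites(results, proteins)
  sites <- aggregate_to_sites(results, mapping)
  log_lines <- c(log_lines,
                 sprintf("unique cysteine sites: %d", nrow(sites)))

  out <- dplyr::left_join(results, mapping$status,
                          by = c("sequence", "leading_protein"))
  if (!is.null(annotations_path)) {
    ann <- read_annotations(annotations_path)
    lab <- annotate_sites(mapping, ann)
    out <- dplyr::left_join(out, lab$peptides,
                            by = c("sequence", "leading_protein"))
    sites <- dplyr::left_join(sites, lab$sites,
                              by = c("accession", "position"))
  }

  # per-replicate oxidation columns for the peptide-level report
  ox_wide <- tidyr::pivot_wider(
    dplyr::mutate(profile,
                  col = sprintf("ox_%s_%d", .data$condition,
                                .data$replicate)),
    id_cols = c("sequence", "leading_protein"),
    names_from = "col", values_from = "ox")
  out <- dplyr::left_join(ox_wide, out, by = c("sequence",
                                               "leading_protein"))

  paths <- list(
    peptides = file.path(out_dir, "results_peptides.tsv"),
    sites = file.path(out_dir, "results_sites.tsv"),
    filter_report = file.path(out_dir, "filter_report.tsv"),
    normalization = file.path(out_dir, "normalization_audit.tsv"),
    log = file.path(out_dir, "run_log.txt")
  )
  write_results(out, paths$peptides)
  write_results(sites, paths$sites)
  readr::write_tsv(report, paths$filter_report)
  readr::write_tsv(attr(normalized, "normalization"), paths$normalization)
  writeLines(log_lines, paths$log)

  summary <- summarize_condition(profile, design)
  invisible(list(results = results, profile = profile, sites = sites,
                 mapping = mapping, summary = summary, paths = paths,
                 report = report))
}
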