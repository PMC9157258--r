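#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats median pt rnorm runif rbeta plogis setNames
#' @importFrom utils combn head
NULL

# Stable row identity for a peptide record: sequence plus leading accession.
peptide_key <- function(sequence, leading_protein) {
  paste(sequence, leading_protein, sep = "|")
}

first_accession <- function(proteins) {
  vapply(strsplit(proteins, ";", fixed = TRUE),
         function(x) if (length(x)) x[[1]] else NA_character_,
         character(1))
}

# Run `expr` with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

AA_ALPHABET_20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

assert_aa <- function(sequence, what = "sequence") {
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AA_ALPHABET_20)
  if (length(bad)) {
    abort(sprintf("%s contains non-standard residues: %s",
                  what, paste(bad, collapse = ", ")),
          class = "cysredox_input_error")
  }
  invisible(sequence)
}

stopf <- function(class, fmt, ...) {
  abort(sprintf(fmt, ...), class = c(class, "cysredox_error"))
}
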