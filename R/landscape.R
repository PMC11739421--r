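#' Construct a combinatorial sequence-fitness landscape
#'
#' A landscape maps length-`k` amino-acid combinations ("combos") at a fixed
#' set of mutated sites to scalar fitness values. The design space is
#' `length(alphabet)^k`; a landscape may cover all of it (combinatorially
#' complete) or a subset.
#'
#' @param combos character vector of variant combo strings, all the same
#'   length, over `alphabet`. Case-folded to upper case.
#' @param fitness numeric vector of fitness values, one per combo.
#' @param alphabet ordered character vector of allowed single-letter symbols.
#'   Defaults to the 20 canonical amino acids. The stop symbol `*` is never
#'   allowed.
#' @param metadata free-form provenance list (source file, normalization
#'   mode, generator parameters, seed).
#' @return An object of class `alde_landscape`: a list with elements `k`,
#'   `alphabet`, `fitness` (named numeric vector, names are combos) and
#'   `metadata`.
#' @examples
#' l <- landscape(c("AC", "AD", "CC"), c(1, 2, 3))
#' l$k
#' @export
landscape <- function(combos, fitness, alphabet = AA20, metadata = list()) {
  combos <- toupper(as.character(combos))
  fitness <- as.numeric(fitness)
  if (length(combos) != length(fitness)) {
    stop_alde("combos (%d) and fitness (%d) lengths differ",
              length(combos), length(fitness), class = "alde_structural_error")
  }
  if (length(combos) == 0L) {
    stop_alde("landscape has no entries", class = "alde_empty_landscape_error")
  }
  lens <- unique(nchar(combos))
  if (length(lens) != 1L) {
    stop_alde("nonuniform combo lengths: %s", paste(lens, collapse = ", "),
              class = "alde_structural_error")
  }
  if (anyDuplicated(combos)) {
    stop_alde("duplicate combos: %s",
              paste(unique(combos[duplicated(combos)]), collapse = ", "),
              class = "alde_structural_error")
  }
  if (any(!is.finite(fitness))) {
    stop_alde("non-finite fitness values present", class = "alde_parse_error")
  }
  bad <- setdiff(unique(strsplit(paste(combos, collapse = ""), "")[[1]]), alphabet)
  if (length(bad) > 0L) {
    stop_alde("symbols outside the alphabet: %s", paste(bad, collapse = ", "),
              class = "alde_structural_error")
  }
  k <- lens
  if (length(combos) > length(alphabet)^k) {
    stop_alde("more entries than the design space allows",
              class = "alde_structural_error")
  }
  names(fitness) <- combos
  structure(list(k = k, alphabet = alphabet, fitness = fitness,
                 metadata = metadata),
            class = "alde_landscape")
}

#' @export
print.alde_landscape <- function(x, ...) {
  cat(sprintf("<alde_landscape> k=%d sites, alphabet size %d, %d/%s variants\n",
              x$k, length(x$alphabet), length(x$fitness),
              format(design_space_size(x$k, length(x$alphabet)), big.mark = ",")))
  cat(sprintf("  fitness range [%.4g, %.4g]\n",
              min(x$fitness), max(x$fitness)))
  if (!is.null(x$metadata$normalization)) {
    cat(sprintf("  normalized: %s (denominator %.4g)\n",
                x$metadata$normalization$mode,
                x$metadata$normalization$denominator))
  }
  invisible(x)
}

#' @export
as.data.frame.alde_landscape <- function(x, ...) {
  data.frame(variant = names(x$fitness), fitness = unname(x$fitness),
             stringsAsFactors = FALSE)
}

#' Load a landscape from a delimited-text file
#'
#' Reads a CSV/TSV with a header row, drops rows whose combo contains the
#' stop symbol `*`, upper-cases combos, and averages rows with identical
#' combos into a single entry (arithmetic mean, as when replicate yields for
#' the same amino-acid combination are averaged). `k` is inferred from combo
#' length.
#'
#' @param path file path; delimiter auto-detected by [data.table::fread()].
#' @param combo_col,fitness_col column names holding the combo string and
#'   the numeric fitness. Defaults `"variant"` and `"fitness"`.
#' @param alphabet allowed symbols; defaults to the 20 canonical amino acids.
#' @return An [landscape()] object. `metadata$load_report` records the number
#'   of rows read, rows dropped for stop codons, and duplicate rows averaged.
#' @export
load_landscape <- function(path, combo_col = "variant",
                           fitness_col = "fitness", alphabet = AA20) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(
    character = combo_col))
  if (!all(c(combo_col, fitness_col) %in% names(dt))) {
    stop_alde("columns '%s'/'%s' not found in %s (have: %s)",
              combo_col, fitness_col, path, paste(names(dt), collapse = ", "),
              class = "alde_structural_error")
  }
  combo <- toupper(as.character(dt[[combo_col]]))
  fit_raw <- dt[[fitness_col]]
  fit <- suppressWarnings(as.numeric(fit_raw))
  bad <- which(!is.finite(fit))
  if (length(bad) > 0L) {
    stop_alde("non-numeric fitness at row %d (value '%s')",
              bad[1], as.character(fit_raw[bad[1]]), class = "alde_parse_error")
  }
  n_read <- length(combo)
  has_stop <- grepl("*", combo, fixed = TRUE)
  combo <- combo[!has_stop]
  fit <- fit[!has_stop]
  if (length(combo) == 0L) {
    stop_alde("no rows remain after stop-codon filtering",
              class = "alde_empty_landscape_error")
  }
  if (length(unique(nchar(combo))) != 1L) {
    stop_alde("nonuniform combo lengths in %s", path,
              class = "alde_structural_error")
  }
  agg <- tapply(fit, combo, mean)
  combos <- names(agg)
  landscape(combos, as.numeric(agg), alphabet = alphabet,
            metadata = list(
              source = path,
              load_report = list(rows_read = n_read,
                                 rows_dropped_stop = sum(has_stop),
                                 rows_averaged = length(fit) - length(combos))))
}

#' Write a landscape to CSV with a JSON provenance sidecar
#'
#' @param l an [landscape()] object.
#' @param path output CSV path; a sidecar `<path>.json` records the metadata
#'   (normalization mode and denominator, load report, generator spec).
#' @return `path`, invisibly.
#' @export
write_landscape <- function(l, path) {
  df <- as.data.frame(l)
  data.table::fwrite(df, path)
  jsonlite::write_json(l$metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Normalize landscape fitnesses
#'
#' Either to the maximum fitness (`mode = "max"`; afterwards the best variant
#' has fitness exactly 1) or to a reference variant such as a parent sequence
#' (`mode = "reference"`; the reference gets fitness 1, improved variants
#' exceed 1).
#'
#' @param l an [landscape()] object.
#' @param mode `"max"` or `"reference"`.
#' @param reference combo string of the reference variant (mode
#'   `"reference"` only).
#' @return A new landscape with every fitness divided by the denominator;
#'   `metadata$normalization` records mode and denominator.
#' @export
normalize_landscape <- function(l, mode = c("max", "reference"),
                                reference = NULL) {
  mode <- match.arg(mode)
  if (mode == "max") {
    denom <- max(l$fitness)
  } else {
    if (is.null(reference) || !reference %in% names(l$fitness)) {
      stop_alde("reference variant '%s' not present in the landscape",
                as.character(reference %||% "NULL"),
                class = "alde_normalization_error")
    }
    denom <- unname(l$fitness[[reference]])
  }
  if (!is.finite(denom) || denom <= 0) {
    stop_alde("normalization denominator is %.4g; need > 0", denom,
              class = "alde_normalization_error")
  }
  meta <- l$metadata
  meta$normalization <- list(mode = mode, denominator = denom,
                             reference = reference)
  landscape(names(l$fitness), l$fitness / denom, alphabet = l$alphabet,
            metadata = meta)
}

#' Size of the combinatorial design space
#'
#' @param k number of mutated sites (>= 1).
#' @param alphabet_size number of symbols per site (>= 2).
#' @return `alphabet_size^k` as an exact whole number (e.g. 160000 for four
#'   sites over the 20 amino acids).
#' @export
design_space_size <- function(k, alphabet_size) {
  stopifnot(k >= 1, alphabet_size >= 2, k == round(k),
            alphabet_size == round(alphabet_size))
  # doubles are exact for whole numbers up to 2^53, covering k <= 10 at 20 aa
  out <- 1
  for (i in seq_len(k)) out <- out * alphabet_size
  out
}

#' Enumerate every variant of a design space
#'
#' @param k number of mutated sites.
#' @param alphabet ordered symbol vector.
#' @param max_size refuse to materialize more than this many variants
#'   (capacity guard; default 2e6).
#' @return Character vector of all `length(alphabet)^k` combos in
#'   lexicographic order by alphabet index (the last site varies fastest).
#' @export
enumerate_design_space <- function(k, alphabet = AA20, max_size = 2e6) {
  n <- design_space_size(k, length(alphabet))
  if (n > max_size) {
    stop_alde(paste0("design space has %s variants, above the %s cap; ",
                     "process it in streamed chunks instead"),
              format(n, big.mark = ","), format(max_size, big.mark = ","),
              class = "alde_capacity_error")
  }
  grid <- expand.grid(rev(replicate(k, alphabet, simplify = FALSE)),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  do.call(paste0, rev(grid))
}

#' Variants with measurable function
#'
#' @param l an [landscape()] object.
#' @param threshold fitness must be strictly greater than this (default 0).
#' @return Character vector of active combos.
#' @export
active_variants <- function(l, threshold = 0) {
  names(l$fitness)[l$fitness > threshold]
}

#' Look up fitness for combos, with a missing-variant policy
#'
#' Landscapes from real screens are only nearly complete. Simulations that
#' query an unmeasured combo either treat it as non-functional
#' (`missing = "zero"`, the default) or drop it (`missing = "skip"`).
#'
#' @param l an [landscape()] object.
#' @param combos character vector of combos to observe.
#' @param missing `"zero"` or `"skip"`.
#' @return Named numeric vector of fitnesses (shorter than `combos` when
#'   `missing = "skip"` drops unmeasured ones).
#' @export
observe_fitness <- function(l, combos, missing = c("zero", "skip")) {
  missing <- match.arg(missing)
  hit <- combos %in% names(l$fitness)
  if (missing == "skip") {
    combos <- combos[hit]
    return(l$fitness[combos])
  }
  out <- stats::setNames(numeric(length(combos)), combos)
  out[combos[hit]] <- l$fitness[combos[hit]]
  out
}
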