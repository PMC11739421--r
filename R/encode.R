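#' Variant encoders
#'
#' An encoder turns a length-`k` amino-acid combination into a numeric
#' feature vector of length `k * per_residue_dim` by concatenating one block
#' per site. Available encoders:
#'
#' * `onehot_encoder()` — 20 indicator columns per residue (which amino
#'   acid is present).
#' * `aaindex_encoder()` — 4 continuous physicochemical descriptors per
#'   residue: the first four principal components of the published AAIndex
#'   property matrix, precomputed and bundled with the package.
#' * `physchem19_encoder()` (alias `georgiev_encoder()`) — 19 continuous
#'   descriptors per residue. The bundled table is a synthetic stand-in: the
#'   19 principal components of the AAIndex matrix (its full rank), matching
#'   the dimensionality of the Georgiev descriptor set, whose published
#'   values are not redistributed here.
#' * `descriptor_encoder()` — any user-supplied per-residue table.
#' * [load_embedding_table()] — precomputed per-residue embeddings, e.g.
#'   from a protein language model (1280 per residue for ESM2-650M).
#'
#' Descriptor tables are z-standardized column-wise over the 20 alphabet
#' rows at construction, which stabilizes Gaussian-process length scales.
#'
#' @param alphabet ordered symbols the encoder accepts.
#' @return An object of class `alde_encoder` with fields `name`,
#'   `per_residue_dim`, `alphabet`, and (for table-backed encoders) `table`,
#'   a `length(alphabet) x per_residue_dim` matrix with symbol rownames.
#' @name encoders
NULL

new_encoder <- function(name, per_residue_dim, alphabet, table = NULL,
                        site_specific = FALSE) {
  if (!is.null(table)) {
    stopifnot(is.matrix(table), ncol(table) == per_residue_dim)
    miss <- setdiff(alphabet, rownames(table))
    if (length(miss) > 0L) {
      stop_alde("descriptor table is missing symbols: %s",
                paste(miss, collapse = ", "),
                class = "alde_completeness_error")
    }
  }
  structure(list(name = name, per_residue_dim = as.integer(per_residue_dim),
                 alphabet = alphabet, table = table,
                 site_specific = site_specific),
            class = "alde_encoder")
}

#' @export
print.alde_encoder <- function(x, ...) {
  cat(sprintf("<alde_encoder> %s: %d dims per residue, alphabet size %d%s\n",
              x$name, x$per_residue_dim, length(x$alphabet),
              if (x$site_specific) ", site-specific table" else ""))
  invisible(x)
}

#' @rdname encoders
#' @export
onehot_encoder <- function(alphabet = AA20) {
  new_encoder("onehot", length(alphabet), alphabet)
}

#' @param table numeric matrix with one row per alphabet symbol (rownames)
#'   and one column per descriptor.
#' @param name provenance tag for the encoder.
#' @param standardize z-score the columns over the alphabet rows (default
#'   TRUE).
#' @rdname encoders
#' @export
descriptor_encoder <- function(table, name = "descriptor",
                               alphabet = rownames(table),
                               standardize = TRUE) {
  tab <- as.matrix(table)
  if (standardize) {
    mu <- colMeans(tab)
    sdv <- apply(tab, 2, stats::sd)
    sdv[sdv == 0] <- 1
    tab <- sweep(sweep(tab, 2, mu), 2, sdv, "/")
  }
  new_encoder(name, ncol(tab), alphabet, table = tab)
}

read_descriptor_csv <- function(file, name) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  tab <- as.matrix(df[, -1, drop = FALSE])
  rownames(tab) <- toupper(df[[1]])
  descriptor_encoder(tab, name = name)
}

#' @rdname encoders
#' @export
aaindex_encoder <- function() {
  read_descriptor_csv(system.file("extdata", "aaindex_pc4.csv",
                                  package = "alde", mustWork = TRUE),
                      "aaindex")
}

#' @rdname encoders
#' @export
physchem19_encoder <- function() {
  read_descriptor_csv(system.file("extdata", "physchem19_synthetic.csv",
                                  package = "alde", mustWork = TRUE),
                      "physchem19")
}

#' @rdname encoders
#' @export
georgiev_encoder <- physchem19_encoder

#' Load a precomputed per-residue embedding table
#'
#' Accepts a delimited text file mapping either each amino-acid symbol
#' (column `residue`) or each (site, symbol) pair (columns `site` and
#' `residue`) to a fixed-length numeric vector; the per-residue dimension is
#' inferred from the columns. Global tables apply the same vector at every
#' site; site-specific tables must cover every site of the design space.
#'
#' @param path delimited text file with a header.
#' @param alphabet symbols that must all be present.
#' @param standardize z-score columns over the table rows (default FALSE:
#'   learned embeddings arrive on their own scale).
#' @return An `alde_encoder` (see [encoders]).
#' @export
load_embedding_table <- function(path, alphabet = AA20, standardize = FALSE) {
  df <- data.table::fread(path, header = TRUE)
  df <- as.data.frame(df)
  site_specific <- "site" %in% names(df)
  if (!"residue" %in% names(df)) {
    stop_alde("embedding table needs a 'residue' column",
              class = "alde_format_error")
  }
  num_cols <- setdiff(names(df), c("residue", "site"))
  tab <- as.matrix(df[, num_cols, drop = FALSE])
  if (!is.numeric(tab)) {
    stop_alde("embedding table has non-numeric value columns",
              class = "alde_format_error")
  }
  if (anyNA(tab)) {
    stop_alde("embedding table has ragged/missing values",
              class = "alde_format_error")
  }
  res <- toupper(df$residue)
  if (site_specific) {
    sites <- sort(unique(df$site))
    per_site <- split(seq_len(nrow(df)), df$site)
    tabs <- lapply(per_site, function(ix) {
      m <- tab[ix, , drop = FALSE]
      rownames(m) <- res[ix]
      miss <- setdiff(alphabet, rownames(m))
      if (length(miss) > 0L) {
        stop_alde("embedding table is missing symbols: %s",
                  paste(miss, collapse = ", "),
                  class = "alde_completeness_error")
      }
      m
    })
    enc <- new_encoder("embedding_table", ncol(tab), alphabet,
                       table = tabs[[1]], site_specific = TRUE)
    enc$site_tables <- tabs
    return(enc)
  }
  rownames(tab) <- res
  miss <- setdiff(alphabet, rownames(tab))
  if (length(miss) > 0L) {
    stop_alde("embedding table is missing symbols: %s",
              paste(miss, collapse = ", "),
              class = "alde_completeness_error")
  }
  if (standardize) return(descriptor_encoder(tab, name = "embedding_table",
                                             alphabet = alphabet))
  new_encoder("embedding_table", ncol(tab), alphabet, table = tab)
}

#' Resolve an encoder by name
#'
#' @param name one of `"onehot"`, `"aaindex"`, `"physchem19"`,
#'   `"georgiev"`, `"embedding"`, or an `alde_encoder` object (returned
#'   unchanged).
#' @param embedding_table path to an embedding table, required for
#'   `"embedding"`.
#' @return An `alde_encoder`.
#' @export
get_encoder <- function(name, embedding_table = NULL) {
  if (inherits(name, "alde_encoder")) return(name)
  switch(name,
         onehot = onehot_encoder(),
         aaindex = aaindex_encoder(),
         physchem19 = physchem19_encoder(),
         georgiev = georgiev_encoder(),
         embedding = {
           if (is.null(embedding_table)) {
             stop_alde("encoder 'embedding' needs an embedding_table path",
                       class = "alde_format_error")
           }
           load_embedding_table(embedding_table)
         },
         stop_alde("unknown encoder '%s'", name, class = "alde_format_error"))
}

#' Encode a single variant
#'
#' One-hot encoding places a single 1 in each site's block at the alphabet
#' index of the residue; table-backed encoders concatenate the per-residue
#' table rows in site order.
#'
#' @param combo variant combo string.
#' @param encoder an `alde_encoder`.
#' @return Numeric vector of length `nchar(combo) * per_residue_dim`.
#' @export
encode_variant <- function(combo, encoder) {
  chars <- strsplit(toupper(combo), "")[[1]]
  pos <- match(chars, encoder$alphabet)
  if (anyNA(pos)) {
    i <- which(is.na(pos))[1]
    stop_alde("unknown symbol '%s' at site %d of '%s'", chars[i], i, combo,
              class = "alde_encoding_error")
  }
  k <- length(chars)
  d <- encoder$per_residue_dim
  if (is.null(encoder$table) && !encoder$site_specific) {
    v <- numeric(k * d)
    v[(seq_len(k) - 1L) * d + pos] <- 1
    return(v)
  }
  if (encoder$site_specific) {
    if (length(encoder$site_tables) < k) {
      stop_alde("site-specific table covers %d sites but combo has %d",
                length(encoder$site_tables), k, class = "alde_structural_error")
    }
    return(unlist(lapply(seq_len(k), function(s) {
      encoder$site_tables[[s]][chars[s], ]
    }), use.names = FALSE))
  }
  as.numeric(t(encoder$table[chars, , drop = FALSE]))
}

#' Build a design matrix for a set of variants
#'
#' @param combos character vector of variant combo strings, all length `k`.
#' @param encoder an `alde_encoder`.
#' @return Numeric matrix, one row per variant in input order (rownames are
#'   the combos), `k * per_residue_dim` columns; attribute `encoder_name`
#'   carries provenance.
#' @export
build_design_matrix <- function(combos, encoder) {
  combos <- toupper(combos)
  k <- if (length(combos) > 0L) {
    lens <- unique(nchar(combos))
    if (length(lens) != 1L) {
      stop_alde("mixed combo lengths: %s", paste(lens, collapse = ", "),
                class = "alde_structural_error")
    }
    lens
  } else {
    1L
  }
  d <- encoder$per_residue_dim
  if (length(combos) == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = k * d)
    attr(m, "encoder_name") <- encoder$name
    return(m)
  }
  if (is.null(encoder$table) && !encoder$site_specific) {
    # vectorized one-hot
    n <- length(combos)
    pos <- matrix(match(unlist(strsplit(combos, ""), use.names = FALSE),
                        encoder$alphabet), nrow = n, byrow = TRUE)
    if (anyNA(pos)) {
      bad <- which(is.na(pos), arr.ind = TRUE)[1, ]
      stop_alde("unknown symbol at site %d of '%s'", bad[2], combos[bad[1]],
                class = "alde_encoding_error")
    }
    m <- matrix(0, nrow = n, ncol = k * d)
    for (s in seq_len(k)) {
      m[cbind(seq_len(n), (s - 1L) * d + pos[, s])] <- 1
    }
  } else {
    m <- t(vapply(combos, encode_variant, numeric(k * d), encoder = encoder))
  }
  rownames(m) <- combos
  attr(m, "encoder_name") <- encoder$name
  m
}
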