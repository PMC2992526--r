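#' Presence/absence matrix of gene families
#'
#' Construct a validated taxa-by-families binary matrix, the universal input
#' of the package. Rows are taxa, columns are gene families, entries are 0
#' (absent) or 1 (present).
#'
#' @param values integer or numeric matrix of 0/1 values, one row per taxon.
#' @param taxon_ids character vector of unique, non-empty taxon identifiers.
#'   Defaults to `rownames(values)`.
#' @param family_ids character vector of unique family identifiers. Defaults
#'   to `colnames(values)`; synthesized as `"F000001"`, ... when absent.
#' @return An object of class `pa_matrix`: an integer matrix with taxon ids
#'   as rownames and family ids as colnames.
#' @examples
#' m <- pa_matrix(rbind(A = c(1, 1, 0), B = c(0, 1, 1)))
#' m
#' @export
pa_matrix <- function(values, taxon_ids = rownames(values),
                      family_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(taxon_ids)) {
    stop2("pa_taxa_error", "taxon_ids are required (no rownames present)")
  }
  taxon_ids <- as.character(taxon_ids)
  if (is.null(family_ids)) {
    family_ids <- sprintf("F%06d", seq_len(ncol(values)))
  }
  family_ids <- as.character(family_ids)
  if (length(taxon_ids) != nrow(values)) {
    stop2("pa_taxa_error", "length(taxon_ids) must equal nrow(values)")
  }
  if (length(family_ids) != ncol(values)) {
    stop2("pa_family_error", "length(family_ids) must equal ncol(values)")
  }
  if (anyDuplicated(taxon_ids) || any(!nzchar(taxon_ids))) {
    stop2("pa_taxa_error", "taxon_ids must be unique non-empty strings")
  }
  if (anyDuplicated(family_ids)) {
    stop2("pa_family_error", "family_ids must be unique")
  }
  storage.mode(values) <- "integer"
  if (anyNA(values) || !all(values == 0L | values == 1L)) {
    stop2("pa_value_error", "all entries must be 0 or 1")
  }
  dimnames(values) <- list(taxon_ids, family_ids)
  structure(values, class = c("pa_matrix", "matrix", "array"))
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("Presence/absence matrix: %d taxa x %d gene families\n",
              nrow(x), ncol(x)))
  cat(sprintf("  presence fraction: %.3f\n", mean(x)))
  invisible(x)
}

#' @export
`[.pa_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) class(out) <- c("pa_matrix", "matrix", "array")
  out
}

stop2 <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "condlogdet_error", "error")))
}

#' Read a presence/absence matrix
#'
#' Reads the PHYLIP-like dialect (header line `"ntaxa nfamilies"`, then one
#' line per taxon: a name terminated by whitespace followed by 0/1
#' characters, which may be separated by spaces) or a tab-delimited table
#' dialect (header row of family ids, first column taxon ids). Taxon names
#' of any length are accepted; the classic fixed 10-character PHYLIP names
#' also parse because the name is whitespace-delimited.
#'
#' @param source a file path or connection, or a character vector of lines
#'   (when `text = TRUE`).
#' @param dialect `"phylip"` or `"table"`.
#' @param text logical; if `TRUE`, `source` is the literal text.
#' @return a [pa_matrix].
#' @export
read_presence_absence <- function(source, dialect = c("phylip", "table"),
                                  text = FALSE) {
  dialect <- match.arg(dialect)
  lines <- if (text) unlist(strsplit(source, "\n", fixed = TRUE))
           else readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop2("pa_parse_error", "empty input")
  if (dialect == "phylip") {
    hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
      stop2("pa_parse_error", "header must be two integers: 'ntaxa nfamilies'")
    }
    ntax <- as.integer(hdr[1L]); nfam <- as.integer(hdr[2L])
    body <- lines[-1L]
    if (length(body) != ntax) {
      stop2("pa_parse_error", "header declares %d taxa but %d rows found",
            ntax, length(body))
    }
    nm <- character(ntax)
    vals <- matrix(0L, ntax, nfam)
    for (i in seq_len(ntax)) {
      ln <- trimws(body[i])
      nm[i] <- sub("\\s.*$", "", ln)
      data <- gsub("\\s+", "", substring(ln, nchar(nm[i]) + 1L))
      if (nfam == 0L && !nzchar(data)) next
      ch <- strsplit(data, "", fixed = TRUE)[[1L]]
      if (length(ch) != nfam) {
        stop2("pa_parse_error",
              "row '%s' has %d characters, expected %d", nm[i],
              length(ch), nfam)
      }
      bad <- !ch %in% c("0", "1")
      if (any(bad)) {
        stop2("pa_nonbinary_error",
              "row '%s' contains non-binary character '%s'", nm[i],
              ch[which(bad)[1L]])
      }
      vals[i, ] <- as.integer(ch)
    }
    if (anyDuplicated(nm)) {
      stop2("pa_duplicate_error", "duplicate taxon name '%s'",
            nm[duplicated(nm)][1L])
    }
    pa_matrix(vals, taxon_ids = nm)
  } else {
    con <- textConnection(lines)
    on.exit(close(con))
    df <- utils::read.delim(con, check.names = FALSE,
                            colClasses = "character")
    nm <- df[[1L]]
    if (anyDuplicated(nm)) {
      stop2("pa_duplicate_error", "duplicate taxon name '%s'",
            nm[duplicated(nm)][1L])
    }
    vals <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.integer(vals), nrow(vals), ncol(vals)))
    if (anyNA(num) || !all(num %in% 0:1)) {
      stop2("pa_nonbinary_error", "table contains non-binary entries")
    }
    pa_matrix(num, taxon_ids = nm,
              family_ids = colnames(df)[-1L])
  }
}

#' Write a presence/absence matrix
#'
#' Inverse of [read_presence_absence()]: the output re-reads to an equal
#' matrix (taxon order, family ids and values preserved; the phylip dialect
#' does not carry family ids, which re-read as synthesized ids).
#'
#' @param matrix a [pa_matrix].
#' @param path file path or connection; if `NULL`, the text is returned.
#' @inheritParams read_presence_absence
#' @return the text, invisibly when written to `path`.
#' @export
write_presence_absence <- function(matrix, path = NULL,
                                   dialect = c("phylip", "table")) {
  dialect <- match.arg(dialect)
  if (dialect == "phylip") {
    rows <- paste(rownames(matrix),
                  apply(matrix, 1L, paste0, collapse = ""))
    if (ncol(matrix) == 0L) rows <- rownames(matrix)
    txt <- c(paste(nrow(matrix), ncol(matrix)), rows)
  } else {
    txt <- c(paste(c("taxon", colnames(matrix)), collapse = "\t"),
             vapply(seq_len(nrow(matrix)), function(i) {
               paste(c(rownames(matrix)[i], matrix[i, ]), collapse = "\t")
             }, character(1L)))
  }
  if (is.null(path)) return(paste0(paste(txt, collapse = "\n"), "\n"))
  writeLines(txt, path)
  invisible(paste0(paste(txt, collapse = "\n"), "\n"))
}

#' Read a parasite taxon list
#'
#' Plain text, one taxon id per line; blank lines and `#` comments ignored.
#'
#' @param source file path; or character vector when `text = TRUE`.
#' @param text logical; if `TRUE`, `source` is the literal content.
#' @return character vector of taxon ids.
#' @export
read_parasite_list <- function(source, text = FALSE) {
  lines <- if (text) unlist(strsplit(source, "\n", fixed = TRUE))
           else readLines(source, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Annotate taxa as parasites/non-parasites
#'
#' @param matrix a [pa_matrix].
#' @param parasites character vector of parasite taxon ids (must all occur
#'   in the matrix).
#' @return named logical vector over all taxa of `matrix` (`TRUE` =
#'   intracellular parasite/endosymbiont).
#' @export
taxon_annotation <- function(matrix, parasites) {
  unknown <- setdiff(parasites, rownames(matrix))
  if (length(unknown)) {
    stop2("pa_taxa_error", "unknown parasite taxa: %s",
          paste(unknown, collapse = ", "))
  }
  stats::setNames(rownames(matrix) %in% parasites, rownames(matrix))
}

#' Bootstrap-resample gene families
#'
#' Samples columns (gene families) with replacement. Category labels, when
#' supplied, travel with the resampled columns, i.e. assignments are treated
#' as fixed under the bootstrap. Resampled family ids are made unique by
#' suffixing `".b<k>"`.
#'
#' @param matrix a [pa_matrix] with at least one family.
#' @param labels optional named vector (names = family ids) of category
#'   labels.
#' @param seed integer seed; identical seeds give identical output.
#' @param stratified logical; if `TRUE`, resample within each label stratum
#'   (keeping stratum sizes fixed) instead of simple resampling.
#' @return list with elements `matrix` (a [pa_matrix]) and `labels` (the
#'   resampled labels, or `NULL`).
#' @export
bootstrap_resample <- function(matrix, labels = NULL, seed,
                               stratified = FALSE) {
  g <- ncol(matrix)
  if (g == 0L) stop2("pa_empty_error", "cannot resample an empty matrix")
  if (!is.null(labels)) labels <- labels[colnames(matrix)]
  idx <- with_seed(seed, {
    if (stratified && !is.null(labels)) {
      unlist(lapply(split(seq_len(g), labels), function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
    } else {
      sample.int(g, g, replace = TRUE)
    }
  })
  out <- matrix[, idx, drop = FALSE]
  ids <- make.unique(colnames(matrix)[idx], sep = ".b")
  colnames(out) <- ids
  lab <- if (is.null(labels)) NULL else stats::setNames(labels[idx], ids)
  list(matrix = pa_matrix(out), labels = lab)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
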