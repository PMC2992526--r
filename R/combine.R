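#' Combine conditioned distance matrices by inverse-variance weighting
#'
#' Pools the per-conditioning-genome logdet estimates for each taxon pair:
#' `D(x,y) = sum_c d_c(x,y)/v_c(x,y) / sum_c 1/v_c(x,y)` over conditioning
#' genomes `c` not in `{x, y}` with existing distances, and
#' `V(x,y) = 1 / sum_c 1/v_c(x,y)`. Distance matrices are thus weighted by
#' the inverse of their variances to account for differences in
#' reliability.
#'
#' @param set list of `cond_dist` objects (from
#'   [conditioned_distance_set()]), or a single one.
#' @param taxa optional full taxon set; defaults to the union over `set`.
#' @return object of class `combined_dist`: list with `taxa`, `D`, `V`,
#'   `contributors` (number of conditioning genomes per pair).
#' @export
combine_matrices <- function(set, taxa = NULL) {
  if (inherits(set, "cond_dist")) set <- list(set)
  if (length(set) < 1L) stop2("cld_combine_error", "need >= 1 matrix")
  if (is.null(taxa)) {
    taxa <- sort(unique(unlist(lapply(set, `[[`, "taxa"))))
  }
  p <- length(taxa)
  SW <- base::matrix(0, p, p, dimnames = list(taxa, taxa))  # sum d/v
  W <- SW                                                   # sum 1/v
  K <- base::matrix(0L, p, p, dimnames = list(taxa, taxa))
  for (m in set) {
    ix <- match(m$taxa, taxa)
    d <- m$D; v <- m$V
    use <- is.finite(d) & is.finite(v) & v > 0
    diag(use) <- FALSE
    w <- base::matrix(0, nrow(d), ncol(d))
    w[use] <- 1 / v[use]
    SW[ix, ix] <- SW[ix, ix] + ifelse(use, d, 0) * w
    W[ix, ix] <- W[ix, ix] + w
    K[ix, ix] <- K[ix, ix] + use
  }
  off <- upper.tri(W)
  if (any(W[off] == 0)) {
    bad <- which(W == 0 & off, arr.ind = TRUE)[1L, ]
    stop2("cld_combine_error",
          "no conditioning genome contributes to pair (%s, %s)",
          taxa[bad[1L]], taxa[bad[2L]])
  }
  D <- SW / W
  V <- 1 / W
  diag(D) <- 0; diag(V) <- 0
  structure(list(taxa = taxa, D = D, V = V, contributors = K),
            class = "combined_dist")
}

#' @export
print.combined_dist <- function(x, ...) {
  cat(sprintf("Combined distance matrix: %d taxa\n", length(x$taxa)))
  k <- x$contributors[upper.tri(x$contributors)]
  cat(sprintf("  contributors per pair: %d-%d (median %g)\n",
              min(k), max(k), stats::median(k)))
  invisible(x)
}

#' Write a square distance matrix in PHYLIP format
#'
#' @param D square matrix with taxon dimnames.
#' @param path output path; if `NULL` the text is returned.
#' @export
write_phylip_distances <- function(D, path = NULL) {
  txt <- c(sprintf("%5d", nrow(D)),
           vapply(seq_len(nrow(D)), function(i) {
             paste(c(formatC(rownames(D)[i], width = -10),
                     sprintf("%.6f", D[i, ])), collapse = "  ")
           }, character(1L)))
  if (is.null(path)) return(paste0(paste(txt, collapse = "\n"), "\n"))
  writeLines(txt, path)
  invisible(paste0(paste(txt, collapse = "\n"), "\n"))
}
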