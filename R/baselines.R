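#' SHOT gene-content distance matrix
#'
#' Shared-ortholog distance that ignores shared absences:
#' `d(x, y) = -ln( shared(x, y) / min(size(x), size(y)) )` with `size` the
#' number of families present in a genome. Consequently the distance is 0
#' whenever one genome's present set is a subset of the other's. Pairs with
#' no shared family are capped at `d_max` with a warning.
#'
#' @param matrix a [pa_matrix]; every taxon must have >= 1 present family.
#' @param d_max cap for zero-overlap pairs (default 10).
#' @return a `combined_dist` with `D` only (`V` is `NULL`: SHOT carries no
#'   variance model).
#' @export
shot_distance_matrix <- function(matrix, d_max = 10) {
  sizes <- rowSums(matrix)
  if (any(sizes == 0L)) {
    stop2("shot_empty_error", "taxon '%s' has an empty genome",
          rownames(matrix)[sizes == 0L][1L])
  }
  shared <- tcrossprod(unclass(matrix))
  mins <- outer(sizes, sizes, pmin)
  D <- -log(shared / mins)
  if (any(is.infinite(D))) {
    warning(sprintf("%d pair(s) share no family; distance capped at %g",
                    sum(is.infinite(D[upper.tri(D)])), d_max))
    D[is.infinite(D)] <- d_max
  }
  diag(D) <- 0
  structure(list(taxa = rownames(matrix), D = D, V = NULL,
                 contributors = NULL),
            class = "combined_dist")
}

#' Chi-squared test of association between two category assignments
#'
#' Pearson chi-squared on a 2x2 contingency table, with Yates continuity
#' correction by default, against the null of no association; p-value from
#' the chi-squared distribution with 1 df.
#'
#' @param table 2x2 matrix of non-negative counts (rows = model A
#'   categories, columns = model B categories).
#' @param correction `"yates"` (default) or `"none"`.
#' @return list with `statistic`, `df` (= 1), `p_value`, `correction`.
#' @export
chi2_association <- function(table, correction = c("yates", "none")) {
  correction <- match.arg(correction)
  table <- as.matrix(table)
  if (!all(dim(table) == 2L) || any(table < 0)) {
    stop2("chi2_error", "a 2x2 matrix of non-negative counts is required")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop2("chi2_error", "zero marginal: association is undefined")
  }
  ht <- stats::chisq.test(table, correct = correction == "yates")
  list(statistic = unname(ht$statistic), df = 1L,
       p_value = unname(ht$p.value), correction = correction)
}

#' Cross-tabulate two category assignments
#'
#' @param assignA,assignB named character vectors over the same family set
#'   (e.g. from [assign_categories()]).
#' @return 2x2 (or `levels A` x `levels B`) contingency matrix of class
#'   `table`, rows = categories of `assignA`.
#' @export
assignment_table <- function(assignA, assignB) {
  if (!setequal(names(assignA), names(assignB))) {
    stop2("chi2_error", "assignments cover different family sets")
  }
  table(A = assignA, B = assignB[names(assignA)])
}
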