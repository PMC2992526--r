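#' Variance-weighted BIONJ tree estimation
#'
#' Neighbor-joining agglomeration with the BIONJ reduction step driven by
#' externally supplied distance variances (rather than BIONJ's internal
#' variance model), so that the per-pair reliabilities estimated by the
#' conditioned logdet machinery propagate into the tree.
#'
#' At each step with `r` active nodes the pair minimizing
#' `S_ij = (r-2) D_ij - R_i - R_j` (with `R_i = sum_k D_ik`) is joined;
#' branch lengths are `b_iu = D_ij/2 + (R_i - R_j)/(2(r-2))`. The reduction
#' weight is `w = 1/2 + [sum_{k != i,j} (V_jk - V_ik)] / (2(r-2) V_ij)`,
#' clamped to \[0, 1\] (`w = 1/2` when `V_ij = 0`), giving
#' `D_uk = w (D_ik - b_iu) + (1-w)(D_jk - b_ju)` and
#' `V_uk = w V_ik + (1-w) V_jk - w(1-w) V_ij` (floored at 1e-12).
#' Ties in `S` are broken lexicographically on node names (an internal node
#' is named after the alphabetically first leaf of its subtree), so trees
#' are deterministic. Terminates at three nodes with the closed-form
#' three-point branch lengths.
#'
#' @param D complete symmetric distance matrix with zero diagonal and taxon
#'   dimnames, or a `combined_dist`.
#' @param V symmetric positive matrix of distance variances (ignored when
#'   `D` is a `combined_dist`, which carries its own); `NULL` means equal
#'   variances (plain NJ agglomeration order).
#' @param clamp_negative logical; if `TRUE`, negative branch lengths are
#'   mapped to 0. Default `FALSE` (report lengths as computed).
#' @return an unrooted `phylo`.
#' @export
bionj <- function(D, V = NULL, clamp_negative = FALSE) {
  if (inherits(D, "combined_dist")) {
    V <- D$V
    D <- D$D
  }
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop2("bionj_error", "need at least 3 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", 1:n)
  if (!isSymmetric(unname(D), tol = 1e-8) || any(!is.finite(D)) ||
      any(abs(diag(D)) > 1e-12)) {
    stop2("bionj_error", "D must be complete, symmetric, with zero diagonal")
  }
  if (is.null(V)) V <- base::matrix(1, n, n) - diag(n)
  V <- as.matrix(V)
  taxa <- rownames(D)
  # order active nodes by name once; tie-breaks then follow matrix order
  ord <- order(taxa)
  D <- D[ord, ord]; V <- V[ord, ord]
  names_act <- taxa[ord]
  ids_act <- match(names_act, taxa)        # phylo tip ids
  n_internal <- n - 2L
  edge <- base::matrix(0L, 2L * n - 3L, 2L)
  elen <- numeric(2L * n - 3L)
  ne <- 0L
  next_tmp <- 0L                            # temp internal ids 1..n-2
  tmp_ids <- integer(0)
  add_edge <- function(parent_tmp, child_id, len) {
    ne <<- ne + 1L
    edge[ne, ] <<- c(-parent_tmp, child_id)  # negative = temp internal id
    elen[ne] <<- len
  }
  r <- n
  while (r > 3L) {
    R <- rowSums(D)
    S <- (r - 2) * D - outer(R, R, `+`)
    diag(S) <- Inf
    smin <- min(S)
    cand <- which(S <= smin + 1e-12 & upper.tri(S), arr.ind = TRUE)
    # lexicographic tie-break on (name_i, name_j); rows are in matrix order,
    # which is name order, so the first row-major candidate wins
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    b_iu <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    b_ju <- D[i, j] - b_iu
    next_tmp <- next_tmp + 1L
    add_edge(next_tmp, ids_act[i], b_iu)
    add_edge(next_tmp, ids_act[j], b_ju)
    ks <- setdiff(seq_len(r), c(i, j))
    w <- if (V[i, j] > 0 && r > 3L) {
      0.5 + sum(V[j, ks] - V[i, ks]) / (2 * (r - 2) * V[i, j])
    } else 0.5
    w <- min(max(w, 0), 1)
    Du <- w * (D[i, ks] - b_iu) + (1 - w) * (D[j, ks] - b_ju)
    Vu <- pmax(w * V[i, ks] + (1 - w) * V[j, ks] - w * (1 - w) * V[i, j],
               1e-12)
    keep <- ks
    D <- rbind(cbind(D[keep, keep, drop = FALSE], Du),
               c(Du, 0))
    V <- rbind(cbind(V[keep, keep, drop = FALSE], Vu),
               c(Vu, 0))
    u_name <- min(names_act[c(i, j)])
    names_act <- c(names_act[keep], u_name)
    ids_act <- c(ids_act[keep], -next_tmp)
    # re-sort active nodes by name to keep the tie-break rule simple
    o <- order(names_act)
    D <- D[o, o]; V <- V[o, o]
    names_act <- names_act[o]; ids_act <- ids_act[o]
    dimnames(D) <- list(names_act, names_act)
    dimnames(V) <- dimnames(D)
    r <- r - 1L
  }
  # three-point closed form
  next_tmp <- next_tmp + 1L
  b1 <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  b2 <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
  b3 <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  add_edge(next_tmp, ids_act[1L], b1)
  add_edge(next_tmp, ids_act[2L], b2)
  add_edge(next_tmp, ids_act[3L], b3)
  stopifnot(next_tmp == n_internal, ne == 2L * n - 3L)
  # map temp internal ids to phylo ids: center (last created) -> n+1,
  # temp t -> n+1+t for the others
  map_id <- function(x) {
    ifelse(x > 0L, x,
           ifelse(-x == n_internal, n + 1L, n + 1L + (-x)))
  }
  edge <- cbind(map_id(edge[, 1L]), map_id(edge[, 2L]))
  if (clamp_negative) elen <- pmax(elen, 0)
  tr <- structure(list(edge = edge, edge.length = elen, tip.label = taxa,
                       Nnode = n_internal), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}
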