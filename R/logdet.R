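#' Conditioned 2x2 joint counts for a taxon pair
#'
#' Restricts the matrix to the families present in the conditioning genome
#' `c` and cross-tabulates the states of `x` and `y` over those families.
#' State order is \[present, absent\]: `N[1,1]` counts families present in
#' both, `N[1,2]` present in `x` and absent in `y`, and so on. The total
#' `n = sum(N)` equals the conditioning genome size.
#'
#' @param matrix a [pa_matrix].
#' @param c,x,y distinct taxon ids of `matrix`; `c` is the conditioning
#'   genome.
#' @return object of class `cond_counts`: list with `N` (2x2 integer
#'   matrix), `n`, `conditioning`, `pair`.
#' @export
conditioned_counts <- function(matrix, c, x, y) {
  ids <- rownames(matrix)
  if (!all(c(c, x, y) %in% ids)) {
    stop2("cld_taxa_error", "c, x, y must be taxa of the matrix")
  }
  if (c == x || c == y || x == y) {
    stop2("cld_taxa_error", "c, x, y must be distinct taxa")
  }
  cols <- matrix[c, ] == 1L
  n <- sum(cols)
  if (n == 0L) stop2("cld_empty_error", "conditioning genome '%s' is empty", c)
  xs <- matrix[x, cols]
  ys <- matrix[y, cols]
  N <- base::matrix(c(sum(xs & ys), sum(!xs & ys),
                      sum(xs & !ys), sum(!xs & !ys)), 2L, 2L)
  dimnames(N) <- list(x = c("present", "absent"),
                      y = c("present", "absent"))
  structure(list(N = N, n = n, conditioning = c, pair = c(x, y)),
            class = "cond_counts")
}

#' @export
print.cond_counts <- function(x, ...) {
  cat(sprintf("Conditioned counts: pair (%s, %s) | conditioning genome %s (n = %d)\n",
              x$pair[1L], x$pair[2L], x$conditioning, x$n))
  print(x$N)
  invisible(x)
}

# Core logdet + delta-method variance from a 2x2 joint frequency matrix F
# (sums to 1) and effective sample size n. Returns c(d, v) or c(NA, NA) when
# the distance does not exist (zero marginal or det <= 0).
logdet_from_freq <- function(F, n) {
  r <- rowSums(F); s <- colSums(F)
  det <- F[1L, 1L] * F[2L, 2L] - F[1L, 2L] * F[2L, 1L]
  if (any(r <= 0) || any(s <= 0) || det <= 0) return(c(NA_real_, NA_real_))
  d <- -0.5 * (log(det) - 0.5 * (log(r[1L]) + log(r[2L]) +
                                 log(s[1L]) + log(s[2L])))
  # g_ij = dd/dF_ij = -1/2 [ (F^-1)_ji - 1/2 (1/r_i + 1/s_j) ]
  Finv_t <- base::matrix(c(F[2L, 2L], F[1L, 2L] * -1,
                           F[2L, 1L] * -1, F[1L, 1L]), 2L, 2L) / det
  # Finv_t[i,j] = (F^-1)_ji
  g <- -0.5 * (Finv_t - 0.5 * (outer(1 / r, 1 / s, `+`)))
  m1 <- sum(F * g)
  v <- (sum(F * g^2) - m1^2) / n
  c(as.numeric(d), as.numeric(v))
}

#' Logdet (paralinear) distance from conditioned counts
#'
#' Two-state logdet with delta-method variance. With `F = N/n`, row
#' marginals `r` and column marginals `s`,
#' `d = -1/2 [ ln det F - 1/2 (ln r1 + ln r2 + ln s1 + ln s2) ]`.
#' The distance does not exist when any marginal is zero or `det N <= 0`;
#' degeneracy is reported via `exists = FALSE`, never as an error.
#'
#' @param counts a `cond_counts` (or a list with numeric `N` and `n`, e.g.
#'   the output of [repair_pseudocount()]).
#' @return object of class `pair_distance`: list with `distance`,
#'   `variance`, `exists`, `repair`.
#' @export
logdet_distance <- function(counts) {
  F <- counts$N / counts$n
  dv <- logdet_from_freq(F, counts$n)
  structure(list(distance = dv[1L], variance = dv[2L],
                 exists = !is.na(dv[1L]),
                 repair = if (is.null(counts$repair)) "none" else counts$repair),
            class = "pair_distance")
}

#' @export
print.pair_distance <- function(x, ...) {
  if (x$exists) {
    cat(sprintf("logdet distance %.6g (variance %.3g, repair = %s)\n",
                x$distance, x$variance, x$repair))
  } else {
    cat("non-existent logdet distance\n")
  }
  invisible(x)
}

#' Pseudocount repair of degenerate counts
#'
#' Adds `beta` to every cell of the 2x2 table (effective total `n + 4*beta`),
#' so that downstream logdet uses the smoothed frequencies. Removes zero
#' marginals always; can flip a negative determinant only when counts are
#' small.
#'
#' @param counts a `cond_counts`.
#' @param beta positive smoothing constant (default 0.5).
#' @return a `cond_counts`-like list with real-valued `N`, updated `n`, and
#'   `repair = "pseudocount"`.
#' @export
repair_pseudocount <- function(counts, beta = 0.5) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop2("cld_beta_error", "beta must be a positive number")
  }
  out <- counts
  out$N <- counts$N + beta
  out$n <- counts$n + 4 * beta
  out$repair <- "pseudocount"
  class(out) <- "cond_counts"
  out
}

#' Constrained-ML repair of degenerate counts
#'
#' Maximizes the multinomial log-likelihood `sum N_ij log F_ij` over 2x2
#' joint frequency matrices subject to `F >= 0`, `sum F = 1` and
#' `det F >= delta`. If the unconstrained MLE `N/n` is feasible it is
#' returned unchanged; otherwise the optimum lies on the boundary
#' `det F = delta`.
#'
#' For a 2x2 table with unit total, `det F` equals the covariance
#' `F[1,1] - r1*s1` of the two binary margins, so the boundary is
#' parametrized exactly by the marginals `(r1, s1)` with covariance fixed at
#' `delta`; the constrained problem reduces to a 2-D unconstrained
#' maximization and the returned matrix satisfies `det F = delta` to
#' machine precision.
#'
#' @param counts a `cond_counts`.
#' @param delta positive determinant floor (default `1e-6`).
#' @return list with `F` (2x2 frequency matrix), `loglik`, `boundary`
#'   (logical: was the constraint active).
#' @export
repair_constrained_ml <- function(counts, delta = 1e-6) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop2("cld_delta_error", "delta must be a positive number")
  }
  N <- counts$N
  n <- sum(N)
  Fhat <- N / n
  det_hat <- Fhat[1L, 1L] * Fhat[2L, 2L] - Fhat[1L, 2L] * Fhat[2L, 1L]
  if (det_hat >= delta) {
    return(list(F = Fhat, loglik = sum(N[N > 0] * log(Fhat[N > 0])),
                boundary = FALSE))
  }
  # boundary det F = delta: F determined by marginals (r1, s1)
  freq_from <- function(r1, s1) {
    base::matrix(c(r1 * s1 + delta, (1 - r1) * s1 - delta,
                   r1 * (1 - s1) - delta, (1 - r1) * (1 - s1) + delta),
                 2L, 2L)
  }
  # fast path: analytic Newton from the observed marginals (the delta -> 0
  # limit of the boundary problem is the independence MLE)
  nw <- cml_boundary_newton(N, delta)
  if (!is.null(nw)) {
    return(list(F = nw$F, loglik = nw$loglik, boundary = TRUE))
  }
  nll <- function(par) {
    r1 <- stats::plogis(par[1L]); s1 <- stats::plogis(par[2L])
    F <- freq_from(r1, s1)
    if (any(F <= 0)) return(1e10)
    -sum(N * ifelse(N > 0, log(F), 0))
  }
  # starts: observed marginals plus a central restart; the boundary
  # likelihood is smooth and in practice unimodal in (r1, s1)
  r0 <- min(max(rowSums(Fhat)[1L], 0.02), 0.98)
  s0 <- min(max(colSums(Fhat)[1L], 0.02), 0.98)
  starts <- rbind(c(r0, s0), c(0.5, 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(stats::qlogis(starts[i, ]), nll, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 1000L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10) {
    return(list(F = NULL, loglik = -Inf, boundary = TRUE))
  }
  F <- freq_from(stats::plogis(best$par[1L]), stats::plogis(best$par[2L]))
  list(F = F, loglik = -best$value, boundary = TRUE)
}

# Newton solver for the boundary constrained-ML problem: maximize
# sum N_ij log F_ij over F parametrized by marginals (r, s) with
# covariance (= det) fixed at delta. Returns NULL if it fails to converge
# to an interior feasible optimum (caller falls back to Nelder-Mead).
cml_boundary_newton <- function(N, delta) {
  n <- sum(N)
  r <- min(max((N[1L, 1L] + N[1L, 2L]) / n, 1e-3), 1 - 1e-3)
  s <- min(max((N[1L, 1L] + N[2L, 1L]) / n, 1e-3), 1 - 1e-3)
  cells <- function(r, s) {
    c(r * s + delta, r * (1 - s) - delta,
      (1 - r) * s - delta, (1 - r) * (1 - s) + delta)
  }
  # pull the start toward (1/2, 1/2) until all cells are positive
  for (k in 1:60) {
    if (all(cells(r, s) > 0)) break
    r <- 0.5 + 0.9 * (r - 0.5); s <- 0.5 + 0.9 * (s - 0.5)
  }
  if (any(cells(r, s) <= 0)) return(NULL)
  Nv <- c(N[1L, 1L], N[1L, 2L], N[2L, 1L], N[2L, 2L])
  ll <- function(r, s) {
    F <- cells(r, s)
    if (any(F[Nv > 0] <= 0)) return(-Inf)
    sum(Nv[Nv > 0] * log(F[Nv > 0]))
  }
  cur <- ll(r, s)
  for (it in 1:60) {
    F <- cells(r, s)
    dFr <- c(s, 1 - s, -s, -(1 - s))
    dFs <- c(r, -r, 1 - r, -(1 - r))
    d2rs <- c(1, -1, -1, 1)
    gr <- sum(Nv * dFr / F)
    gs <- sum(Nv * dFs / F)
    hrr <- -sum(Nv * (dFr / F)^2)
    hss <- -sum(Nv * (dFs / F)^2)
    hrs <- sum(Nv * (d2rs / F - dFr * dFs / F^2))
    det_h <- hrr * hss - hrs^2
    if (!is.finite(det_h) || det_h <= 0) {
      step <- c(gr, gs) * 1e-3            # gradient ascent fallback
    } else {
      step <- -c(hss * gr - hrs * gs, hrr * gs - hrs * gr) / det_h
    }
    lam <- 1
    repeat {
      r2 <- min(max(r + lam * step[1L], 1e-9), 1 - 1e-9)
      s2 <- min(max(s + lam * step[2L], 1e-9), 1 - 1e-9)
      new <- ll(r2, s2)
      if (new >= cur - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    moved <- abs(r2 - r) + abs(s2 - s)
    r <- r2; s <- s2; cur <- new
    if (abs(gr) + abs(gs) < 1e-9 || moved < 1e-13) break
  }
  if (!is.finite(cur) || abs(gr) + abs(gs) > 1e-3 * (1 + abs(cur))) {
    return(NULL)
  }
  F <- base::matrix(cells(r, s), 2L, 2L)
  if (any(F < 0)) return(NULL)
  list(F = F, loglik = cur)
}

# Vectorized conditioned logdet for one conditioning genome.
# M: 0/1 matrix (taxa other than c) x (families present in c).
# Returns list(D, V, repair_code) over the rows of M; repair codes:
# 0 none, 1 pseudocount, 2 constrained ML, NA non-existent (policy "none").
cld_one_conditioning <- function(M, repair = c("on_failure", "none", "always"),
                                 beta = 0.5, delta = 1e-6) {
  repair <- match.arg(repair)
  r <- nrow(M); n <- ncol(M)
  N11 <- tcrossprod(M)
  rs <- rowSums(M)
  N10 <- outer(rs, rep(1, r)) - N11  # x present, y absent
  N01 <- t(N10)
  N00 <- n - N11 - N10 - N01
  # vectorized logdet + delta-method variance over all pairs at once,
  # from cellwise 2x2 frequency matrices
  dv_all <- function(F11, F10, F01, F00, ntot) {
    det <- F11 * F00 - F10 * F01
    r1 <- F11 + F10; s1 <- F11 + F01
    ok <- det > 0 & r1 > 0 & r1 < 1 & s1 > 0 & s1 < 1
    # degenerate entries are masked by `ok`; keep their logs quiet
    det[!ok] <- NA_real_
    ld <- -0.5 * (log(det) - 0.5 * (log(r1) + log(1 - r1) +
                                    log(s1) + log(1 - s1)))
    g11 <- -0.5 * (F00 / det - 0.5 * (1 / r1 + 1 / s1))
    g10 <- -0.5 * (-F01 / det - 0.5 * (1 / r1 + 1 / (1 - s1)))
    g01 <- -0.5 * (-F10 / det - 0.5 * (1 / (1 - r1) + 1 / s1))
    g00 <- -0.5 * (F11 / det - 0.5 * (1 / (1 - r1) + 1 / (1 - s1)))
    m1 <- F11 * g11 + F10 * g10 + F01 * g01 + F00 * g00
    m2 <- F11 * g11^2 + F10 * g10^2 + F01 * g01^2 + F00 * g00^2
    list(ok = ok, d = ld, v = (m2 - m1^2) / ntot)
  }
  D <- base::matrix(0, r, r, dimnames = list(rownames(M), rownames(M)))
  V <- D
  RC <- base::matrix(0L, r, r, dimnames = dimnames(D))
  sym <- function(M) { M[lower.tri(M)] <- t(M)[lower.tri(M)]; M }
  raw <- dv_all(N11 / n, N10 / n, N01 / n, N00 / n, n)
  ok <- raw$ok
  D[ok] <- raw$d[ok]; V[ok] <- raw$v[ok]
  D <- sym(D); V <- sym(V)   # exact symmetry (transpose-order fp drift)
  always_cml <- repair == "always"
  if (repair == "none") {
    D[!ok] <- NA_real_; V[!ok] <- NA_real_; RC[!ok] <- NA_integer_
    diag(D) <- 0; diag(V) <- 0; diag(RC) <- 0L
    return(list(D = D, V = V, repair_code = RC, n = n))
  }
  fixed <- ok
  if (!always_cml && !all(ok)) {
    # vectorized pseudocount pass over the failing pairs
    n2 <- n + 4 * beta
    sm <- dv_all((N11 + beta) / n2, (N10 + beta) / n2, (N01 + beta) / n2,
                 (N00 + beta) / n2, n2)
    use <- !ok & sm$ok
    D[use] <- sm$d[use]; V[use] <- sm$v[use]; RC[use] <- 1L
    D <- sym(D); V <- sym(V)
    fixed <- ok | use
  }
  need <- which((!fixed | always_cml) & upper.tri(D), arr.ind = TRUE)
  for (k in seq_len(nrow(need))) {
    i <- need[k, 1L]; j <- need[k, 2L]
    cts <- list(N = base::matrix(c(N11[i, j], N01[i, j],
                                   N10[i, j], N00[i, j]), 2L, 2L), n = n)
    cml <- repair_constrained_ml(cts, delta)
    dv <- if (is.null(cml$F)) c(NA_real_, NA_real_)
          else logdet_from_freq(cml$F, n)
    if (is.na(dv[1L])) {
      D[i, j] <- D[j, i] <- NA_real_
      V[i, j] <- V[j, i] <- NA_real_
      RC[i, j] <- RC[j, i] <- NA_integer_
    } else {
      D[i, j] <- D[j, i] <- dv[1L]
      V[i, j] <- V[j, i] <- dv[2L]
      RC[i, j] <- RC[j, i] <- 2L
    }
  }
  diag(D) <- 0; diag(V) <- 0; diag(RC) <- 0L
  list(D = D, V = V, repair_code = RC, n = n)
}

#' Conditioned logdet distance matrices, one per conditioning genome
#'
#' For each taxon `c` in turn, computes the logdet distance (and
#' delta-method variance) between every pair of the remaining taxa from the
#' families present in `c`. Pairs whose raw distance does not exist (zero
#' marginal or non-positive determinant) are repaired according to `repair`:
#' `"on_failure"` (default) first tries pseudocounts, then constrained ML;
#' `"always"` applies constrained ML to every pair (a no-op where `N/n` is
#' already feasible); `"none"` leaves them missing.
#'
#' @param matrix a [pa_matrix] with >= 4 taxa.
#' @param repair repair policy.
#' @param beta pseudocount (see [repair_pseudocount()]).
#' @param delta determinant floor (see [repair_constrained_ml()]).
#' @param taxa optional subset of taxa to use as conditioning genomes
#'   (distances are still computed over all remaining taxa).
#' @return list of `cond_dist` objects, one per conditioning genome with
#'   non-empty gene set; each has `conditioning`, `taxa`, `D`, `V`,
#'   `repair_code`, `n` (conditioning genome size). Empty conditioning
#'   genomes are skipped with a warning.
#' @export
conditioned_distance_set <- function(matrix,
                                     repair = c("on_failure", "none", "always"),
                                     beta = 0.5, delta = 1e-6,
                                     taxa = rownames(matrix)) {
  repair <- match.arg(repair)
  if (nrow(matrix) < 4L) {
    stop2("cld_taxa_error", "need at least 4 taxa")
  }
  out <- list()
  for (cg in taxa) {
    cols <- matrix[cg, ] == 1L
    if (!any(cols)) {
      warning(sprintf("conditioning genome '%s' is empty; skipped", cg))
      next
    }
    M <- unclass(matrix)[setdiff(rownames(matrix), cg), cols, drop = FALSE]
    res <- cld_one_conditioning(M, repair = repair, beta = beta, delta = delta)
    out[[cg]] <- structure(
      list(conditioning = cg, taxa = rownames(M), D = res$D, V = res$V,
           repair_code = res$repair_code, n = res$n),
      class = "cond_dist")
  }
  out
}

#' @export
print.cond_dist <- function(x, ...) {
  cat(sprintf("Conditioned logdet distances | conditioning genome %s (size %d)\n",
              x$conditioning, x$n))
  cat(sprintf("  %d taxa; repaired pairs: %d pseudocount, %d constrained ML, %d missing\n",
              length(x$taxa), sum(x$repair_code == 1L, na.rm = TRUE) / 2L,
              sum(x$repair_code == 2L, na.rm = TRUE) / 2L,
              sum(is.na(x$repair_code)) / 2L))
  invisible(x)
}
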