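#' Gain-loss regime and its transition probabilities
#'
#' A two-state (present/absent) continuous-time chain with gain rate `gain`
#' (absent -> present) and loss rate `loss` (present -> absent) per unit
#' edge length. The equilibrium presence probability is
#' `pi = gain / (gain + loss)`; over an edge of length `t` with rate-class
#' multiplier `m`,
#' `P(absent -> present) = pi (1 - exp(-m (gain+loss) t))` and
#' `P(present -> absent) = (1 - pi)(1 - exp(-m (gain+loss) t))`, diagonals
#' by complement. State order everywhere is \[present, absent\].
#'
#' @param gain,loss non-negative rates, not both zero.
#' @return object of class `gain_loss_regime` (list with `gain`, `loss`,
#'   `pi`, `rate = gain + loss`).
#' @export
gain_loss_regime <- function(gain, loss) {
  if (gain < 0 || loss < 0 || (gain == 0 && loss == 0)) {
    stop2("regime_error", "rates must be >= 0 and not both zero")
  }
  structure(list(gain = gain, loss = loss, pi = gain / (gain + loss),
                 rate = gain + loss), class = "gain_loss_regime")
}

#' @rdname gain_loss_regime
#' @param regime a `gain_loss_regime`.
#' @param t edge length (>= 0).
#' @param m rate-class multiplier (>= 0).
#' @return `transition_matrix`: 2x2 row-stochastic matrix, rows = parent
#'   state, columns = child state, order \[present, absent\].
#' @export
transition_matrix <- function(regime, t, m = 1) {
  e <- exp(-m * regime$rate * t)
  pi <- regime$pi
  base::matrix(c(pi + (1 - pi) * e, pi * (1 - e),
                 (1 - pi) * (1 - e), (1 - pi) + pi * e),
               2L, 2L,
               dimnames = list(c("present", "absent"),
                               c("present", "absent")))
}

#' Discrete gamma rate-class multipliers
#'
#' Equal-probability discretization of a mean-1 gamma distribution by class
#' means (Yang-style), renormalized so the multipliers average exactly 1.
#'
#' @param shape gamma shape parameter (> 0).
#' @param k number of classes (default 4).
#' @return numeric vector of `k` multipliers with mean exactly 1.
#' @export
discrete_gamma_classes <- function(shape, k = 4L) {
  if (shape <= 0) stop2("regime_error", "shape must be positive")
  b <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape, shape)
  # mean over each slice: integral of x f(x) is a Gamma(shape+1, shape) cdf
  cum <- stats::pgamma(b, shape + 1, shape)
  m <- k * diff(cum)
  m / mean(m)
}

#' Parameters of the phylogenetic two-category mixture
#'
#' Two categories of gene families evolve on a rooted reference tree:
#' *essential* families follow one regime everywhere; *non-essential*
#' families follow a background regime except on and below the stems of
#' parasite clans, where rates switch to a parasite regime (typically much
#' faster loss). Each category has four equal-probability discrete gamma
#' rate classes (mean 1). Root state frequencies are the equilibrium of the
#' root regime (the background regime for the non-essential category).
#'
#' @param alpha_N fraction of non-essential families, in (0, 1).
#' @param essential,background,parasite `gain_loss_regime` objects for the
#'   essential category, the non-essential background, and the
#'   non-essential parasite regime.
#' @param shape_E,shape_N gamma shapes of the rate classes per category.
#' @param k number of rate classes (default 4).
#' @param condition_observable logical: condition every component
#'   likelihood on the family being present in at least one genome.
#' @return object of class `phylo_mixture_params`.
#' @export
phylo_mixture_params <- function(alpha_N, essential, background, parasite,
                                 shape_E = 1, shape_N = 1, k = 4L,
                                 condition_observable = FALSE) {
  if (alpha_N <= 0 || alpha_N >= 1) {
    stop2("regime_error", "alpha_N must lie in (0, 1)")
  }
  structure(list(alpha_N = alpha_N, essential = essential,
                 background = background, parasite = parasite,
                 shape_E = shape_E, shape_N = shape_N, k = as.integer(k),
                 mult_E = discrete_gamma_classes(shape_E, k),
                 mult_N = discrete_gamma_classes(shape_N, k),
                 condition_observable = condition_observable),
            class = "phylo_mixture_params")
}

#' @export
print.phylo_mixture_params <- function(x, ...) {
  cat("Phylogenetic gain-loss mixture parameters\n")
  cat(sprintf("  alpha_N = %.4f; %d gamma classes per category (shapes %.3g / %.3g)\n",
              x$alpha_N, x$k, x$shape_E, x$shape_N))
  for (nm in c("essential", "background", "parasite")) {
    r <- x[[nm]]
    cat(sprintf("  %-10s gain %.4g, loss %.4g (equilibrium presence %.3f)\n",
                nm, r$gain, r$loss, r$pi))
  }
  cat(sprintf("  observability conditioning: %s\n",
              if (x$condition_observable) "on" else "off"))
  invisible(x)
}

#' Stems of the maximal parasite clans of a rooted tree
#'
#' Returns the edges at whose basal end the non-essential regime switches
#' to parasite rates: the stem edge of every maximal clan whose descendant
#' leaves are all parasites. The entire stem edge and all edges below it
#' use parasite rates.
#'
#' @param tree a rooted `phylo` whose leaves are all annotated.
#' @param annotation named logical vector over the leaf labels (`TRUE` =
#'   parasite).
#' @return list with `edges` (indices into `tree$edge` of the stems),
#'   `parasite_edges` (logical over edges: child clade all-parasite, i.e.
#'   edges evolving under the parasite regime), and `leaves` (the parasite
#'   leaf set covered).
#' @export
parasite_switch_edges <- function(tree, annotation) {
  if (!ape::is.rooted(tree)) {
    stop2("tree_root_error", "a rooted tree is required")
  }
  flags <- annotation[tree$tip.label]
  if (anyNA(flags)) {
    stop2("mix_annotation_error", "annotation must cover all leaves")
  }
  if (all(flags)) {
    stop2("tree_root_error", "all leaves are parasites; no outgroup exists")
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  all_par <- c(flags, rep(NA, nnode))       # per node: clade all-parasite?
  tr <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    if (is.na(all_par[p])) all_par[p] <- TRUE
    all_par[p] <- all_par[p] && all_par[ch]
  }
  child_flag <- all_par[tree$edge[, 2L]]
  # stem: child clade all-parasite, parent clade not
  par_of <- all_par[tree$edge[, 1L]]
  stems <- which(child_flag & !par_of)
  list(edges = stems, parasite_edges = child_flag,
       leaves = tree$tip.label[flags])
}

# Per-(category, class) pattern log-likelihoods by Felsenstein pruning,
# vectorized over families. X: taxa x families 0/1 matrix with rownames
# matching tree$tip.label. Returns list(loglik = G x 2k matrix with columns
# E1..Ek, N1..Nk; log_p0 = length 2k vector of all-absent pattern
# log-probabilities; combos = data.frame(category, class)).
pattern_logliks <- function(X, tree, params) {
  ntip <- length(tree$tip.label)
  X <- X[tree$tip.label, , drop = FALSE]
  G <- ncol(X)
  sw <- parasite_switch_edges(tree, attr(params, "annotation"))
  tr <- ape::reorder.phylo(tree, "postorder")
  post_edges <- tr$edge
  post_len <- tr$edge.length
  # map parasite flag onto the postorder edge ordering
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  pkey <- paste(post_edges[, 1L], post_edges[, 2L])
  on_par <- sw$parasite_edges[match(pkey, key)]
  combos <- expand.grid(class = seq_len(params$k),
                        category = c("E", "N"),
                        stringsAsFactors = FALSE)[, 2:1]
  out <- base::matrix(NA_real_, G, nrow(combos))
  log_p0 <- numeric(nrow(combos))
  root <- ntip + 1L
  for (ci in seq_len(nrow(combos))) {
    cat_ <- combos$category[ci]
    m <- if (cat_ == "E") params$mult_E[combos$class[ci]]
         else params$mult_N[combos$class[ci]]
    base_reg <- if (cat_ == "E") params$essential else params$background
    # partial likelihoods, log-scaled per node to avoid underflow
    L1 <- base::matrix(1, ntip + tree$Nnode, G)   # state present
    L2 <- L1                                      # state absent
    L1[seq_len(ntip), ] <- X
    L2[seq_len(ntip), ] <- 1 - X
    scale_log <- base::matrix(0, 1L, G)
    seen <- logical(ntip + tree$Nnode)
    for (i in seq_len(nrow(post_edges))) {
      p <- post_edges[i, 1L]; ch <- post_edges[i, 2L]
      reg <- if (cat_ == "N" && on_par[i]) params$parasite else base_reg
      P <- transition_matrix(reg, post_len[i], m)
      a <- P[1L, 1L] * L1[ch, ] + P[1L, 2L] * L2[ch, ]
      b <- P[2L, 1L] * L1[ch, ] + P[2L, 2L] * L2[ch, ]
      if (!seen[p]) {
        L1[p, ] <- a; L2[p, ] <- b; seen[p] <- TRUE
      } else {
        L1[p, ] <- L1[p, ] * a; L2[p, ] <- L2[p, ] * b
      }
      mx <- pmax(L1[p, ], L2[p, ])
      bad <- mx < 1e-280 & mx > 0
      if (any(bad)) {
        L1[p, bad] <- L1[p, bad] / mx[bad]
        L2[p, bad] <- L2[p, bad] / mx[bad]
        scale_log[bad] <- scale_log[bad] + log(mx[bad])
      }
    }
    pi_root <- base_reg$pi
    lik <- pi_root * L1[root, ] + (1 - pi_root) * L2[root, ]
    out[, ci] <- log(lik) + as.numeric(scale_log)
    # all-absent pattern probability for observability conditioning
    p0 <- pattern_prob_all_absent(tr, on_par, cat_, m, base_reg, params)
    log_p0[ci] <- p0
  }
  colnames(out) <- paste0(combos$category, combos$class)
  list(loglik = out, log_p0 = log_p0, combos = combos)
}

# log-probability of the all-absent pattern for one (category, class)
pattern_prob_all_absent <- function(tr, on_par, cat_, m, base_reg, params) {
  ntip <- length(tr$tip.label)
  L1 <- rep(1, ntip + tr$Nnode); L2 <- L1
  L1[seq_len(ntip)] <- 0
  seen <- logical(ntip + tr$Nnode)
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    reg <- if (cat_ == "N" && on_par[i]) params$parasite else base_reg
    P <- transition_matrix(reg, tr$edge.length[i], m)
    a <- P[1L, 1L] * L1[ch] + P[1L, 2L] * L2[ch]
    b <- P[2L, 1L] * L1[ch] + P[2L, 2L] * L2[ch]
    if (!seen[p]) { L1[p] <- a; L2[p] <- b; seen[p] <- TRUE }
    else { L1[p] <- L1[p] * a; L2[p] <- L2[p] * b }
  }
  root <- ntip + 1L
  log(base_reg$pi * L1[root] + (1 - base_reg$pi) * L2[root])
}

#' Log-likelihood of one presence/absence pattern
#'
#' Felsenstein pruning over the two-state gain-loss chain for a single
#' family pattern under one (category, rate class) combination. The root
#' distribution is the equilibrium of the root regime; on and below
#' parasite-clan stems the non-essential category switches to the parasite
#' regime (the essential category never switches).
#'
#' @param pattern named 0/1 vector over all leaf labels.
#' @param tree rooted `phylo` with edge lengths.
#' @param params a [phylo_mixture_params].
#' @param annotation named logical parasite flags over the leaves.
#' @param category `"essential"` or `"non_essential"`.
#' @param class rate class index in `1:params$k`.
#' @return log pattern probability (a number).
#' @export
family_loglik <- function(pattern, tree, params, annotation,
                          category = c("non_essential", "essential"),
                          class = 1L) {
  category <- match.arg(category)
  if (anyNA(pattern[tree$tip.label])) {
    stop2("mix_pattern_error", "pattern must cover all leaves")
  }
  X <- base::matrix(pattern[tree$tip.label], ncol = 1L,
                    dimnames = list(tree$tip.label, "g"))
  attr(params, "annotation") <- annotation
  pl <- pattern_logliks(X, tree, params)
  col <- paste0(if (category == "essential") "E" else "N", class)
  unname(pl$loglik[1L, col])
}

#' Log-likelihood of the phylogenetic mixture
#'
#' `sum_g ln[ alpha_N (1/k) sum_j L(g | N, j)
#'          + (1 - alpha_N) (1/k) sum_j L(g | E, j) ]`,
#' with each component likelihood optionally divided by
#' `1 - P(all absent)` when observability conditioning is on. Duplicate
#' patterns are collapsed before pruning.
#'
#' @param matrix a [pa_matrix] whose taxa match the tree's leaves.
#' @inheritParams family_loglik
#' @return the log-likelihood (a number).
#' @export
mixture_loglik <- function(matrix, tree, params, annotation) {
  if (!setequal(rownames(matrix), tree$tip.label)) {
    stop2("tree_leafset_error", "matrix taxa and tree leaves differ")
  }
  X <- t(unclass(matrix))[, , drop = FALSE]    # families x taxa
  key <- apply(X, 1L, paste0, collapse = "")
  uniq <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[uniq])))
  Xu <- t(X[uniq, , drop = FALSE])             # taxa x unique patterns
  attr(params, "annotation") <- annotation
  pl <- pattern_logliks(Xu, tree, params)
  ll <- pl$loglik
  if (params$condition_observable) {
    ll <- sweep(ll, 2L, log1p(-exp(pl$log_p0)), `-`)
  }
  isN <- pl$combos$category == "N"
  prior <- ifelse(isN, params$alpha_N / params$k,
                  (1 - params$alpha_N) / params$k)
  lw <- sweep(ll, 2L, log(prior), `+`)
  mx <- apply(lw, 1L, max)
  sum(w * (mx + log(rowSums(exp(lw - mx)))))
}

#' Fit the phylogenetic mixture by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) optimization over log gain/loss rates of
#' the three regimes, `logit(alpha_N)` and log gamma shapes, with multiple
#' seeded restarts; edge lengths of the reference tree are held fixed and
#' rates are per unit edge length (no global rescaling parameter, for
#' identifiability). With `fix_params`, optimization is bypassed and the
#' supplied parameters are returned verbatim with their log-likelihood
#' (classification-only mode).
#'
#' @param matrix a [pa_matrix].
#' @param tree rooted reference `phylo` with strictly positive edge
#'   lengths.
#' @param annotation named logical parasite flags over the leaves.
#' @param fix_params optional [phylo_mixture_params]: skip optimization.
#' @param restarts number of seeded starts.
#' @param seed integer seed.
#' @param tol relative convergence tolerance (passed to `optim` as
#'   `factr = tol / .Machine$double.eps`).
#' @param condition_observable passed into the fitted parameters.
#' @param k number of rate classes.
#' @return object of class `phylo_mixture`: list with `params`
#'   (a [phylo_mixture_params]), `loglik`, `converged`, `fixed`.
#' @export
fit_phylo_mixture <- function(matrix, tree, annotation, fix_params = NULL,
                              restarts = 3L, seed = 1L, tol = 1e-6,
                              condition_observable = FALSE, k = 4L) {
  if (any(tree$edge.length <= 0)) {
    stop2("tree_root_error", "tree must have strictly positive edge lengths")
  }
  if (!is.null(fix_params)) {
    ll <- mixture_loglik(matrix, tree, fix_params, annotation)
    return(structure(list(params = fix_params, loglik = ll,
                          converged = TRUE, fixed = TRUE,
                          annotation = annotation),
                     class = "phylo_mixture"))
  }
  unpack <- function(th) {
    phylo_mixture_params(
      alpha_N = stats::plogis(th[1L]),
      essential = gain_loss_regime(exp(th[2L]), exp(th[3L])),
      background = gain_loss_regime(exp(th[4L]), exp(th[5L])),
      parasite = gain_loss_regime(exp(th[6L]), exp(th[7L])),
      shape_E = exp(th[8L]), shape_N = exp(th[9L]), k = k,
      condition_observable = condition_observable)
  }
  negll <- function(th) {
    p <- tryCatch(unpack(th), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    v <- tryCatch(-mixture_loglik(matrix, tree, p, annotation),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- with_seed(seed, {
    lapply(seq_len(max(1L, restarts)), function(i) {
      c(stats::qlogis(stats::runif(1, .3, .95)),
        log(stats::runif(6, .1, 3)),
        log(stats::runif(2, .3, 3)))
    })
  })
  lower <- c(-7, rep(log(1e-4), 6), rep(log(0.05), 2))
  upper <- c(7, rep(log(50), 6), rep(log(50), 2))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 500L,
                                  factr = tol / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e10 &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop2("mix_fit_error", "optimizer failed to find a finite likelihood")
  }
  structure(list(params = unpack(best$par), loglik = -best$value,
                 converged = best$convergence == 0L, fixed = FALSE,
                 annotation = annotation),
            class = "phylo_mixture")
}

#' @export
print.phylo_mixture <- function(x, ...) {
  cat("Phylogenetic gain-loss mixture fit",
      if (x$fixed) "(parameters fixed)" else "", "\n")
  print(x$params)
  cat(sprintf("  log-likelihood %.3f%s\n", x$loglik,
              if (x$converged) "" else " (optimizer did not converge)"))
  invisible(x)
}

#' @export
coef.phylo_mixture <- function(object, ...) {
  p <- object$params
  c(alpha_N = p$alpha_N,
    gain_E = p$essential$gain, loss_E = p$essential$loss,
    gain_N = p$background$gain, loss_N = p$background$loss,
    gain_P = p$parasite$gain, loss_P = p$parasite$loss,
    shape_E = p$shape_E, shape_N = p$shape_N)
}

#' @export
logLik.phylo_mixture <- function(object, ...) {
  structure(object$loglik, df = 9L, class = "logLik")
}

#' Empirical-Bayes assignment to (category, rate class) combinations
#'
#' Per family, the posterior over the `2k` combinations is proportional to
#' `prior(category, class) * likelihood`; the assignment is the posterior
#' argmax. Combinations holding fewer than `min_combo` assigned families
#' are marked discarded (their distance estimates would have very high
#' variance).
#'
#' @param matrix a [pa_matrix].
#' @param tree rooted reference `phylo`.
#' @param params a [phylo_mixture_params] (e.g. generating values, or from
#'   a fit).
#' @param annotation named logical parasite flags.
#' @param min_combo minimum families for a combination to be retained
#'   (default 50).
#' @return object of class `combo_assignment`: list with `assignment`
#'   (named character vector, values like `"N3"`), `posterior` (families x
#'   combinations matrix, rows sum to 1), `retained`, `discarded`,
#'   `combos`.
#' @export
classify_families <- function(matrix, tree, params, annotation,
                              min_combo = 50L) {
  X <- t(unclass(matrix))
  key <- apply(X, 1L, paste0, collapse = "")
  uniq <- !duplicated(key)
  Xu <- t(X[uniq, , drop = FALSE])
  attr(params, "annotation") <- annotation
  pl <- pattern_logliks(Xu, tree, params)
  ll <- pl$loglik
  if (params$condition_observable) {
    ll <- sweep(ll, 2L, log1p(-exp(pl$log_p0)), `-`)
  }
  isN <- pl$combos$category == "N"
  prior <- ifelse(isN, params$alpha_N / params$k,
                  (1 - params$alpha_N) / params$k)
  lp <- sweep(ll, 2L, log(prior), `+`)
  mx <- apply(lp, 1L, max)
  post_u <- exp(lp - mx)
  post_u <- post_u / rowSums(post_u)
  idx <- match(key, key[uniq])
  post <- post_u[idx, , drop = FALSE]
  rownames(post) <- colnames(matrix)
  hard <- colnames(ll)[max.col(post, ties.method = "first")]
  names(hard) <- colnames(matrix)
  sizes <- table(factor(hard, levels = colnames(ll)))
  retained <- names(sizes)[sizes >= min_combo]
  if (length(retained) == 0L) {
    stop2("mix_combo_error",
          "no combination holds >= %s families; nothing retained",
          format(min_combo))
  }
  structure(list(assignment = hard, posterior = post, retained = retained,
                 discarded = setdiff(colnames(ll), retained),
                 combos = pl$combos, min_combo = min_combo),
            class = "combo_assignment")
}

#' @export
print.combo_assignment <- function(x, ...) {
  cat("Empirical-Bayes (category, rate class) assignment\n")
  print(table(x$assignment))
  cat(sprintf("  retained: %s\n", paste(x$retained, collapse = ", ")))
  if (length(x$discarded)) {
    cat(sprintf("  discarded (< %d families): %s\n", x$min_combo,
                paste(x$discarded, collapse = ", ")))
  }
  invisible(x)
}

#' Per-combination conditioned logdet distances, combined
#'
#' [partitioned_distances()] over the retained (category, rate class)
#' combinations of a [classify_families()] result.
#'
#' @param matrix a [pa_matrix].
#' @param assignment a `combo_assignment`.
#' @inheritParams partitioned_distances
#' @return a `combined_dist`.
#' @export
combo_partitioned_distances <- function(matrix, assignment,
                                        weights = c("inverse_variance",
                                                    "proportions"),
                                        repair = "on_failure", beta = 0.5,
                                        delta = 1e-6) {
  weights <- match.arg(weights)
  lab <- assignment$assignment
  keep <- names(lab)[lab %in% assignment$retained]
  partitioned_distances(matrix[, keep, drop = FALSE], lab[keep],
                        weights = weights, repair = repair, beta = beta,
                        delta = delta)
}
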