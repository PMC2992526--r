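# Shared in-code fixtures for the test suite; everything is generated at
# test time under explicit seeds.

# Binomial-mixture generator: nP parasite + nN non-parasite genomes,
# G families, non-essential fraction alpha with presence probabilities
# (pp in parasites, pq elsewhere), essential presence pr everywhere.
gen_binomial_mixture <- function(G = 5000, nP = 12, nN = 38, alpha = 0.75,
                                 pp = 0.02, pq = 0.16, pr = 0.69, seed = 5) {
  set.seed(seed)
  ne <- stats::runif(G) < alpha
  M <- matrix(0L, nP + nN, G)
  par_rows <- seq_len(nP)
  M[par_rows, ne] <- rbinom(nP * sum(ne), 1, pp)
  M[-par_rows, ne] <- rbinom(nN * sum(ne), 1, pq)
  M[, !ne] <- rbinom((nP + nN) * sum(!ne), 1, pr)
  rownames(M) <- c(sprintf("P%02d", seq_len(nP)), sprintf("N%02d", seq_len(nN)))
  list(matrix = pa_matrix(M),
       truth = ifelse(ne, "non_essential", "essential"),
       annotation = stats::setNames(grepl("^P", rownames(M)), rownames(M)))
}

# Homogeneous (no parasite shift, single rate class) gain-loss parameters.
homogeneous_params <- function(gain = 1.2, loss = 0.8) {
  phylo_mixture_params(alpha_N = 0.5,
                       essential = gain_loss_regime(gain, loss),
                       background = gain_loss_regime(gain, loss),
                       parasite = gain_loss_regime(gain, loss),
                       shape_E = 1, shape_N = 1, k = 1L)
}

# Small heterogeneous parameter set for pruning / classification tests.
toy_phylo_params <- function(condition_observable = FALSE) {
  phylo_mixture_params(alpha_N = 0.6,
                       essential = gain_loss_regime(1.2, 0.5),
                       background = gain_loss_regime(0.9, 0.7),
                       parasite = gain_loss_regime(0.2, 1.9),
                       shape_E = 0.7, shape_N = 1.4, k = 4L,
                       condition_observable = condition_observable)
}

# Annotation helper for trees whose parasite leaves start with "P".
p_annotation <- function(tree) {
  stats::setNames(grepl("^P", tree$tip.label), tree$tip.label)
}

# Brute-force pattern log-likelihood by enumerating ancestral states.
brute_family_loglik <- function(pattern, tree, params, annotation,
                                category, class) {
  sw <- parasite_switch_edges(tree, annotation)
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  cat_ <- if (category == "essential") "E" else "N"
  m <- if (cat_ == "E") params$mult_E[class] else params$mult_N[class]
  breg <- if (cat_ == "E") params$essential else params$background
  tot <- 0
  for (code in 0:(2^nn - 1)) {
    st <- c(pattern[tree$tip.label], as.integer(intToBits(code))[seq_len(nn)])
    pr <- if (st[ntip + 1L] == 1) breg$pi else 1 - breg$pi
    for (e in seq_len(nrow(tree$edge))) {
      reg <- if (cat_ == "N" && sw$parasite_edges[e]) params$parasite else breg
      P <- transition_matrix(reg, tree$edge.length[e], m)
      i <- if (st[tree$edge[e, 1L]] == 1) 1L else 2L
      j <- if (st[tree$edge[e, 2L]] == 1) 1L else 2L
      pr <- pr * P[i, j]
    }
    tot <- tot + pr
  }
  log(tot)
}

# Grid oracle for the boundary constrained-ML problem: best log-likelihood
# over a K x K grid of feasible marginal pairs with det fixed at delta.
grid_constrained_ml <- function(N, delta = 1e-6, K = 200) {
  Nv <- c(N[1, 1], N[1, 2], N[2, 1], N[2, 2])
  term <- function(nv, F) {
    if (nv == 0) return(ifelse(F >= 0, 0, -Inf))
    ifelse(F > 0, nv * log(F), -Inf)
  }
  best <- -Inf
  gr <- seq(0.001, 0.999, length.out = K)
  for (a in gr) {
    ll <- term(Nv[1], a * gr + delta) +
      term(Nv[2], a * (1 - gr) - delta) +
      term(Nv[3], (1 - a) * gr - delta) +
      term(Nv[4], (1 - a) * (1 - gr) + delta)
    best <- max(best, max(ll))
  }
  best
}

# Four-point condition residual of a 4-taxon distance matrix.
four_point_residual <- function(D) {
  s1 <- D[1, 2] + D[3, 4]
  s2 <- D[1, 3] + D[2, 4]
  s3 <- D[1, 4] + D[2, 3]
  ss <- sort(c(s1, s2, s3))
  ss[3] - ss[2]
}
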