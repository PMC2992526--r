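test_that("transition matrices are stochastic and satisfy Chapman-Kolmogorov", {
  set.seed(2)
  for (i in 1:20) {
    reg <- gain_loss_regime(runif(1, 0.01, 3), runif(1, 0.01, 3))
    m <- runif(1, 0.1, 3)
    t1 <- runif(1, 0, 2); t2 <- runif(1, 0, 2)
    P1 <- transition_matrix(reg, t1, m)
    P2 <- transition_matrix(reg, t2, m)
    expect_equal(unname(rowSums(P1)), c(1, 1), tolerance = 1e-12)
    expect_true(all(P1 >= 0 & P1 <= 1))
    expect_equal(unname(P1 %*% P2),
                 unname(transition_matrix(reg, t1 + t2, m)),
                 tolerance = 1e-10)
  }
  expect_error(gain_loss_regime(0, 0), class = "regime_error")
})

test_that("discrete gamma multipliers are equal-probability class means with mean 1", {
  for (shape in c(0.3, 1, 5)) {
    m <- discrete_gamma_classes(shape)
    expect_length(m, 4L)
    expect_equal(mean(m), 1, tolerance = 1e-9)
    expect_true(all(diff(m) > 0))
  }
  # strong rate variation spreads classes; weak variation concentrates them
  expect_gt(diff(range(discrete_gamma_classes(0.3))),
            diff(range(discrete_gamma_classes(5))))
  expect_equal(discrete_gamma_classes(1, k = 1L), 1)
})

test_that("parasite switch edges are the stems of maximal parasite clans", {
  tr <- read_newick("((P1:1,P2:1):1,(N1:1,N2:1):1);", text = TRUE)
  sw <- parasite_switch_edges(tr, p_annotation(tr))
  expect_length(sw$edges, 1L)
  # the stem's child clade is exactly {P1, P2}
  expect_setequal(sw$leaves, c("P1", "P2"))
  expect_equal(sum(sw$parasite_edges), 3L)  # stem + two pendants
  # dispersed parasites: one stem per clan, incl. a single-leaf clan
  tr4 <- read_newick(
    "(((P1:1,P2:1):1,N1:1):1,((P3:1,N2:1):1,(P4:1,N3:1):1):1);", text = TRUE)
  sw4 <- parasite_switch_edges(tr4, p_annotation(tr4))
  expect_length(sw4$edges, 3L)              # {P1,P2}, {P3}, {P4}
  expect_setequal(sw4$leaves, c("P1", "P2", "P3", "P4"))
  allp <- read_newick("((P1:1,P2:1):1,P3:1);", text = TRUE)
  expect_error(parasite_switch_edges(allp, p_annotation(allp)),
               class = "tree_root_error")
})

test_that("pruning equals exhaustive enumeration on small random trees", {
  set.seed(100)
  for (case in 1:12) {
    ntip <- sample(3:6, 1)
    tr <- ape::rtree(ntip)
    tr$tip.label <- c("P1", paste0("N", seq_len(ntip - 1)))[sample.int(ntip)]
    ann <- p_annotation(tr)
    params <- phylo_mixture_params(
      alpha_N = runif(1, 0.2, 0.8),
      essential = gain_loss_regime(runif(1, 0.2, 2), runif(1, 0.2, 2)),
      background = gain_loss_regime(runif(1, 0.2, 2), runif(1, 0.2, 2)),
      parasite = gain_loss_regime(runif(1, 0.05, 0.5), runif(1, 1, 3)),
      shape_E = runif(1, 0.4, 2), shape_N = runif(1, 0.4, 2))
    pat <- stats::setNames(rbinom(ntip, 1, 0.5), tr$tip.label)
    category <- sample(c("essential", "non_essential"), 1)
    cls <- sample.int(4, 1)
    expect_equal(
      family_loglik(pat, tr, params, ann, category, cls),
      brute_family_loglik(pat, tr, params, ann, category, cls),
      tolerance = 1e-10)
  }
})

test_that("pattern probabilities sum to one over all patterns", {
  tr <- ape::rtree(5)
  tr$tip.label <- c("P1", "P2", "N1", "N2", "N3")
  ann <- p_annotation(tr)
  params <- toy_phylo_params()
  for (spec_ in list(c("essential", 1), c("non_essential", 3))) {
    tot <- 0
    for (code in 0:31) {
      pat <- stats::setNames(as.integer(intToBits(code))[1:5], tr$tip.label)
      tot <- tot + exp(family_loglik(pat, tr, params, ann, spec_[1],
                                     as.integer(spec_[2])))
    }
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("mixture log-likelihood reduces correctly at boundaries and dedups", {
  set.seed(6)
  tr <- ape::rtree(5)
  tr$tip.label <- c("P1", "P2", "N1", "N2", "N3")
  ann <- p_annotation(tr)
  params <- toy_phylo_params()
  X <- pa_matrix(matrix(rbinom(5 * 30, 1, 0.5), 5, 30,
                        dimnames = list(tr$tip.label, NULL)))
  # direct per-family summation oracle
  direct <- 0
  for (g in seq_len(ncol(X))) {
    pat <- stats::setNames(unclass(X)[, g], rownames(X))
    lN <- vapply(1:4, function(j)
      exp(family_loglik(pat, tr, params, ann, "non_essential", j)),
      numeric(1))
    lE <- vapply(1:4, function(j)
      exp(family_loglik(pat, tr, params, ann, "essential", j)), numeric(1))
    direct <- direct + log(params$alpha_N * mean(lN) +
                             (1 - params$alpha_N) * mean(lE))
  }
  expect_equal(mixture_loglik(X, tr, params, ann), direct, tolerance = 1e-8)
  # duplicated families contribute additively
  X2 <- pa_matrix(cbind(unclass(X), unclass(X)),
                  family_ids = sprintf("g%03d", 1:60))
  expect_equal(mixture_loglik(X2, tr, params, ann),
               2 * mixture_loglik(X, tr, params, ann), tolerance = 1e-8)
  # likelihood is invariant to taxon and family order
  perm <- X[c(3, 1, 5, 2, 4), sample.int(30)]
  expect_equal(mixture_loglik(perm, tr, params, ann),
               mixture_loglik(X, tr, params, ann), tolerance = 1e-10)
  # alpha_N -> 0 reduces to the essential-only likelihood
  p0 <- toy_phylo_params()
  p0$alpha_N <- 1e-12
  lE_only <- sum(vapply(seq_len(ncol(X)), function(g) {
    pat <- stats::setNames(unclass(X)[, g], rownames(X))
    log(mean(vapply(1:4, function(j)
      exp(family_loglik(pat, tr, p0, ann, "essential", j)), numeric(1))))
  }, numeric(1)))
  expect_equal(mixture_loglik(X, tr, p0, ann), lE_only, tolerance = 1e-6)
})

test_that("fix_params mode returns inputs verbatim; fit attains the generating loglik", {
  set.seed(14)
  tr <- ape::rtree(8)
  tr$tip.label <- c(paste0("P", 1:2), paste0("N", 1:6))[sample.int(8)]
  ann <- p_annotation(tr)
  params <- toy_phylo_params()
  sim <- simulate_gene_content(tr, ann, params, 600, seed = 15,
                               condition_on_observable = FALSE)
  fx <- fit_phylo_mixture(sim$matrix, tr, ann, fix_params = params)
  expect_identical(fx$params, params)
  expect_true(fx$fixed)
  expect_equal(fx$loglik, mixture_loglik(sim$matrix, tr, params, ann))
  fit <- fit_phylo_mixture(sim$matrix, tr, ann, restarts = 2, seed = 4)
  expect_gte(fit$loglik, fx$loglik - 1e-6)
  expect_length(coef(fit), 9L)
})

test_that("classification posteriors are proper and accurate on separated regimes", {
  tr <- reference_tree()
  ann <- p_annotation(tr)
  params <- default_experiment_params()
  sim <- simulate_gene_content(tr, ann, params, 1500, seed = 33)
  cls <- classify_families(sim$matrix, tr, params, ann, min_combo = 20)
  expect_equal(unname(rowSums(cls$posterior)), rep(1, 1500),
               tolerance = 1e-9)
  acc <- mean(substr(cls$assignment, 1, 1) == substr(sim$truth, 1, 1))
  expect_gte(acc, 0.9)
  expect_error(classify_families(sim$matrix, tr, params, ann,
                                 min_combo = Inf),
               class = "mix_combo_error")
  # one retained combination reproduces the plain pipeline on its columns
  lab <- cls$assignment
  k <- names(which.max(table(lab)))
  keep <- names(lab)[lab == k]
  one <- structure(list(assignment = lab[keep], retained = k),
                   class = "combo_assignment")
  expect_warning(
    cd1 <- combo_partitioned_distances(sim$matrix[, keep, drop = FALSE], one),
    "single-category")
  plain <- combine_matrices(conditioned_distance_set(
    sim$matrix[, keep, drop = FALSE]))
  expect_equal(cd1$D, plain$D, tolerance = 1e-12)
})
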