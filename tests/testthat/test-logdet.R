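test_that("conditioned counts cross-tabulate families present in the conditioning genome", {
  X <- pa_matrix(rbind(c1 = c(1, 1, 1, 1, 0, 0), x = c(1, 1, 0, 0, 1, 0),
                       y = c(1, 0, 0, 1, 0, 1), z = c(1, 1, 1, 0, 0, 1)))
  cc <- conditioned_counts(X, "c1", "x", "y")
  expect_equal(unname(cc$N), matrix(1L, 2, 2))
  expect_equal(cc$n, 4L)
  expect_error(conditioned_counts(X, "c1", "x", "x"), class = "cld_taxa_error")
  expect_error(conditioned_counts(X, "x", "x", "y"), class = "cld_taxa_error")
  # identical columns concentrate counts on the diagonal
  X2 <- pa_matrix(rbind(c1 = rep(1, 6), x = c(1, 1, 0, 0, 1, 0),
                        y = c(1, 1, 0, 0, 1, 0), z = rep(1, 6)))
  cc2 <- conditioned_counts(X2, "c1", "x", "y")
  expect_equal(unname(cc2$N), matrix(c(3L, 0L, 0L, 3L), 2, 2))
  X3 <- pa_matrix(rbind(c1 = rep(0, 3), x = c(1, 0, 1), y = c(0, 1, 1),
                        z = rep(1, 3)))
  expect_error(conditioned_counts(X3, "c1", "x", "y"),
               class = "cld_empty_error")
})

test_that("logdet distance matches the closed form and reports degeneracy", {
  same <- logdet_distance(list(N = matrix(c(50, 0, 0, 50), 2, 2), n = 100))
  expect_true(same$exists)
  expect_equal(same$distance, 0)
  d <- logdet_distance(list(N = matrix(c(40, 10, 10, 40), 2, 2), n = 100))
  expect_equal(d$distance, -0.5 * (log(0.15) - 0.5 * log(0.0625)),
               tolerance = 1e-12)
  expect_equal(round(d$distance, 4), 0.2554)
  expect_gt(d$variance, 0)
  neg <- logdet_distance(list(N = matrix(c(10, 40, 40, 10), 2, 2), n = 100))
  expect_false(neg$exists)
  expect_true(is.na(neg$distance))
  zmar <- logdet_distance(list(N = matrix(c(0, 0, 60, 40), 2, 2), n = 100))
  expect_false(zmar$exists)
})

test_that("pseudocount repair smooths cells and barely moves healthy distances", {
  cts <- list(N = matrix(c(0, 5, 5, 90), 2, 2), n = 100)
  expect_false(logdet_distance(cts)$exists)
  rep_ <- repair_pseudocount(cts)
  expect_equal(unname(rep_$N), matrix(c(0.5, 5.5, 5.5, 90.5), 2, 2))
  expect_equal(rep_$n, 102)
  expect_true(logdet_distance(rep_)$exists)
  expect_error(repair_pseudocount(cts, beta = 0), class = "cld_beta_error")
  healthy <- list(N = matrix(c(400, 100, 100, 400), 2, 2), n = 1000)
  d0 <- logdet_distance(healthy)$distance
  d1 <- logdet_distance(repair_pseudocount(healthy))$distance
  expect_lt(abs(d1 - d0), 10 * 0.5 / 1000)
})

test_that("constrained ML returns the MLE when feasible, the det boundary otherwise", {
  feas <- repair_constrained_ml(list(N = matrix(c(40, 10, 10, 40), 2, 2)))
  expect_identical(feas$F, matrix(c(40, 10, 10, 40), 2, 2) / 100)
  expect_false(feas$boundary)
  infeas <- repair_constrained_ml(list(N = matrix(c(10, 40, 40, 10), 2, 2)))
  expect_true(infeas$boundary)
  F <- infeas$F
  expect_equal(F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1], 1e-6,
               tolerance = 1e-9)
  expect_equal(sum(F), 1, tolerance = 1e-12)
  expect_error(repair_constrained_ml(list(N = matrix(1, 2, 2)), delta = -1),
               class = "cld_delta_error")
})

test_that("constrained ML beats a 200x200 feasible-grid oracle", {
  set.seed(42)
  checked <- 0L
  while (checked < 8L) {
    N <- matrix(rpois(4, sample(c(1, 3, 10, 40), 4, replace = TRUE)), 2, 2)
    if (sum(N) == 0) next
    Fh <- N / sum(N)
    if (Fh[1, 1] * Fh[2, 2] - Fh[1, 2] * Fh[2, 1] >= 1e-6) next
    res <- repair_constrained_ml(list(N = N))
    expect_gte(res$loglik, grid_constrained_ml(N) - 1e-6)
    checked <- checked + 1L
  }
})

test_that("conditioned distance matrices are symmetric with zero diagonal", {
  set.seed(8)
  X <- pa_matrix(matrix(rbinom(6 * 400, 1, 0.55), 6, 400,
                        dimnames = list(paste0("t", 1:6), NULL)))
  set <- conditioned_distance_set(X)
  expect_length(set, 6L)
  for (m in set) {
    expect_equal(dim(m$D), c(5L, 5L))
    expect_identical(m$D, t(m$D))
    expect_identical(m$V, t(m$V))
    expect_equal(unname(diag(m$D)), rep(0, 5))
    expect_equal(m$n, sum(X[m$conditioning, ]))
  }
  expect_error(conditioned_distance_set(X[1:3, ]), class = "cld_taxa_error")
  # repair policy "none" leaves degenerate pairs missing
  Xs <- pa_matrix(matrix(rbinom(5 * 12, 1, 0.5), 5, 12,
                         dimnames = list(paste0("t", 1:5), NULL)))
  none <- conditioned_distance_set(Xs, repair = "none")
  onf <- conditioned_distance_set(Xs, repair = "on_failure")
  expect_true(any(is.na(unlist(lapply(none, `[[`, "D")))))
  expect_false(any(is.na(unlist(lapply(onf, `[[`, "D")))))
})

test_that("large homogeneous samples need no repair and distances are consistent", {
  tree <- read_newick("((A:0.15,B:0.2):0.1,(C:0.25,D:0.1):0.1);", text = TRUE)
  params <- homogeneous_params()
  ann <- stats::setNames(rep(FALSE, 4), tree$tip.label)
  sim <- simulate_gene_content(tree, ann, params, 10000, seed = 31,
                               condition_on_observable = FALSE)
  set <- conditioned_distance_set(sim$matrix)
  expect_true(all(unlist(lapply(set, `[[`, "repair_code")) == 0L))
  comb <- combine_matrices(set)
  ord <- c("A", "B", "C", "D")
  res_big <- four_point_residual(comb$D[ord, ord])
  expect_lt(res_big, 0.05)
  # residual shrinks with more families (consistency toward additivity)
  sim_small <- simulate_gene_content(tree, ann, params, 500, seed = 31,
                                     condition_on_observable = FALSE)
  comb_small <- combine_matrices(conditioned_distance_set(sim_small$matrix))
  expect_lt(res_big, four_point_residual(comb_small$D[ord, ord]) + 0.02)
})

test_that("delta-method variance tracks the family-bootstrap variance", {
  # one pair under one conditioning genome: counts drawn from a fixed joint
  # distribution over 500 families, bootstrap across families
  set.seed(77)
  probs <- c(0.45, 0.15, 0.1, 0.3)
  G <- 500
  fam <- sample.int(4, G, replace = TRUE, prob = probs)
  counts <- tabulate(fam, 4)
  est <- logdet_distance(list(N = matrix(counts, 2, 2), n = G))
  boot <- replicate(500, {
    f <- fam[sample.int(G, G, replace = TRUE)]
    dv <- logdet_distance(list(N = matrix(tabulate(f, 4), 2, 2), n = G))
    dv$distance
  })
  emp <- stats::var(boot, na.rm = TRUE)
  expect_lt(abs(est$variance - emp) / emp, 0.3)
})
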