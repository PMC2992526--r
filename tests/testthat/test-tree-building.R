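make_cond_dist <- function(conditioning, taxa, D, V) {
  dimnames(D) <- list(taxa, taxa)
  dimnames(V) <- list(taxa, taxa)
  structure(list(conditioning = conditioning, taxa = taxa, D = D, V = V,
                 repair_code = 0 * D, n = 100L), class = "cond_dist")
}

test_that("inverse-variance combination pools pair estimates correctly", {
  two <- function(d, v) {
    make_cond_dist("c", c("x", "y"), matrix(c(0, d, d, 0), 2, 2),
                   matrix(c(0, v, v, 0), 2, 2))
  }
  eq <- combine_matrices(list(two(1, 1), two(3, 1)))
  expect_equal(eq$D["x", "y"], 2)
  expect_equal(eq$V["x", "y"], 0.5)
  expect_equal(eq$contributors["x", "y"], 2L)
  wt <- combine_matrices(list(two(1, 0.5), two(3, 2)))
  expect_equal(wt$D["x", "y"], 1.4)
  expect_equal(wt$V["x", "y"], 0.4)
  single <- make_cond_dist("c", c("a", "b"),
                           matrix(c(0, 2, 2, 0), 2, 2),
                           matrix(c(0, 3, 3, 0), 2, 2))
  alone <- combine_matrices(single)
  expect_equal(alone$D["a", "b"], 2)
  expect_equal(alone$V["a", "b"], 3)
  # a pair with no contributor is an error naming the pair
  gap <- make_cond_dist("c", c("x", "y"),
                        matrix(NA_real_, 2, 2), matrix(NA_real_, 2, 2))
  expect_error(combine_matrices(list(gap)), "x, y",
               class = "cld_combine_error")
})

test_that("bionj recovers additive trees exactly, any positive variances", {
  # ((A:1,B:2):1,(C:3,D:4));
  taxa <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
              dimnames = list(taxa, taxa))
  for (vseed in 1:3) {
    set.seed(vseed)
    V <- matrix(runif(16, 0.1, 2), 4, 4); V <- (V + t(V)) / 2; diag(V) <- 0
    dimnames(V) <- dimnames(D)
    tr <- bionj(D, V)
    expect_true(contains_clan(tr, c("A", "B")))
    got <- ape::cophenetic.phylo(tr)[taxa, taxa]
    expect_equal(unname(got), unname(D), tolerance = 1e-9)
  }
  # agreement with an independent neighbor-joining implementation
  nj_ref <- ape::nj(as.dist(D))
  expect_equal(rf_distance(bionj(D), nj_ref), 0L)
  # larger random additive matrix
  set.seed(11)
  gen <- ape::rtree(8)
  Dg <- ape::cophenetic.phylo(gen)
  est <- bionj(Dg)
  expect_equal(rf_distance(est, gen), 0L)
  expect_equal(unname(ape::cophenetic.phylo(est)[rownames(Dg), colnames(Dg)]),
               unname(Dg), tolerance = 1e-9)
})

test_that("bionj three-point formulas and tie-breaking are exact", {
  D3 <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- bionj(D3)
  len <- stats::setNames(t3$edge.length[match(1:3, t3$edge[, 2])],
                         t3$tip.label)
  expect_equal(len, c(a = 0, b = 2, c = 4))
  De <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(De) <- 0
  te <- bionj(De)
  expect_true(contains_clan(te, c("a", "b")))   # lexicographically first pair
  expect_error(bionj(De[, c(2, 1, 3, 4)]), class = "bionj_error")
})

test_that("majority consensus keeps strictly-majority splits with supports", {
  t1 <- read_newick("((A,B),(C,D),E);", text = TRUE)
  t2 <- read_newick("((A,C),(B,D),E);", text = TRUE)
  all_same <- majority_consensus(rep(list(t1), 200))
  expect_equal(rf_distance(all_same, t1), 0L)
  expect_true(all(as.numeric(all_same$node.label[-1]) == 100))
  # 3:1 -> AB|CDE and CD|ABE at 75
  mixed <- majority_consensus(c(rep(list(t1), 3), list(t2)))
  expect_true(contains_clan(mixed, c("A", "B")))
  expect_true(contains_clan(mixed, c("C", "D")))
  expect_false(contains_clan(mixed, c("A", "C")))
  expect_true(all(as.numeric(mixed$node.label[-1]) == 75))
  # exactly 50% is excluded (strict rule)
  half <- majority_consensus(c(rep(list(t1), 2), rep(list(t2), 2)))
  expect_false(contains_clan(half, c("A", "B")))
  expect_false(contains_clan(half, c("A", "C")))
  expect_error(majority_consensus(list(t1, read_newick("((A,B),C);",
                                                       text = TRUE))),
               class = "tree_leafset_error")
})

test_that("consensus contains exactly the strict-majority splits, pairwise compatible", {
  # independent split counting via ape::prop.part on each input tree
  split_keys <- function(tr) {
    tr <- ape::unroot(tr)
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    ref <- sort(tr$tip.label)
    keys <- character(0)
    for (p in parts) {
      side <- labs[p]
      if (length(side) <= 1 || length(side) >= length(labs) - 1) next
      if (ref[1] %in% side) side <- setdiff(ref, side)
      if (length(side) <= 1) next
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
    unique(keys)
  }
  set.seed(5)
  trees <- lapply(1:9, function(i) ape::rtree(7))
  cns <- majority_consensus(trees)
  counts <- table(unlist(lapply(trees, split_keys)))
  expected <- sort(names(counts)[counts / 9 > 0.5])
  expect_identical(sort(split_keys(cns)), expected)
  # pairwise compatibility of the consensus splits
  sides <- strsplit(split_keys(cns), "|", fixed = TRUE)
  labs <- sort(trees[[1]]$tip.label)
  for (a in sides) for (b in sides) {
    compat <- all(a %in% b) || all(b %in% a) ||
      length(intersect(a, b)) == 0 || setequal(union(a, b), labs)
    expect_true(compat)
  }
})

test_that("rf distance counts the split symmetric difference and is a metric", {
  t1 <- read_newick("((A,B),(C,D));", text = TRUE)
  t2 <- read_newick("((A,C),(B,D));", text = TRUE)
  star <- read_newick("(A,B,C,D);", text = TRUE)
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  expect_equal(rf_distance(t1, star), 1L)
  expect_error(rf_distance(t1, read_newick("((A,B),(C,E));", text = TRUE)),
               class = "tree_leafset_error")
  set.seed(13)
  trees <- lapply(1:6, function(i) ape::rtree(8))
  for (i in 1:6) for (j in 1:6) {
    dij <- rf_distance(trees[[i]], trees[[j]])
    expect_equal(dij, rf_distance(trees[[j]], trees[[i]]))
    if (i == j) expect_equal(dij, 0L)
    for (k in 1:6) {
      expect_lte(dij, rf_distance(trees[[i]], trees[[k]]) +
                   rf_distance(trees[[k]], trees[[j]]))
    }
  }
})

test_that("clan membership is read off unrooted splits", {
  tr <- read_newick("((P1,P2),(N1,N2));", text = TRUE)
  expect_true(contains_clan(tr, c("P1", "P2")))
  expect_false(contains_clan(tr, c("P1", "N1")))
  cat5 <- read_newick("(((P1,P2),P3),(N1,N2));", text = TRUE)
  expect_true(contains_clan(cat5, c("P1", "P2", "P3")))
  expect_true(contains_clan(cat5, "P1"))      # pendant edge
  expect_error(contains_clan(tr, character(0)), class = "tree_clan_error")
  expect_error(contains_clan(tr, c("P1", "P2", "N1", "N2")),
               class = "tree_clan_error")
  expect_error(contains_clan(tr, "Z"), class = "tree_clan_error")
})
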