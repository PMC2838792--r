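
test_that("parsimony score basics: invariant and single-change characters", {
  n <- 6
  st <- matrix(0L, n, 3)
  st[1, 2] <- 1L                       # one individual differs on trait 2
  tm <- trait_matrix(st, rep("F", n), as.character(1:n))
  for (phy in enumerate_topologies(rownames(tm))[c(1, 30, 60)]) {
    expect_equal(parsimony_score(phy, tm), 1)
    per <- parsimony_score(phy, tm, per_character = TRUE)
    expect_equal(unname(per), c(0, 1, 0))
  }
  # all-identical individuals score 0 on any tree
  tm0 <- trait_matrix(matrix(1L, n, 4), rep("F", n), as.character(1:n))
  expect_equal(parsimony_score(enumerate_topologies(rownames(tm0))[[10]],
                               tm0), 0)
})

test_that("score is invariant to rerooting and leaf-order permutation", {
  tm <- random_trait_matrix(6, 10, p_ordinal = 0.3, p_missing = 0.1,
                            seed = 11)
  phy <- enumerate_topologies(rownames(tm))[[17]]
  s0 <- parsimony_score(phy, tm)
  for (og in c(2, 5)) {
    r <- ape::root(phy, outgroup = rownames(tm)[og], resolve.root = TRUE)
    expect_equal(parsimony_score(r, tm), s0)
  }
  perm <- sample(nrow(tm))
  tm2 <- trait_matrix(unclass(tm)[perm, ], attr(tm, "family_id")[perm],
                      attr(tm, "individual_id")[perm],
                      trait_kind = attr(tm, "trait_kind"))
  expect_equal(parsimony_score(phy, tm2), s0)
})

test_that("Wagner (ordered) score dominates Fitch on the same characters", {
  for (seed in 1:5) {
    tm <- random_trait_matrix(6, 8, p_ordinal = 1, seed = seed)
    phy <- enumerate_topologies(rownames(tm))[[seed * 7]]
    expect_gte(parsimony_score(phy, tm, ordered_ordinal = TRUE),
               parsimony_score(phy, tm, ordered_ordinal = FALSE))
  }
})

test_that("binary scoring agrees with an independent phylogenetics engine", {
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    tm <- random_trait_matrix(7, 15, seed = seed)
    phy <- enumerate_topologies(rownames(tm))[[seed * 100]]
    dat <- phangorn::phyDat(unclass(tm), type = "USER", levels = 0:1)
    expect_equal(parsimony_score(phy, tm),
                 as.numeric(phangorn::parsimony(phy, dat)))
  }
})

test_that("exhaustive minimum is reached by ratchet search (6 leaves)", {
  for (seed in c(3, 14)) {
    tm <- random_trait_matrix(6, 12, seed = seed)
    best <- oracle_exhaustive_score(tm)
    ts <- ratchet_search(tm, n_iterations = 10, seed = seed)
    expect_equal(ts$score, best)
  }
})

test_that("perfect phylogeny scores one change per variable character", {
  fx <- make_toy_fixture()
  ts <- ratchet_search(fx$traits, n_iterations = 10, seed = 2)
  expect_equal(ts$score, fx$expected$optimal_score)
})

test_that("ratchet is deterministic under a fixed seed", {
  tm <- random_trait_matrix(7, 10, p_missing = 0.1, seed = 21)
  a <- ratchet_search(tm, n_iterations = 8, seed = 99)
  b <- ratchet_search(tm, n_iterations = 8, seed = 99)
  expect_equal(a$score, b$score)
  expect_equal(lapply(a$trees, ape::write.tree),
               lapply(b$trees, ape::write.tree))
})

test_that("fewer than four individuals yields the trivial topology", {
  tm <- random_trait_matrix(3, 5, seed = 2)
  ts <- ratchet_search(tm, n_iterations = 5, seed = 1)
  expect_equal(length(ts$trees), 1)
  expect_setequal(ts$trees[[1]]$tip.label, rownames(tm))
})

test_that("SPR refinement reaches the exhaustive optimum from a bad start", {
  tm <- random_trait_matrix(6, 12, seed = 31)
  best <- oracle_exhaustive_score(tm)
  topos <- enumerate_topologies(rownames(tm))
  scores <- vapply(topos, parsimony_score, 0, traits = tm)
  worst <- topos[[which.max(scores)]]
  fake <- structure(list(trees = list(worst), score = max(scores),
                         labels = rownames(tm)), class = "pheno_treeset")
  ref <- spr_refine(fake, tm)
  expect_equal(ref$score, best)
  expect_lte(ref$score, max(scores))
  # already-optimal input is left unchanged in score
  opt <- topos[[which.min(scores)]]
  ref2 <- spr_refine(list(opt), tm)
  expect_equal(ref2$score, best)
})

test_that("SPR refinement of all-identical members gives score 0", {
  tm <- trait_matrix(matrix(1L, 5, 4), rep("F", 5), as.character(1:5))
  ts <- ratchet_search(tm, n_iterations = 2, seed = 5)
  expect_equal(ts$score, 0)
})

test_that("majority-rule consensus keeps exactly the majority bipartitions", {
  tm <- random_trait_matrix(6, 8, seed = 41)
  topos <- enumerate_topologies(rownames(tm))
  # identical input trees: consensus is that tree (same splits)
  t1 <- topos[[100]]
  cons <- majority_consensus(list(t1, t1, t1))
  key <- function(phy) sort(cladelink:::ct_splits(
    cladelink:::phylo_to_ct(phy)))
  expect_equal(key(cons), key(t1))
  # a bipartition in 2 of 3 trees is retained (2/3 > 0.51)
  t2 <- topos[[101]]
  shared <- intersect(intersect(key(t1), key(t1)), key(t2))
  cons2 <- majority_consensus(list(t1, t1, t2))
  expect_true(all(key(t1) %in% key(cons2)))
  # trees sharing no bipartition give a star
  k1 <- key(topos[[1]])
  far <- which(vapply(topos, function(t) !any(key(t) %in% k1), TRUE))[1]
  cons3 <- majority_consensus(list(topos[[1]], topos[[far]]))
  expect_equal(length(key(cons3)), 0)
  # incompatible leaf sets error
  small <- enumerate_topologies(rownames(tm)[1:5])[[1]]
  expect_error(majority_consensus(list(t1, small)), "incompatible")
})

test_that("consensus agrees with ape's majority-rule consensus", {
  tm <- random_trait_matrix(7, 10, seed = 51)
  ts <- ratchet_search(tm, n_iterations = 15, seed = 3)
  if (length(ts$trees) >= 2) {
    ours <- majority_consensus(ts)
    apec <- ape::consensus(ts$trees, p = 0.51)
    key <- function(phy) sort(cladelink:::ct_splits(
      cladelink:::phylo_to_ct(phy)))
    expect_equal(key(ours), key(apec))
  } else succeed("single optimal tree; consensus trivially equal")
})

test_that("mapped trait changes sum to the parsimony score", {
  for (seed in c(6, 7)) {
    tm <- random_trait_matrix(6, 10, p_ordinal = 0.3, p_missing = 0.1,
                              seed = seed)
    phy <- enumerate_topologies(rownames(tm))[[5 * seed]]
    ch <- map_trait_changes(phy, tm)
    # ordered characters may cover several steps on one edge, so compare
    # the summed step cost, not the row count
    expect_equal(sum(abs(ch$to - ch$from)),
                 sum(parsimony_score(phy, tm, per_character = TRUE)))
  }
  # ordered characters can move more than one step on an edge
  st <- matrix(c(0L, 3L, 0L, 0L), 4, 1)
  tmo <- trait_matrix(st, rep("F", 4), as.character(1:4),
                      trait_kind = "ordinal4")
  phy <- enumerate_topologies(rownames(tmo))[[1]]
  ch <- map_trait_changes(phy, tmo)
  expect_equal(sum(abs(ch$to - ch$from)), 3)
})

test_that("an invariant character maps no changes; a single variant maps one", {
  n <- 5
  st <- cbind(rep(0L, n), c(1L, rep(0L, n - 1)))
  tm <- trait_matrix(st, rep("F", n), as.character(1:n))
  phy <- enumerate_topologies(rownames(tm))[[3]]
  ch <- map_trait_changes(phy, tm)
  expect_equal(unique(ch$trait), "t2")
  expect_equal(nrow(ch), 1)
  # the change sits on the pendant edge of the differing leaf
  expect_equal(ch$child, 1)
})

test_that("ratchet/SPR equals exhaustive search on random 7-leaf matrices", {
  # the full 100-matrix sweep runs in the acceptance suite; here a spot
  # check including ordinal and missing states
  for (seed in c(8, 15)) {
    tm <- random_trait_matrix(7, 12, p_ordinal = 0.25, p_missing = 0.05,
                              seed = seed)
    best <- oracle_exhaustive_score(tm)
    ts <- ratchet_search(tm, n_iterations = 10, seed = seed)
    expect_equal(ts$score, best)
  }
})
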