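test_that("symptom profile applies a strict 70% prevalence rule", {
  st <- cbind(always = rep(1L, 10),
              seventy = c(rep(1L, 7), rep(0L, 3)),       # exactly 70%
              most = c(rep(1L, 8), rep(0L, 2)),
              with_na = c(rep(1L, 6), rep(NA, 2), 0L, 0L))  # 6/8 = 75%
  tm <- trait_matrix(st, rep("F", 10), as.character(1:10))
  prof <- symptom_profile(rownames(tm), tm)
  expect_true("always" %in% prof)
  expect_false("seventy" %in% prof)     # 70.0% is not > 70%
  expect_true("most" %in% prof)
  expect_true("with_na" %in% prof)      # prevalence among scored members
  # random clade equals a direct recount
  set.seed(3)
  tm2 <- random_trait_matrix(30, 12, p_missing = 0.1, seed = 3)
  clade <- sample(rownames(tm2), 12)
  prof2 <- symptom_profile(clade, tm2, prevalence_threshold = 0.5)
  manual <- colnames(tm2)[vapply(seq_len(ncol(tm2)), function(j) {
    v <- unclass(tm2)[clade, j]
    mean(v[!is.na(v)] >= 1) > 0.5
  }, TRUE)]
  expect_setequal(prof2, manual)
})

test_that("ordinal severity counts as present at any level above absent", {
  st <- matrix(c(0L, 1L, 2L, 3L), 4, 1)
  tm <- trait_matrix(st, rep("F", 4), as.character(1:4),
                     trait_kind = "ordinal4")
  expect_equal(symptom_profile(rownames(tm), tm, 0.5), "t1")  # 3/4 present
})

test_that("four-group counts partition the scored cohort", {
  in_clade <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  in_diag <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  present <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  cc <- four_group_counts(in_clade, in_diag, present)
  expect_equal(cc$n1 + cc$n2 + cc$n3 + cc$n4, 6)
  expect_equal(cc$n4, 2)   # in both
  expect_equal(cc$n3, 1)   # clade only
  expect_equal(cc$n2, 2)   # diagnosis only
  expect_equal(cc$x4, 1)
})

test_that("LRT statistic is zero when the group rates coincide", {
  cc <- structure(list(x1 = 5, n1 = 20, x2 = 5, n2 = 10,
                       x3 = 3, n3 = 6, x4 = 7, n4 = 14),
                  class = "four_group_counts")
  r <- lrt_symptom(cc)   # p2 = 0.5 = pooled(3,4) = 10/20
  expect_equal(r$statistic, 0)
  # all-zero counts are degenerate but defined
  cc0 <- structure(list(x1 = 0, n1 = 5, x2 = 0, n2 = 5,
                        x3 = 0, n3 = 5, x4 = 0, n4 = 5),
                   class = "four_group_counts")
  expect_equal(lrt_symptom(cc0)$statistic, 0)
})

test_that("LRT statistic matches the grid-search oracle", {
  set.seed(17)
  for (i in 1:300) {
    n <- sample(3:50, 3, replace = TRUE)
    x <- rbinom(3, n, runif(3))
    got <- cladelink:::lrt_stat(x[1], n[1], x[2], n[2], x[3], n[3])
    want <- oracle_grid_lrt(x[1], n[1], x[2], n[2], x[3], n[3])
    expect_equal(got, max(0, want), tolerance = 1e-3)
  }
  # the worked four-group example
  cc <- structure(list(x1 = 3, n1 = 30, x2 = 2, n2 = 20,
                       x3 = 8, n3 = 10, x4 = 9, n4 = 10),
                  class = "four_group_counts")
  expect_equal(lrt_symptom(cc)$statistic,
               oracle_grid_lrt(2, 20, 8, 10, 9, 10), tolerance = 1e-4)
})

test_that("boundary cases pick the right comparison or are flagged", {
  mk <- function(...) structure(list(...), class = "four_group_counts")
  # containment: clade inside the diagnostic category (group 3 empty)
  r <- lrt_symptom(mk(x1 = 0, n1 = 10, x2 = 2, n2 = 20,
                      x3 = 0, n3 = 0, x4 = 9, n4 = 10))
  expect_equal(r$case, "containment")
  expect_equal(r$statistic, oracle_grid_lrt(2, 20, 0, 0, 9, 10),
               tolerance = 1e-4)
  # disjoint: no overlap (group 4 empty), p2 vs p3
  r2 <- lrt_symptom(mk(x1 = 0, n1 = 10, x2 = 2, n2 = 20,
                       x3 = 8, n3 = 10, x4 = 0, n4 = 0))
  expect_equal(r2$case, "disjoint")
  expect_equal(r2$statistic, oracle_grid_lrt(2, 20, 8, 10, 0, 0),
               tolerance = 1e-4)
  # empty comparison group: undefined, flagged rather than p = 1
  r3 <- lrt_symptom(mk(x1 = 0, n1 = 10, x2 = 0, n2 = 0,
                       x3 = 8, n3 = 10, x4 = 0, n4 = 0))
  expect_false(r3$defined)
  expect_true(is.na(r3$statistic))
})

test_that("group 1 never affects the statistic", {
  base <- list(x2 = 4, n2 = 15, x3 = 6, n3 = 9, x4 = 2, n4 = 7)
  s <- vapply(c(0, 5, 50), function(x1) {
    cc <- structure(c(list(x1 = x1, n1 = max(x1, 60)), base),
                    class = "four_group_counts")
    lrt_symptom(cc)$statistic
  }, 0)
  expect_equal(s[1], s[2])
  expect_equal(s[1], s[3])
})

test_that("permutation p-values: determinism, null stat, add-one floor", {
  sim <- simulate_symptom_cohort(
    120, c("dep", "scz"),
    list(dep = c(t1 = 0.3, t2 = 0.9), scz = c(t1 = 0.3, t2 = 0.1)),
    seed = 8)
  clade <- sim$labels$key[sim$labels$diagnosis == "scz"][1:30]
  dkeys <- sim$labels$key[sim$labels$diagnosis == "dep"]
  r1 <- clade_trait_test(clade, dkeys, sim$traits, "t2",
                         n_perm = 199, seed = 42)
  r2 <- clade_trait_test(clade, dkeys, sim$traits, "t2",
                         n_perm = 199, seed = 42)
  expect_identical(r1$perm_p, r2$perm_p)
  expect_gte(r1$perm_p, 1 / 200)
  # strong separation: small p at the add-one floor scale
  expect_lt(r1$perm_p, 0.05)
  # a statistic of zero has permutation p near 1
  cc_builder <- function(permute) {
    structure(list(x1 = 0, n1 = 1, x2 = 5, n2 = 10, x3 = 3, n3 = 6,
                   x4 = 2, n4 = 4), class = "four_group_counts")
  }
  p0 <- permutation_p(cc_builder, n_perm = 99, seed = 1)
  expect_equal(as.numeric(p0), 1)
})

test_that("under the null the permutation test rejects at its nominal rate", {
  # one trait, no clade/diagnosis effect; rejection rate at 0.05 should sit
  # inside the binomial 99% interval
  set.seed(123)
  n_sim <- 120
  rej <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    sim <- simulate_symptom_cohort(
      90, c("g1", "g2"),
      list(g1 = c(t1 = 0.3), g2 = c(t1 = 0.3)), seed = 1000 + s)
    clade <- sample(sim$labels$key, 30)
    dkeys <- sim$labels$key[sim$labels$diagnosis == "g1"]
    r <- clade_trait_test(clade, dkeys, sim$traits, "t1",
                          n_perm = 99, seed = 2000 + s)
    rej[s] <- !is.na(r$perm_p) && r$perm_p <= 0.05
  }
  ci <- qbinom(c(0.005, 0.995), n_sim, 0.05)
  expect_gte(sum(rej), ci[1])
  expect_lte(sum(rej), ci[2])
})

test_that("clade-by-trait summary reports prevalence and BH adjustment", {
  sim <- simulate_symptom_cohort(
    60, c("dep", "scz"),
    list(dep = c(a = 0.9, b = 0.1), scz = c(a = 0.1, b = 0.9)),
    seed = 5)
  # build a clade_set-like object with one clade = the scz half
  cl <- structure(list(
    table = data.frame(label = "2_0", level = 2, index = 0, node = 0,
                       n_members = 30, n_families = 30,
                       stringsAsFactors = FALSE),
    members = list(`2_0` =
      sim$labels$key[sim$labels$diagnosis == "scz"][1:20]),
    tree = NULL), class = "clade_set")
  diag <- data.frame(key = sim$labels$key,
                     diagnosis = sim$labels$diagnosis,
                     stringsAsFactors = FALSE)
  tab <- symptom_significance(cl, sim$traits, diag, n_perm = 99, seed = 9)
  expect_setequal(tab$trait, c("a", "b"))
  expect_true(all(tab$bh_p >= tab$perm_p - 1e-12))
  expect_true(tab$in_profile[tab$trait == "b"])
})
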