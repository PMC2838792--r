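#' Symptom profile of a clade
#'
#' Traits present (state >= 1) in strictly more than `prevalence_threshold`
#' of the clade members scored for that trait.
#'
#' @param clade character vector of member keys.
#' @param traits a [trait_matrix()].
#' @param prevalence_threshold strict lower bound on prevalence (default
#'   0.70).
#' @return character vector of trait names.
#' @export
symptom_profile <- function(clade, traits, prevalence_threshold = 0.70) {
  rows <- intersect(clade, rownames(traits))
  if (!length(rows)) stop("no clade member is scored for any trait")
  st <- unclass(traits)[rows, , drop = FALSE]
  prev <- colMeans(st >= 1, na.rm = TRUE)
  names(prev)[!is.na(prev) & prev > prevalence_threshold]
}

#' Four-group symptom counts
#'
#' Partitions the scored cohort for one trait into: group 2 = diagnostic
#' category minus clade, group 3 = clade minus diagnostic category, group 4 =
#' their intersection, and group 1 = everyone else. `x_i` counts members of
#' group `i` with the symptom present; `n_i` is the group size.
#'
#' @param in_clade,in_diagnosis,present logical vectors over the scored
#'   cohort (individuals with a non-missing state for the trait).
#' @return an object of class `four_group_counts`.
#' @export
four_group_counts <- function(in_clade, in_diagnosis, present) {
  stopifnot(length(in_clade) == length(in_diagnosis),
            length(in_clade) == length(present))
  g2 <- in_diagnosis & !in_clade
  g3 <- in_clade & !in_diagnosis
  g4 <- in_clade & in_diagnosis
  g1 <- !in_clade & !in_diagnosis
  structure(list(
    x1 = sum(present[g1]), n1 = sum(g1),
    x2 = sum(present[g2]), n2 = sum(g2),
    x3 = sum(present[g3]), n3 = sum(g3),
    x4 = sum(present[g4]), n4 = sum(g4)),
    class = "four_group_counts")
}

# counts for a named trait given clade and diagnostic-category membership
counts_for_trait <- function(clade, diagnosis_keys, traits, trait) {
  v <- unclass(traits)[, trait]
  scored <- rownames(traits)[!is.na(v)]
  present <- v[!is.na(v)] >= 1
  four_group_counts(scored %in% clade, scored %in% diagnosis_keys, present)
}

# binomial log-likelihood with the 0*log(0) = 0 convention
binom_ll <- function(x, n, p) {
  t1 <- ifelse(x == 0, 0, x * log(p))
  t2 <- ifelse(n - x == 0, 0, (n - x) * log1p(-p))
  t1 + t2
}

# Vectorized likelihood-ratio statistic comparing group 2 against the pooled
# groups 3+4 (the general case). Callers pass zero-size groups as n = 0.
lrt_stat <- function(x2, n2, x3, n3, x4, n4) {
  xa <- x3 + x4; na <- n3 + n4
  p0 <- (x2 + xa) / (n2 + na)
  pa2 <- ifelse(n2 > 0, x2 / n2, 0)
  pa34 <- ifelse(na > 0, xa / na, 0)
  ll0 <- binom_ll(x2 + xa, n2 + na, p0)
  lla <- binom_ll(x2, n2, pa2) + binom_ll(xa, na, pa34)
  pmax(0, 2 * (lla - ll0))
}

#' Four-group likelihood-ratio test for a symptom
#'
#' Tests whether a trait's probability differs between a clade and the
#' diagnostic category its members were assigned to. Under the null the
#' trait probability is common to groups 2-4 (`p2 = p3 = p4`); under the
#' alternative group 2 differs from the pooled clade groups
#' (`p2 != p3 = p4`). Group 1 contributes identically to both likelihoods
#' and cancels. When the clade is contained in the diagnostic category
#' (group 3 empty) `p2` is compared to `p4`; when clade and category are
#' disjoint (group 4 empty) `p2` is compared to `p3`. If the applicable
#' comparison has an empty group the test is undefined and flagged.
#'
#' @param counts a [four_group_counts()].
#' @return object of class `lrt_result`: `statistic` (2 * log LR, natural
#'   log), plug-in MLEs under both hypotheses, the comparison case, and
#'   `defined`.
#' @export
lrt_symptom <- function(counts) {
  c2 <- counts
  case <- if (c2$n3 == 0 && c2$n4 == 0) "empty-clade"
          else if (c2$n3 == 0) "containment"
          else if (c2$n4 == 0) "disjoint"
          else "general"
  pick <- switch(case,
    general     = list(x2 = c2$x2, n2 = c2$n2, x3 = c2$x3, n3 = c2$n3,
                       x4 = c2$x4, n4 = c2$n4),
    containment = list(x2 = c2$x2, n2 = c2$n2, x3 = 0, n3 = 0,
                       x4 = c2$x4, n4 = c2$n4),
    disjoint    = list(x2 = c2$x2, n2 = c2$n2, x3 = c2$x3, n3 = c2$n3,
                       x4 = 0, n4 = 0),
    `empty-clade` = NULL)
  defined <- !is.null(pick) && pick$n2 > 0 && (pick$n3 + pick$n4) > 0
  if (!defined) {
    return(structure(list(statistic = NA_real_, case = case,
                          defined = FALSE, p0 = NA_real_,
                          pA = c(NA_real_, NA_real_), counts = counts),
                     class = "lrt_result"))
  }
  stat <- lrt_stat(pick$x2, pick$n2, pick$x3, pick$n3, pick$x4, pick$n4)
  xa <- pick$x3 + pick$x4; na <- pick$n3 + pick$n4
  structure(list(
    statistic = stat, case = case, defined = TRUE,
    p0 = (pick$x2 + xa) / (pick$n2 + na),
    pA = c(p2 = pick$x2 / pick$n2, p34 = xa / na),
    counts = counts), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  if (!x$defined) {
    cat("Four-group LRT: undefined (", x$case, " with empty group)\n",
        sep = "")
  } else {
    cat("Four-group LRT (", x$case, "): 2*logLR = ",
        format(x$statistic, digits = 4),
        ", p2_hat = ", format(x$pA[1], digits = 3),
        ", p_clade_hat = ", format(x$pA[2], digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Permutation p-value for a four-group LRT
#'
#' `counts_builder(permute)` must return a [four_group_counts()]: the
#' observed counts when `permute = FALSE`, and counts under one random
#' reshuffle of clade membership (group sizes held fixed) when
#' `permute = TRUE`. The p-value uses the add-one convention
#' `(#\{perm >= obs\} + 1) / (n_perm + 1)`.
#'
#' @param counts_builder function as described above.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return the empirical p-value, with the observed statistic as attribute
#'   `statistic`.
#' @export
permutation_p <- function(counts_builder, n_perm = 10000, seed = NULL) {
  with_seed(seed, {
    obs <- lrt_symptom(counts_builder(FALSE))
    if (!obs$defined) stop("observed test undefined; cannot permute")
    stats <- vapply(seq_len(n_perm), function(i) {
      r <- lrt_symptom(counts_builder(TRUE))
      if (r$defined) r$statistic else NA_real_
    }, 0)
    p <- (sum(stats >= obs$statistic - 1e-12, na.rm = TRUE) + 1) /
      (n_perm + 1)
    structure(p, statistic = obs$statistic)
  })
}

#' Test one clade/trait pair against a diagnostic category
#'
#' Convenience wrapper building the four-group counts for `trait`, running
#' [lrt_symptom()], and estimating the permutation p-value by shuffling
#' clade membership within the scored cohort (clade size and diagnostic
#' labels held fixed).
#'
#' @param clade member keys; @param diagnosis_keys keys of the diagnostic
#'   category; @param traits a [trait_matrix()]; @param trait trait name.
#' @param n_perm,seed see [permutation_p()].
#' @return an `lrt_result` with `perm_p` added.
#' @export
clade_trait_test <- function(clade, diagnosis_keys, traits, trait,
                             n_perm = 10000, seed = NULL) {
  v <- unclass(traits)[, trait]
  scored <- rownames(traits)[!is.na(v)]
  present <- v[!is.na(v)] >= 1
  in_diag <- scored %in% diagnosis_keys
  in_clade0 <- scored %in% clade
  k <- sum(in_clade0)
  builder <- function(permute) {
    m <- if (permute) {
      idx <- sample.int(length(scored), k)
      seq_along(scored) %in% idx
    } else in_clade0
    four_group_counts(m, in_diag, present)
  }
  res <- lrt_symptom(builder(FALSE))
  if (res$defined)
    res$perm_p <- as.numeric(permutation_p(builder, n_perm, seed))
  else res$perm_p <- NA_real_
  res
}

#' Clade-by-trait symptom summary
#'
#' Prevalence of every trait in every clade with significance flags from the
#' four-group LRT against a chosen diagnostic category per clade (the
#' category holding the plurality of its members, unless given). Reports
#' unadjusted permutation p-values; a Benjamini-Hochberg column is added as
#' a convenience.
#'
#' @param clades a `clade_set`.
#' @param traits a [trait_matrix()].
#' @param diagnoses data frame from [read_diagnoses()] (columns `key`,
#'   `diagnosis`).
#' @param prevalence_threshold profile cut-off (strict, default 0.70).
#' @param n_perm,seed see [permutation_p()].
#' @return data frame: clade, trait, prevalence, in_profile, x/n counts,
#'   statistic, perm_p, bh_p.
#' @export
symptom_significance <- function(clades, traits, diagnoses,
                                 prevalence_threshold = 0.70,
                                 n_perm = 1000, seed = NULL) {
  out <- list()
  for (lab in clades$table$label) {
    mem <- clade_members(clades, lab)
    dm <- diagnoses$diagnosis[match(mem, diagnoses$key)]
    dm <- dm[!is.na(dm)]
    if (!length(dm)) next
    major <- names(sort(table(dm), decreasing = TRUE))[1]
    dkeys <- diagnoses$key[diagnoses$diagnosis == major]
    scored_mem <- intersect(mem, rownames(traits))
    if (!length(scored_mem)) next
    prev <- colMeans(unclass(traits)[scored_mem, , drop = FALSE] >= 1,
                     na.rm = TRUE)
    for (tr in colnames(traits)) {
      res <- clade_trait_test(mem, dkeys, traits, tr, n_perm = n_perm,
                              seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        clade = lab, diagnosis = major, trait = tr,
        prevalence = unname(prev[tr]),
        in_profile = !is.na(prev[tr]) && prev[tr] > prevalence_threshold,
        x2 = res$counts$x2, n2 = res$counts$n2,
        x3 = res$counts$x3, n3 = res$counts$n3,
        x4 = res$counts$x4, n4 = res$counts$n4,
        statistic = res$statistic, perm_p = res$perm_p,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  if (!is.null(tab)) tab$bh_p <- p.adjust(tab$perm_p, method = "BH")
  tab
}
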