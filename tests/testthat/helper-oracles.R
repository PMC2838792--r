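# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: likelihoods are computed by explicit
# enumeration from first principles, parsimony optima by exhaustive
# topology scans, and binomial maxima by grid search.

# ---- binomial LRT grid-search oracle (1e-6 terminal resolution) -----------
oracle_grid_ll_max <- function(x, n) {
  ll <- function(p) {
    t1 <- if (x == 0) rep(0, length(p)) else x * log(p)
    t2 <- if (n - x == 0) rep(0, length(p)) else (n - x) * log(1 - p)
    t1 + t2
  }
  p <- seq(1e-6, 1 - 1e-6, by = 1e-3)
  best <- p[which.max(ll(p))]
  p2 <- seq(max(1e-9, best - 2e-3), min(1 - 1e-9, best + 2e-3), by = 1e-6)
  max(ll(p2))
}

oracle_grid_lrt <- function(x2, n2, x3, n3, x4, n4) {
  2 * (oracle_grid_ll_max(x2, n2) + oracle_grid_ll_max(x3 + x4, n3 + n4) -
         oracle_grid_ll_max(x2 + x3 + x4, n2 + n3 + n4))
}

# ---- exhaustive parsimony oracle ------------------------------------------
oracle_exhaustive_score <- function(traits) {
  topos <- enumerate_topologies(rownames(traits))
  min(vapply(topos, parsimony_score, 0, traits = traits))
}

# ---- pedigree likelihood oracle by explicit genotype enumeration ----------
# States are ordered haplotype pairs (paternal, maternal); a haplotype is a
# (disease allele d in {1,2}, marker allele m in 1..A) pair coded
# h = (d-1)*A + m. Gamete probabilities are written out from first
# principles: the two parental haplotypes each with probability
# (1-theta)/2, the two recombinants with theta/2.
oracle_family_loglik <- function(ped, fam, affection, geno, marker, model,
                                 freqs, theta) {
  p <- ped[ped$family_id == fam, , drop = FALSE]
  keys <- paste(p$family_id, p$id, sep = "/")
  A <- length(freqs)
  H <- 2L * A
  S <- H * H
  hap_d <- function(h) (h - 1L) %/% A + 1L
  hap_m <- function(h) (h - 1L) %% A + 1L
  hapfreq <- ifelse(hap_d(seq_len(H)) == 2, model$q, 1 - model$q) *
    unname(freqs[hap_m(seq_len(H))])
  h1_of <- rep(seq_len(H), times = H)
  h2_of <- rep(seq_len(H), each = H)
  nd <- (hap_d(h1_of) == 2) + (hap_d(h2_of) == 2)
  gam <- matrix(0, S, H)
  for (s in seq_len(S)) {
    gam[s, h1_of[s]] <- gam[s, h1_of[s]] + (1 - theta) / 2
    gam[s, h2_of[s]] <- gam[s, h2_of[s]] + (1 - theta) / 2
    r1 <- (hap_d(h1_of[s]) - 1L) * A + hap_m(h2_of[s])
    r2 <- (hap_d(h2_of[s]) - 1L) * A + hap_m(h1_of[s])
    gam[s, r1] <- gam[s, r1] + theta / 2
    gam[s, r2] <- gam[s, r2] + theta / 2
  }
  jm <- 2L * (match(marker, attr(geno, "markers")) - 1L)
  n <- nrow(p)
  idx_f <- match(paste(p$family_id, p$father_id, sep = "/"), keys)
  idx_m <- match(paste(p$family_id, p$mother_id, sep = "/"), keys)
  wtab <- lapply(seq_len(n), function(i) {
    k <- keys[i]
    status <- if (k %in% names(affection)) affection[[k]] else "unknown"
    f <- model$penetrance[nd + 1]
    v <- switch(status, affected = f, unaffected = 1 - f, rep(1, S))
    pair <- as.integer(geno[match(k, rownames(geno)),
                            c(jm + 1L, jm + 2L)])
    if (!any(is.na(pair))) {
      m1 <- hap_m(h1_of); m2 <- hap_m(h2_of)
      v <- v * ((m1 == pair[1] & m2 == pair[2]) |
                  (m1 == pair[2] & m2 == pair[1]))
    }
    if (is.na(idx_f[i])) v <- v * hapfreq[h1_of] * hapfreq[h2_of]
    v
  })
  # vectorized enumeration over the first five people, loop over the rest
  n_vec <- min(n, 5L)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), n_vec)))
  base <- rep(1, nrow(grid))
  for (i in seq_len(n_vec)) base <- base * wtab[[i]][grid[, i]]
  eval_tail <- function(tail_states) {
    v <- base
    st <- function(i) if (i <= n_vec) grid[, i]
                      else rep(tail_states[i - n_vec], nrow(grid))
    if (n > n_vec)
      for (i in seq(n_vec + 1, n)) v <- v * wtab[[i]][st(i)]
    for (i in seq_len(n)) {
      if (is.na(idx_f[i])) next
      si <- st(i)
      v <- v * gam[cbind(st(idx_f[i]), h1_of[si])] *
        gam[cbind(st(idx_m[i]), h2_of[si])]
    }
    sum(v)
  }
  total <- if (n <= n_vec) eval_tail(integer(0))
  else {
    tails <- as.matrix(expand.grid(rep(list(seq_len(S)), n - n_vec)))
    sum(vapply(seq_len(nrow(tails)), function(r)
      eval_tail(tails[r, ]), 0))
  }
  log(total)
}

# ---- random small pedigrees for likelihood oracle sweeps ------------------
random_small_pedigree <- function(seed) {
  set.seed(seed)
  shape <- sample(c("trio", "quad", "quint", "threegen"), 1)
  fam <- "F1"
  if (shape == "trio") {
    ped <- pedigree(rep(fam, 3), c("1", "2", "3"), c(NA, NA, "1"),
                    c(NA, NA, "2"), c("male", "female", "unknown"))
  } else if (shape == "quad") {
    ped <- pedigree(rep(fam, 4), as.character(1:4),
                    c(NA, NA, "1", "1"), c(NA, NA, "2", "2"),
                    c("male", "female", "male", "female"))
  } else if (shape == "quint") {
    ped <- pedigree(rep(fam, 5), as.character(1:5),
                    c(NA, NA, "1", "1", "1"), c(NA, NA, "2", "2", "2"),
                    c("male", "female", rep("unknown", 3)))
  } else {
    # grandparents -> father; mother marries in; two grandchildren
    ped <- pedigree(rep(fam, 6), as.character(1:6),
                    c(NA, NA, "1", NA, "3", "3"),
                    c(NA, NA, "2", NA, "4", "4"),
                    c("male", "female", "male", "female",
                      "unknown", "unknown"))
  }
  n <- nrow(ped)
  al <- matrix(sample(1:2, 2 * n, replace = TRUE), n, 2)
  al[runif(n) < 0.2, ] <- NA            # some untyped individuals
  geno <- genotype_table(al, "M1", paste(fam, ped$id, sep = "/"))
  aff <- sample(c("affected", "unaffected", "unknown"), n, replace = TRUE)
  names(aff) <- paste(fam, ped$id, sep = "/")
  list(ped = ped, geno = geno, affection = aff,
       freqs = stats::setNames(c(0.6, 0.4), c("1", "2")))
}

# ---- trio transmission enumeration (Mendelian oracle) ---------------------
oracle_trio_consistent <- function(child, father, mother, alleles) {
  if (any(is.na(child))) return(TRUE)
  opts <- function(g) if (any(is.na(g))) alleles else g
  for (a in opts(father)) for (b in opts(mother))
    if (all(sort(c(a, b)) == sort(child))) return(TRUE)
  FALSE
}

# phase-known fully informative pedigree whose maximum LOD is N*log10(2):
# affected grandfather 1/1 x unaffected grandmother 2/2 fix the father's
# phase (disease with marker allele 1); each nonrecombinant child
# contributes log10(2) at theta = 0 under a fully penetrant dominant model.
nonrecombinant_family <- function(N) {
  ids <- c("gf", "gm", "fa", "mo", paste0("c", seq_len(N)))
  ped <- pedigree(rep("F1", 4 + N), ids,
                  c(NA, NA, "gf", NA, rep("fa", N)),
                  c(NA, NA, "gm", NA, rep("mo", N)),
                  c("male", "female", "male", "female", rep("male", N)))
  al <- rbind(c(1, 1), c(2, 2), c(1, 2), c(3, 4))
  aff <- c("affected", "unaffected", "affected", "unaffected")
  for (i in seq_len(N)) {
    if (i %% 2 == 1) { al <- rbind(al, c(1, 3)); aff <- c(aff, "affected") }
    else { al <- rbind(al, c(2, 4)); aff <- c(aff, "unaffected") }
  }
  keys <- paste("F1", ids, sep = "/")
  names(aff) <- keys
  list(ped = ped, geno = genotype_table(al, "M1", keys), affection = aff,
       freqs = stats::setNames(rep(0.25, 4), as.character(1:4)))
}

# random binary/ordinal trait matrices over a handful of individuals
random_trait_matrix <- function(n_ind, n_char, p_ordinal = 0, p_missing = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kind <- ifelse(runif(n_char) < p_ordinal, "ordinal4", "dichotomous")
  st <- vapply(seq_len(n_char), function(j)
    if (kind[j] == "ordinal4") sample(0:3, n_ind, replace = TRUE)
    else sample(0:1, n_ind, replace = TRUE), integer(n_ind))
  st <- matrix(st, n_ind, n_char)
  if (p_missing > 0) st[runif(length(st)) < p_missing] <- NA
  trait_matrix(st, rep("F", n_ind), as.character(seq_len(n_ind)),
               trait_kind = kind)
}
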