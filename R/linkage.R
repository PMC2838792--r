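#' The four standard genetic models
#'
#' Two-point parametric linkage is run under four single-locus models:
#' a fully penetrant dominant (Dom-1, disease allele frequency 0.01), a
#' fully penetrant recessive (Rec-1, frequency 0.09), a 55%-penetrant
#' dominant with phenocopy rate 0.0005 (Dom-2, frequency 0.01), and a
#' 55%-penetrant recessive with phenocopy rate 0.0005 (Rec-2, frequency
#' 0.09). Penetrances are given for 0/1/2 copies of the disease allele.
#'
#' @return named list of models, each `list(name, q, penetrance)`.
#' @export
genetic_models <- function() {
  list(
    `Dom-1` = list(name = "Dom-1", q = 0.01, penetrance = c(0, 1, 1)),
    `Rec-1` = list(name = "Rec-1", q = 0.09, penetrance = c(0, 0, 1)),
    `Dom-2` = list(name = "Dom-2", q = 0.01,
                   penetrance = c(0.0005, 0.55, 0.55)),
    `Rec-2` = list(name = "Rec-2", q = 0.09,
                   penetrance = c(0.0005, 0.0005, 0.55))
  )
}

#' Default recombination-fraction grid
#' @return numeric vector of theta values in `[0, 0.5]`.
#' @export
default_theta_grid <- function() c(0, 0.01, seq(0.05, 0.5, by = 0.05))

# ---- joint disease-marker state space -------------------------------------
# A marker with A alleles gives H = 2A haplotypes, indexed
# h = (d - 1) * A + m with d = 1 (normal) or 2 (disease) and m the marker
# allele. A person's state is an ordered haplotype pair
# s = h1 + (h2 - 1) * H (h1 = paternal), so state vectors have length H^2.

# gamete-transmission matrix T[s, h] for recombination fraction theta
transmission_matrix <- function(A, theta) {
  H <- 2L * A
  h1 <- rep(seq_len(H), times = H)
  h2 <- rep(seq_len(H), each = H)
  d1 <- (h1 - 1L) %/% A; m1 <- (h1 - 1L) %% A
  d2 <- (h2 - 1L) %/% A; m2 <- (h2 - 1L) %% A
  g_pr <- d1 * A + m2 + 1L          # d from hap1, marker from hap2
  g_rp <- d2 * A + m1 + 1L
  s <- seq_len(H * H)
  T <- matrix(0, H * H, H)
  add <- function(g, p) {
    idx <- cbind(s, g)
    T[idx] <<- T[idx] + p
  }
  add(h1, (1 - theta) / 2)
  add(h2, (1 - theta) / 2)
  add(g_pr, theta / 2)
  add(g_rp, theta / 2)
  T
}

# founder state prior under Hardy-Weinberg and linkage equilibrium
founder_prior <- function(freqs, q) {
  A <- length(freqs)
  hap <- c((1 - q) * freqs, q * freqs)
  as.vector(outer(hap, hap))        # s = h1 + (h2-1)*H, column-major
}

# penetrance factor per state for one affection status
penetrance_vector <- function(A, penetrance, status) {
  H <- 2L * A
  h1 <- rep(seq_len(H), times = H)
  h2 <- rep(seq_len(H), each = H)
  nd <- (h1 - 1L) %/% A + (h2 - 1L) %/% A
  f <- penetrance[nd + 1L]
  switch(status, affected = f, unaffected = 1 - f,
         unknown = rep(1, H * H))
}

# marker-observation indicator per state for one (possibly untyped) genotype
observation_vector <- function(A, pair) {
  H <- 2L * A
  if (any(is.na(pair))) return(rep(1, H * H))
  h1 <- rep(seq_len(H), times = H)
  h2 <- rep(seq_len(H), each = H)
  m1 <- (h1 - 1L) %% A + 1L
  m2 <- (h2 - 1L) %% A + 1L
  as.numeric((m1 == pair[1] & m2 == pair[2]) |
             (m1 == pair[2] & m2 == pair[1]))
}

# ---- pedigree peeling ------------------------------------------------------
# Nuclear-family decomposition for one family; the "unit graph" connecting
# nuclear units through shared individuals must be a tree (no loops).
family_structure <- function(ped, fam) {
  p <- ped[ped$family_id == fam, , drop = FALSE]
  keys <- ind_key(p$family_id, p$id)
  nonf <- which(!is.na(p$father_id))
  couple <- unique(data.frame(
    f = ind_key(p$family_id[nonf], p$father_id[nonf]),
    m = ind_key(p$family_id[nonf], p$mother_id[nonf]),
    stringsAsFactors = FALSE))
  units <- lapply(seq_len(nrow(couple)), function(i) {
    ch <- keys[nonf][p$father_id[nonf] == sub("^.*/", "", couple$f[i]) &
                     p$mother_id[nonf] == sub("^.*/", "", couple$m[i])]
    list(father = couple$f[i], mother = couple$m[i], children = ch)
  })
  n_units <- length(units)
  if (n_units == 0)
    return(list(keys = keys, units = list(), order = integer(0),
                connector = character(0)))
  unit_people <- lapply(units, function(u) c(u$father, u$mother, u$children))
  # tree check on the bipartite person-unit incidence graph
  people_in <- unique(unlist(unit_people))
  n_edges <- sum(lengths(unit_people))
  if (n_edges != length(people_in) + n_units - 1)
    stop("family ", fam, " contains a loop; loop-breaking is not supported")
  # BFS over units from unit 1 through shared individuals
  parent_unit <- rep(NA_integer_, n_units)
  connector <- rep(NA_character_, n_units)
  visited <- c(TRUE, rep(FALSE, n_units - 1))
  queue <- 1L
  bfs <- 1L
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in seq_len(n_units)) {
      if (visited[v]) next
      shared <- intersect(unit_people[[u]], unit_people[[v]])
      if (length(shared)) {
        visited[v] <- TRUE
        parent_unit[v] <- u
        connector[v] <- shared[1]
        queue <- c(queue, v)
        bfs <- c(bfs, v)
      }
    }
  }
  if (!all(visited))
    stop("family ", fam, ": disconnected mating structure")
  list(keys = keys, units = units, order = rev(bfs), connector = connector,
       founders = keys[is.na(p$father_id)])
}

# Exact single-family log-likelihood at one theta by peeling nuclear units.
# w: named list of per-individual state weights (prior x penetrance x
# marker observation). Messages are max-normalized against underflow with
# the scale tracked exactly; returns log L (-Inf for zero likelihood).
peel_family_exact <- function(struct, w, T) {
  H <- ncol(T)
  logscale <- 0
  if (!length(struct$units)) {
    tot <- 0
    for (k in struct$keys) tot <- tot + log(sum(w[[k]]))
    return(tot)
  }
  child_factor <- function(wc) {
    M <- matrix(wc, H, H)
    T %*% M %*% t(T)
  }
  msgs <- setNames(vector("list", length(struct$keys)), struct$keys)
  wt <- function(k) {
    v <- w[[k]]
    if (!is.null(msgs[[k]])) for (m in msgs[[k]]) v <- v * m
    v
  }
  for (ui in seq_along(struct$order)) {
    u <- struct$order[ui]
    unit <- struct$units[[u]]
    conn <- struct$connector[u]
    is_root <- ui == length(struct$order)
    wf <- wt(unit$father); wm <- wt(unit$mother)
    if (is_root || (conn %in% c(unit$father, unit$mother))) {
      K <- NULL
      for (ch in unit$children) {
        C <- child_factor(wt(ch))
        K <- if (is.null(K)) C else K * C
      }
      if (is.null(K)) K <- matrix(1, H * H, H * H)
      if (is_root) {
        tot <- sum(wf * (K %*% wm))
        if (tot <= 0) return(-Inf)
        return(log(tot) + logscale)
      }
      # the message excludes the connector's own weight, which is applied
      # once when the neighboring unit absorbs wt(conn)
      mu <- if (conn == unit$father) as.vector(K %*% wm)
            else as.vector(crossprod(K, wf))
    } else {
      K <- NULL
      for (ch in setdiff(unit$children, conn)) {
        C <- child_factor(wt(ch))
        K <- if (is.null(K)) C else K * C
      }
      U <- outer(wf, wm)
      if (!is.null(K)) U <- U * K
      mu <- as.vector(crossprod(T, U) %*% T)
    }
    mx <- max(mu)
    if (mx <= 0) return(-Inf)
    logscale <- logscale + log(mx)
    msgs[[conn]] <- c(msgs[[conn]], list(mu / mx))
  }
  stop("unreachable")
}

# per-individual state weights for one family/marker/model
state_weights <- function(struct, affection, geno, marker, A, prior,
                          pen_tab) {
  pair_mat <- geno_pair(geno, marker, struct$keys)
  w <- vector("list", length(struct$keys))
  names(w) <- struct$keys
  for (k in struct$keys) {
    status <- if (k %in% names(affection)) affection[[k]] else "unknown"
    v <- pen_tab[[status]] * observation_vector(A, pair_mat[k, ])
    if (k %in% struct$founders) v <- v * prior
    w[[k]] <- v
  }
  w
}

#' Two-point LOD curve for one family
#'
#' Exact pedigree likelihood by Elston-Stewart peeling over the joint
#' disease-marker state space: founders carry Hardy-Weinberg priors at the
#' disease locus (frequency `model$q`) and the marker, transmission
#' recombines with fraction theta, penetrance applies to the affection
#' coding (unknown contributes a factor 1), and untyped marker genotypes are
#' summed over. Returns `log10 L(theta) / L(0.5)` on the grid.
#'
#' @param ped a [pedigree()]; @param fam family id.
#' @param affection named coding vector from [affection_coding()].
#' @param geno a [genotype_table()]; @param marker marker name.
#' @param model one element of [genetic_models()].
#' @param freqs named allele-frequency vector for the marker.
#' @param theta_grid recombination fractions (default
#'   [default_theta_grid()]).
#' @return numeric LOD vector over `theta_grid`; all-`NA` (with a warning)
#'   if the family is Mendelian-inconsistent at the marker.
#' @export
family_lod_curve <- function(ped, fam, affection, geno, marker, model,
                             freqs, theta_grid = default_theta_grid()) {
  struct <- family_structure(ped, fam)
  A <- length(freqs)
  prior <- founder_prior(freqs, model$q)
  pen_tab <- list(
    affected = penetrance_vector(A, model$penetrance, "affected"),
    unaffected = penetrance_vector(A, model$penetrance, "unaffected"),
    unknown = penetrance_vector(A, model$penetrance, "unknown"))
  w <- state_weights(struct, affection, geno, marker, A, prior, pen_tab)
  ll <- vapply(theta_grid, function(th)
    peel_family_exact(struct, w, transmission_matrix(A, th)), 0)
  ll_half <- peel_family_exact(struct, w, transmission_matrix(A, 0.5))
  if (!is.finite(ll_half)) {
    warning("family ", fam, " at ", marker,
            ": zero likelihood (Mendelian inconsistency); excluded")
    return(rep(NA_real_, length(theta_grid)))
  }
  (ll - ll_half) / log(10)
}

#' Admixture heterogeneity LOD (HLOD)
#'
#' Maximizes `HLOD(alpha, theta) = sum_fam log10(alpha 10^lod_fam(theta) +
#' (1 - alpha))` over an alpha grid (step 0.01, golden-section refinement)
#' and the theta grid; the joint test compares the maximum to the null of
#' no linkage and no heterogeneity. At `alpha = 1` the HLOD equals the
#' homogeneity LOD.
#'
#' @param family_curves matrix (families x theta) of per-family LOD scores.
#' @param theta_grid the grid the curves were evaluated on.
#' @param alpha_step grid step for the admixture proportion.
#' @return list: `hlod`, `alpha`, `theta`, `homog_lod`,
#'   `homog_theta`.
#' @export
hlod_admixture <- function(family_curves, theta_grid = default_theta_grid(),
                           alpha_step = 0.01) {
  fc <- as.matrix(family_curves)
  fc <- fc[stats::complete.cases(fc), , drop = FALSE]
  if (!nrow(fc)) stop("no family curves")
  alphas <- seq(0, 1, by = alpha_step)
  best <- c(hlod = -Inf, alpha = 0, theta = 0)
  hl_at <- function(alpha, v) sum(log10(alpha * v + (1 - alpha)))
  for (j in seq_along(theta_grid)) {
    v <- 10^fc[, j]
    hs <- vapply(alphas, hl_at, 0, v = v)
    b <- which.max(hs)
    h <- hs[b]; a <- alphas[b]
    # golden-section refinement inside the bracketing grid cells
    lo <- max(0, a - alpha_step); hi <- min(1, a + alpha_step)
    op <- stats::optimize(function(x) hl_at(x, v), c(lo, hi), maximum = TRUE)
    if (op$objective > h) { h <- op$objective; a <- op$maximum }
    if (h > best["hlod"] + 1e-12) {
      best <- c(hlod = h, alpha = a, theta = theta_grid[j])
    }
  }
  sums <- colSums(fc)
  list(hlod = unname(best["hlod"]), alpha = unname(best["alpha"]),
       theta = unname(best["theta"]),
       homog_lod = max(sums), homog_theta = theta_grid[which.max(sums)])
}

#' Clade-conditioned two-point linkage scan
#'
#' For every retained clade, marker, and genetic model: derives the clade's
#' affection coding, computes per-family LOD curves by exact peeling, and
#' maximizes both the homogeneity LOD and the admixture HLOD. Families with
#' a Mendelian inconsistency at a marker are excluded from that marker with
#' a warning (raised by [family_lod_curve()]).
#'
#' @param clades a `clade_set` (already filtered, see [filter_clades()]).
#' @param ped a [pedigree()]; @param geno a [genotype_table()].
#' @param map a [genetic_map()] supplying marker order and allele
#'   frequencies.
#' @param models list of models (default all four of [genetic_models()]).
#' @param traits optional [trait_matrix()] so unscored relatives are coded
#'   unknown.
#' @param theta_grid recombination grid.
#' @param markers optional subset of markers to scan.
#' @return object of class `linkage_result`: a data frame with one row per
#'   clade x marker x model (`max_lod`, `theta_lod`, `hlod`, `alpha`,
#'   `theta_hlod`, `n_families`).
#' @export
run_linkage <- function(clades, ped, geno, map, models = genetic_models(),
                        traits = NULL, theta_grid = default_theta_grid(),
                        markers = map_markers(map)) {
  rows <- list()
  excluded <- list()
  for (lab in clades$table$label) {
    code <- affection_coding(clade_members(clades, lab), ped, traits)
    fams <- attr(code, "families")
    structs <- lapply(fams, function(f) family_structure(ped, f))
    names(structs) <- fams
    for (marker in markers) {
      freqs <- map$freqs[[marker]]
      A <- length(freqs)
      pairs <- geno_pair(geno, marker)
      for (model in models) {
        prior <- founder_prior(freqs, model$q)
        pen_tab <- list(
          affected = penetrance_vector(A, model$penetrance, "affected"),
          unaffected = penetrance_vector(A, model$penetrance, "unaffected"),
          unknown = penetrance_vector(A, model$penetrance, "unknown"))
        Ts <- lapply(theta_grid, function(th) transmission_matrix(A, th))
        T_half <- transmission_matrix(A, 0.5)
        curves <- matrix(NA_real_, length(fams), length(theta_grid))
        for (fi in seq_along(fams)) {
          struct <- structs[[fi]]
          w <- state_weights(struct, code, geno, marker, A, prior, pen_tab)
          ll_half <- peel_family_exact(struct, w, T_half)
          if (!is.finite(ll_half)) {
            # zero likelihood: Mendelian inconsistency at the marker or an
            # affection pattern impossible under this (e.g. fully
            # penetrant) model; family dropped for this test only
            excluded[[length(excluded) + 1L]] <- data.frame(
              clade = lab, marker = marker, model = model$name,
              family = fams[fi], stringsAsFactors = FALSE)
            next
          }
          curves[fi, ] <- vapply(seq_along(theta_grid), function(j)
            peel_family_exact(struct, w, Ts[[j]]) - ll_half, 0) / log(10)
        }
        ok <- stats::complete.cases(curves)
        if (!any(ok)) next
        sums <- colSums(curves[ok, , drop = FALSE])
        hl <- hlod_admixture(curves[ok, , drop = FALSE], theta_grid)
        rows[[length(rows) + 1L]] <- data.frame(
          clade = lab, marker = marker, model = model$name,
          max_lod = max(sums), theta_lod = theta_grid[which.max(sums)],
          hlod = hl$hlod, alpha = hl$alpha, theta_hlod = hl$theta,
          n_families = sum(ok), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  excl <- if (length(excluded)) do.call(rbind, excluded)
          else data.frame(clade = character(), marker = character(),
                          model = character(), family = character(),
                          stringsAsFactors = FALSE)
  if (nrow(excl))
    warning(nrow(excl), " family x test combinations had zero likelihood ",
            "(model-incompatible or Mendelian-inconsistent) and were ",
            "excluded; see attr(result, 'excluded')")
  attr(out, "excluded") <- excl
  class(out) <- c("linkage_result", "data.frame")
  out
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("Linkage results:", nrow(x), "clade x marker x model tests\n")
  print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Per-clade maximum linkage summary
#'
#' One row per clade: the maximum score over all markers, genetic models
#' and analysis schemes (homogeneity LOD and HLOD), with the marker, model,
#' admixture proportion, and theta at which it is attained.
#'
#' @param object a `linkage_result`; @param ... unused.
#' @return data frame, one row per clade.
#' @export
summary.linkage_result <- function(object, ...) {
  df <- as.data.frame(object)
  df$zmax <- pmax(df$max_lod, df$hlod)
  out <- do.call(rbind, lapply(split(df, df$clade), function(d) {
    b <- d[which.max(d$zmax), ]
    data.frame(clade = b$clade, zmax = b$zmax, alpha = b$alpha,
               marker = b$marker, model = b$model,
               theta = b$theta_hlod, n_families = b$n_families,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(-out$zmax), ]
}
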