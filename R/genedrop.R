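#' Haldane map function
#'
#' Converts a centimorgan distance to a recombination fraction,
#' `theta = (1 - exp(-2d/100)) / 2`; Kosambi offered as an alternative.
#'
#' @param d_cM distance in centimorgans.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return recombination fraction in `[0, 0.5)`.
#' @export
cM_to_theta <- function(d_cM, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  d <- d_cM / 100
  switch(map_function,
         haldane = (1 - exp(-2 * d)) / 2,
         kosambi = tanh(2 * d) / 2)
}

#' Gene-drop a genotype replicate
#'
#' Randomly assigns genotypes to the founders of each family from the
#' marker allele frequencies (linkage equilibrium across markers) and mates
#' individuals within families according to the pedigree structure,
#' transmitting haplotypes with recombination between adjacent markers given
#' by the map function on the cM gaps. The observed missingness pattern is
#' re-applied, so which (individual, marker) cells are typed is identical to
#' the observed data.
#'
#' @param ped a [pedigree()]; @param map a [genetic_map()].
#' @param founder_freqs named list per marker of allele frequencies; default
#'   takes the map's frequencies.
#' @param missingness_mask logical matrix (individuals x markers, rownames =
#'   keys) marking untyped cells, or a [genotype_table()] whose `NA` pattern
#'   is copied; `NULL` types everyone.
#' @param seed integer seed.
#' @param map_function see [cM_to_theta()].
#' @return a [genotype_table()].
#' @export
gene_drop <- function(ped, map, founder_freqs = NULL,
                      missingness_mask = NULL, seed = NULL,
                      map_function = "haldane") {
  markers <- map_markers(map)
  nm <- length(markers)
  if (is.null(founder_freqs)) founder_freqs <- map$freqs
  freq_list <- lapply(markers, function(m) founder_freqs[[m]])
  allele_labels <- lapply(freq_list, function(f) as.integer(names(f)))
  # per-adjacent-gap recombination fraction; Inf gap (chromosome break) = 0.5
  chrom <- map$table$chrom
  gaps <- c(Inf, diff(map$table$pos_cM))
  gaps[c(FALSE, chrom[-1] != chrom[-nm])] <- Inf
  theta <- ifelse(is.infinite(gaps), 0.5, cM_to_theta(gaps, map_function))
  keys <- ped_keys(ped)
  with_seed(seed, {
    hap1 <- matrix(0L, nrow(ped), nm, dimnames = list(keys, markers))
    hap2 <- hap1
    # parents before children
    done <- setNames(rep(FALSE, nrow(ped)), keys)
    pending <- seq_len(nrow(ped))
    while (length(pending)) {
      ready <- pending[vapply(pending, function(i) {
        is.na(ped$father_id[i]) ||
          (done[ind_key(ped$family_id[i], ped$father_id[i])] &&
           done[ind_key(ped$family_id[i], ped$mother_id[i])])
      }, TRUE)]
      for (i in ready) {
        if (is.na(ped$father_id[i])) {
          for (j in seq_len(nm)) {
            a <- allele_labels[[j]]
            hap1[i, j] <- a[sample.int(length(a), 1,
                                       prob = freq_list[[j]])]
            hap2[i, j] <- a[sample.int(length(a), 1,
                                       prob = freq_list[[j]])]
          }
        } else {
          fi <- match(ind_key(ped$family_id[i], ped$father_id[i]), keys)
          mi <- match(ind_key(ped$family_id[i], ped$mother_id[i]), keys)
          hap1[i, ] <- meiosis(hap1[fi, ], hap2[fi, ], theta)
          hap2[i, ] <- meiosis(hap1[mi, ], hap2[mi, ], theta)
        }
        done[i] <- TRUE
      }
      pending <- setdiff(pending, ready)
    }
    al <- matrix(0L, nrow(ped), 2 * nm)
    al[, seq(1, 2 * nm, by = 2)] <- hap1
    al[, seq(2, 2 * nm, by = 2)] <- hap2
    g <- genotype_table(al, markers, keys)
    if (!is.null(missingness_mask)) {
      if (inherits(missingness_mask, "genotype_table")) {
        mm <- is.na(missingness_mask[, seq(1, 2 * nm, by = 2), drop = FALSE])
        rownames(mm) <- rownames(missingness_mask)
        colnames(mm) <- markers
        missingness_mask <- mm
      }
      for (j in seq_len(nm)) {
        untyped <- rownames(missingness_mask)[missingness_mask[, j]]
        g[match(untyped, rownames(g)), c(2 * j - 1, 2 * j)] <- NA_integer_
      }
    }
    g
  })
}

# one recombinant gamete from an ordered pair of parental haplotypes;
# theta[j] is the recombination fraction between markers j-1 and j
# (theta[1] = 0.5 starts each chromosome at random phase)
meiosis <- function(h1, h2, theta) {
  nm <- length(h1)
  switch_now <- runif(nm) < theta
  phase <- cumsum(switch_now) %% 2L   # 0 = current source is h1 track
  # cumsum trick: each switch toggles the source haplotype
  ifelse(phase == 1L, h2, h1)
}

#' Generate a set of gene-drop replicates
#'
#' By default allele frequencies are the observed founder frequencies
#' (falling back to the map's when a marker has no typed founder), so the
#' replicates condition on the observed allele frequencies and intermarker
#' distances.
#'
#' @param ped,map see [gene_drop()].
#' @param geno observed [genotype_table()] providing the missingness mask
#'   and founder frequencies.
#' @param n_replicates number of replicates (default 100).
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param freq_source `"founders"` (default) or `"map"`.
#' @param map_function see [cM_to_theta()].
#' @return list of [genotype_table()]s, with attribute `seed`.
#' @export
make_replicates <- function(ped, map, geno, n_replicates = 100, seed = NULL,
                            freq_source = c("founders", "map"),
                            map_function = "haldane") {
  freq_source <- match.arg(freq_source)
  freqs <- map$freqs
  if (freq_source == "founders") {
    for (m in map_markers(map)) {
      est <- tryCatch(estimate_founder_allele_freqs(ped, geno, m),
                      error = function(e) NULL)
      if (!is.null(est)) freqs[[m]] <- est
    }
  }
  reps <- lapply(seq_len(n_replicates), function(r)
    gene_drop(ped, map, founder_freqs = freqs, missingness_mask = geno,
              seed = if (is.null(seed)) NULL else seed + r,
              map_function = map_function))
  attr(reps, "seed") <- seed
  reps
}

#' Model-based and global empirical p-values
#'
#' Compares each clade's observed maximum score (over all genetic models,
#' analysis schemes and markers) with the distribution of the corresponding
#' maxima in genotype replicates analyzed under the identical clade set,
#' models and markers. The model-based p-value `p_M` counts replicates whose
#' within-clade maximum reaches the observed clade maximum; the global
#' `p_G` counts replicates whose maximum across all clades reaches it. Both
#' use the add-one convention `( # + 1) / (R + 1)`.
#'
#' @param observed a `linkage_result` for the observed genotypes.
#' @param replicates list of `linkage_result`s, one per replicate.
#' @return data frame: clade, observed `zmax`, `p_M`, `p_G`, `n_replicates`.
#' @export
empirical_p <- function(observed, replicates) {
  if (!length(replicates)) stop("no replicates supplied")
  clade_max <- function(res) {
    df <- as.data.frame(res)
    z <- pmax(df$max_lod, df$hlod)
    tapply(z, df$clade, max)
  }
  obs <- clade_max(observed)
  rep_mat <- vapply(replicates, function(r) {
    m <- clade_max(r)
    m[names(obs)]
  }, numeric(length(obs)))
  rep_mat <- matrix(rep_mat, nrow = length(obs),
                    dimnames = list(names(obs), NULL))
  rep_global <- apply(rep_mat, 2, max, na.rm = TRUE)
  R <- length(replicates)
  p_m <- vapply(names(obs), function(cl)
    (sum(rep_mat[cl, ] >= obs[[cl]], na.rm = TRUE) + 1) / (R + 1), 0)
  p_g <- vapply(names(obs), function(cl)
    (sum(rep_global >= obs[[cl]]) + 1) / (R + 1), 0)
  data.frame(clade = names(obs), zmax = as.numeric(obs),
             p_M = p_m, p_G = p_g, n_replicates = R,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full empirical p-value procedure
#'
#' Generates `n_replicates` gene-drop replicates, re-runs the linkage scan
#' on each with the phenotype network and clades held fixed (only genotypes
#' are randomized), and returns [empirical_p()]'s table.
#'
#' @inheritParams run_linkage
#' @param n_replicates,seed,freq_source,map_function see
#'   [make_replicates()].
#' @return data frame as from [empirical_p()], with the observed
#'   `linkage_result` attached as attribute `observed`.
#' @export
run_empirical_pvalues <- function(clades, ped, geno, map,
                                  models = genetic_models(), traits = NULL,
                                  theta_grid = default_theta_grid(),
                                  markers = map_markers(map),
                                  n_replicates = 100, seed = NULL,
                                  freq_source = "founders",
                                  map_function = "haldane") {
  observed <- run_linkage(clades, ped, geno, map, models, traits,
                          theta_grid, markers)
  reps <- make_replicates(ped, map, geno, n_replicates, seed,
                          freq_source, map_function)
  rep_results <- lapply(reps, function(g)
    run_linkage(clades, ped, g, map, models, traits, theta_grid, markers))
  out <- empirical_p(observed, rep_results)
  attr(out, "observed") <- observed
  out
}
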