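#' Simulate a microsatellite marker panel
#'
#' Evenly spaced markers (default 416 markers across 10 chromosomes at
#' 7.5 cM) with Dirichlet-drawn allele frequencies, emulating a
#' genome-scan-era microsatellite panel.
#'
#' @param n_chrom number of chromosomes.
#' @param spacing_cM intermarker distance.
#' @param n_markers total markers, distributed as evenly as possible.
#' @param n_alleles alleles per marker.
#' @param seed integer seed.
#' @param concentration Dirichlet concentration per allele (default 2,
#'   avoiding near-degenerate frequencies).
#' @return a [genetic_map()].
#' @export
simulate_marker_panel <- function(n_chrom = 10, spacing_cM = 7.5,
                                  n_markers = 416, n_alleles = 8,
                                  seed = NULL, concentration = 2) {
  per <- rep(n_markers %/% n_chrom, n_chrom)
  extra <- n_markers %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  chrom <- rep(as.character(seq_len(n_chrom)), per)
  idx <- unlist(lapply(per, seq_len))
  marker <- paste0("C", chrom, "M", idx)
  pos <- (idx - 1) * spacing_cM
  with_seed(seed, {
    freqs <- lapply(marker, function(m) {
      if (n_alleles == 1) return(setNames(1, "1"))
      g <- stats::rgamma(n_alleles, shape = concentration)
      setNames(g / sum(g), as.character(seq_len(n_alleles)))
    })
    names(freqs) <- marker
    genetic_map(chrom, marker, pos, freqs)
  })
}

#' Configuration of the synthetic KPD study
#'
#' Defaults emulate the GAW14 Kofendred Personality Disorder simulation:
#' three populations (Aipotu, Karangar, Danacaa) of 100 families each,
#' ascertained so that at least two family members express a qualifying
#' latent phenotype (any of P1-P3 for Aipotu, P2/P3 for Karangar, P1 for
#' Danacaa); four epistatic disease loci D1-D4 plus penetrance-modifier
#' loci D5-D6; latent phenotypes expressed as overlapping trait sets over
#' twelve behavioral traits a-l (P1 = \{b,e,f,h\}, P2 = \{c..h\} without b,
#' P3 = \{c..h\} plus b) with a small background symptom noise rate; and a
#' 416-marker microsatellite panel at 7.5 cM. The exact GAW14 penetrance
#' tables are not public, so the epistatic predicates and penetrance values
#' here are this package's own documented choices.
#'
#' @param n_families_per_pop families per population (default 100).
#' @param n_children children per nuclear family (default 4).
#' @param panel list passed to [simulate_marker_panel()] (fields `n_chrom`,
#'   `spacing_cM`, `n_markers`, `n_alleles`).
#' @param penetrance probability a disease genotype expresses its latent
#'   phenotype (default 0.9).
#' @param modifier_factor multiplicative penetrance factor in carriers of
#'   the relevant modifier locus (default 0.6).
#' @param noise_rate per-trait background presence probability (default
#'   0.02).
#' @param expression_prob probability each defining trait of an expressed
#'   latent phenotype is present (default 1).
#' @param max_redraws bound on ascertainment rejection redraws per family.
#' @return a `kpd_config` list.
#' @export
kpd_config <- function(n_families_per_pop = 100, n_children = 4,
                       panel = list(n_chrom = 10, spacing_cM = 7.5,
                                    n_markers = 416, n_alleles = 8),
                       penetrance = 0.9, modifier_factor = 0.6,
                       noise_rate = 0.02, expression_prob = 1,
                       max_redraws = 5000) {
  traits <- letters[1:12]
  cfg <- list(
    populations = list(
      list(name = "Aipotu", prefix = "A", n_families = n_families_per_pop,
           qualifying = c("P1", "P2", "P3"), min_count = 2),
      list(name = "Karangar", prefix = "K", n_families = n_families_per_pop,
           qualifying = c("P2", "P3"), min_count = 2),
      list(name = "Danacaa", prefix = "D", n_families = n_families_per_pop,
           qualifying = "P1", min_count = 2)
    ),
    disease_loci = list(
      D1 = list(chrom = "1", pos_cM = 26, freq = 0.35),
      D2 = list(chrom = "2", pos_cM = 26, freq = 0.30),
      D3 = list(chrom = "3", pos_cM = 26, freq = 0.35),
      D4 = list(chrom = "4", pos_cM = 26, freq = 0.20)
    ),
    modifier_loci = list(
      D5 = list(chrom = "5", pos_cM = 26, freq = 0.20, modifies = "P1"),
      D6 = list(chrom = "6", pos_cM = 26, freq = 0.20,
                modifies = c("P2", "P3"))
    ),
    # epistatic two-locus predicates: rec = two disease alleles,
    # dom = at least one
    latent_rules = list(
      P1 = list(list(D1 = "rec", D2 = "dom")),
      P2 = list(list(D2 = "rec", D3 = "dom"), list(D4 = "rec")),
      P3 = list(list(D2 = "dom", D3 = "rec"))
    ),
    trait_names = traits,
    trait_map = list(P1 = c("b", "e", "f", "h"),
                     P2 = c("c", "d", "e", "f", "g", "h"),
                     P3 = c("b", "c", "d", "e", "f", "g", "h")),
    n_children = n_children, panel = panel, penetrance = penetrance,
    modifier_factor = modifier_factor, noise_rate = noise_rate,
    expression_prob = expression_prob, max_redraws = max_redraws
  )
  class(cfg) <- "kpd_config"
  cfg
}

# genotype predicate over disease-allele counts (2 = two copies, 1 = carrier)
satisfies <- function(counts, clause) {
  all(vapply(names(clause), function(loc) {
    need <- clause[[loc]]
    if (need == "rec") counts[[loc]] == 2L else counts[[loc]] >= 1L
  }, TRUE))
}

#' Simulate a synthetic KPD family study
#'
#' Drops founder haplotypes through nuclear families with Haldane
#' recombination across the marker panel and the (unobserved) disease and
#' modifier loci, applies the epistatic genotype-to-latent-phenotype rules
#' with modifier-adjusted penetrance, expresses latent phenotypes as trait
#' sets plus background noise, and redraws each family until its
#' population's ascertainment rule holds.
#'
#' @param config a [kpd_config()].
#' @param seed integer seed.
#' @return list: `ped` ([pedigree()]; diagnosis = expressed phenotype),
#'   `geno` ([genotype_table()]), `traits` ([trait_matrix()]), `map`
#'   ([genetic_map()]), and a `truth` record (per-individual latent
#'   genotype and expression, plus the locus positions).
#' @export
simulate_kpd_study <- function(config = kpd_config(), seed = NULL) {
  map <- simulate_marker_panel(config$panel$n_chrom, config$panel$spacing_cM,
                               config$panel$n_markers,
                               config$panel$n_alleles,
                               seed = if (is.null(seed)) NULL else seed)
  with_seed(if (is.null(seed)) NULL else seed + 1L, {
    loci <- c(config$disease_loci, config$modifier_loci)
    # combined transmission map: markers plus hidden loci, ordered per
    # chromosome by position
    comb <- map$table
    comb$kind <- "marker"
    for (ln in names(loci)) {
      l <- loci[[ln]]
      comb <- rbind(comb, data.frame(chrom = l$chrom, marker = ln,
                                     pos_cM = l$pos_cM, kind = "locus"))
    }
    comb <- comb[order(as.numeric(comb$chrom), comb$pos_cM), ]
    nm <- nrow(comb)
    gaps <- c(Inf, diff(comb$pos_cM))
    gaps[c(FALSE, comb$chrom[-1] != comb$chrom[-nm])] <- Inf
    theta <- ifelse(is.infinite(gaps), 0.5, cM_to_theta(gaps))
    # per-position allele labels and frequencies (hidden loci biallelic;
    # allele 2 = disease/modifier allele)
    freq_list <- lapply(seq_len(nm), function(j) {
      if (comb$kind[j] == "marker") map$freqs[[comb$marker[j]]]
      else { q <- loci[[comb$marker[j]]]$freq; setNames(c(1 - q, q), 1:2) }
    })
    locus_idx <- setNames(match(names(loci), comb$marker), names(loci))
    marker_idx <- match(map$table$marker, comb$marker)
    n_ch <- config$n_children
    fam_n <- 2L + n_ch

    draw_family <- function() {
      # rows 1-2 founders, 3.. children; two haplotype matrices
      hap1 <- matrix(0L, fam_n, nm)
      hap2 <- matrix(0L, fam_n, nm)
      for (j in seq_len(nm)) {
        a <- as.integer(names(freq_list[[j]]))
        draws <- a[sample.int(length(a), 4, replace = TRUE,
                              prob = freq_list[[j]])]
        hap1[1:2, j] <- draws[1:2]
        hap2[1:2, j] <- draws[3:4]
      }
      for (i in 3:fam_n) {
        hap1[i, ] <- meiosis(hap1[1, ], hap2[1, ], theta)
        hap2[i, ] <- meiosis(hap1[2, ], hap2[2, ], theta)
      }
      counts <- lapply(names(loci), function(ln) {
        j <- locus_idx[[ln]]
        (hap1[, j] == 2L) + (hap2[, j] == 2L)
      })
      names(counts) <- names(loci)
      latent <- rep(NA_character_, fam_n)
      expressed <- rep(NA_character_, fam_n)
      for (i in seq_len(fam_n)) {
        ci <- lapply(counts, `[`, i)
        for (ph in names(config$latent_rules)) {
          hit <- any(vapply(config$latent_rules[[ph]], function(cl)
            satisfies(ci, cl), TRUE))
          if (hit) { latent[i] <- ph; break }
        }
        if (!is.na(latent[i])) {
          pen <- config$penetrance
          for (mn in names(config$modifier_loci)) {
            ml <- config$modifier_loci[[mn]]
            if (latent[i] %in% ml$modifies && ci[[mn]] >= 1L)
              pen <- pen * config$modifier_factor
          }
          if (runif(1) < pen) expressed[i] <- latent[i]
        }
      }
      list(hap1 = hap1, hap2 = hap2, latent = latent, expressed = expressed)
    }

    rows <- list(); gmat <- list(); tmat <- list(); truth_rows <- list()
    n_traits <- length(config$trait_names)
    for (pop in config$populations) {
      for (f in seq_len(pop$n_families)) {
        famid <- sprintf("%s%03d", pop$prefix, f)
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > config$max_redraws)
            stop("ascertainment unattainable for population ", pop$name,
                 " after ", config$max_redraws, " redraws")
          fd <- draw_family()
          if (sum(fd$expressed %in% pop$qualifying, na.rm = TRUE) >=
              pop$min_count) break
        }
        ids <- as.character(seq_len(fam_n))
        sex <- c("male", "female",
                 sample(c("male", "female"), n_ch, replace = TRUE))
        aff <- ifelse(is.na(fd$expressed), 1L, 2L)
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = famid, id = ids,
          father_id = c(NA, NA, rep("1", n_ch)),
          mother_id = c(NA, NA, rep("2", n_ch)),
          sex = sex, affection = aff,
          diagnosis = ifelse(is.na(fd$expressed), "unaffected",
                             fd$expressed),
          population = pop$name, stringsAsFactors = FALSE)
        al <- matrix(0L, fam_n, 2L * length(marker_idx))
        al[, seq(1, ncol(al), by = 2)] <- fd$hap1[, marker_idx]
        al[, seq(2, ncol(al), by = 2)] <- fd$hap2[, marker_idx]
        gmat[[length(gmat) + 1L]] <- al
        tm <- matrix(0L, fam_n, n_traits)
        for (i in seq_len(fam_n)) {
          if (!is.na(fd$expressed[i])) {
            def <- config$trait_map[[fd$expressed[i]]]
            on <- runif(length(def)) < config$expression_prob
            tm[i, match(def[on], config$trait_names)] <- 1L
          }
          noise <- runif(n_traits) < config$noise_rate
          tm[i, noise] <- 1L
        }
        tmat[[length(tmat) + 1L]] <- tm
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          key = ind_key(famid, ids), latent = fd$latent,
          expressed = fd$expressed, population = pop$name,
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    ped <- pedigree(tab$family_id, tab$id, tab$father_id, tab$mother_id,
                    tab$sex, tab$affection, tab$diagnosis)
    geno <- genotype_table(do.call(rbind, gmat), map$table$marker,
                           ped_keys(ped))
    tmx <- do.call(rbind, tmat)
    colnames(tmx) <- config$trait_names
    traits <- trait_matrix(tmx, tab$family_id, tab$id,
                           trait_kind = rep("dichotomous", n_traits))
    truth <- list(individuals = do.call(rbind, truth_rows),
                  loci = loci, config = config)
    list(ped = ped, geno = geno, traits = traits, map = map, truth = truth)
  })
}

#' Deterministic toy fixture: eight patients, ten symptoms
#'
#' Two blocks of four patients carry disjoint, perfectly compatible symptom
#' sets, so exhaustive parsimony search must separate the blocks; used in
#' documentation and tests.
#'
#' @return list: `traits` (a [trait_matrix()]) and `expected` (the two
#'   blocks of patient keys and the optimal score).
#' @export
make_toy_fixture <- function() {
  m <- rbind(
    #        s1 s2 s3 s4 s5 s6 s7 s8 s9 s10
    p1  = c( 1, 1, 0, 1, 1, 0, 0, 0, 0, 0),
    p2  = c( 1, 1, 0, 1, 0, 0, 0, 0, 0, 0),
    p3  = c( 1, 0, 1, 1, 0, 0, 0, 0, 0, 0),
    p4  = c( 1, 0, 1, 1, 0, 0, 0, 0, 0, 0),
    p5  = c( 0, 0, 0, 0, 0, 1, 1, 0, 1, 0),
    p6  = c( 0, 0, 0, 0, 0, 1, 1, 0, 1, 0),
    p7  = c( 0, 0, 0, 0, 0, 1, 0, 1, 1, 0),
    p8  = c( 0, 0, 0, 0, 0, 1, 0, 1, 1, 1))
  colnames(m) <- paste0("s", 1:10)
  traits <- trait_matrix(m, family_id = rep("T", 8), individual_id =
                           rownames(m))
  list(traits = traits,
       expected = list(block_a = ind_key("T", paste0("p", 1:4)),
                       block_b = ind_key("T", paste0("p", 5:8)),
                       optimal_score = 10))
}

#' Simulate a symptom cohort with diagnostic groups
#'
#' Bernoulli symptom draws per diagnostic group from given presence
#' probabilities, with optional profile mixing between groups; used for
#' calibration and power studies of the four-group likelihood-ratio test.
#'
#' @param n_individuals total cohort size, split evenly across groups.
#' @param diagnostic_groups character vector of group names.
#' @param symptom_profiles named list (per group) of per-trait presence
#'   probability vectors (equal lengths, shared trait names).
#' @param overlap in `[0, 1]`: each group's profile is mixed with the mean
#'   of all groups by this weight (0 = none).
#' @param seed integer seed.
#' @return list: `traits` (a [trait_matrix()], one family per individual)
#'   and `labels` (data frame key/diagnosis).
#' @export
simulate_symptom_cohort <- function(n_individuals, diagnostic_groups,
                                    symptom_profiles, overlap = 0,
                                    seed = NULL) {
  stopifnot(setequal(names(symptom_profiles), diagnostic_groups))
  probs <- do.call(rbind, symptom_profiles[diagnostic_groups])
  tn <- colnames(probs)
  if (is.null(tn)) tn <- paste0("t", seq_len(ncol(probs)))
  if (overlap > 0 && length(diagnostic_groups) > 1) {
    grand <- colMeans(probs)
    for (g in seq_len(nrow(probs)))
      probs[g, ] <- (1 - overlap) * probs[g, ] + overlap * grand
  }
  with_seed(seed, {
    grp <- rep_len(seq_along(diagnostic_groups), n_individuals)
    st <- matrix(0L, n_individuals, ncol(probs))
    for (i in seq_len(n_individuals))
      st[i, ] <- as.integer(runif(ncol(probs)) < probs[grp[i], ])
    colnames(st) <- tn
    fam <- sprintf("F%04d", seq_len(n_individuals))
    traits <- trait_matrix(st, fam, rep("1", n_individuals))
    list(traits = traits,
         labels = data.frame(key = ind_key(fam, "1"),
                             diagnosis = diagnostic_groups[grp],
                             stringsAsFactors = FALSE))
  })
}
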