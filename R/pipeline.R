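#' Assemble a pipeline run configuration
#'
#' Merges user settings over defaults. `x` may be a YAML file path or a
#' named list. Settings: either `input` (paths `ped`, `map`, `traits`,
#' optionally `diagnoses`) or `simulate` (arguments for [kpd_config()]);
#' `network` (`iterations`, `reweight_fraction`, `move`,
#' `consensus_threshold`); `clades` (`min_families`); `linkage` (`models`,
#' character subset of the four model names); `pvalues` (`n_replicates`);
#' `symptoms` (`n_perm`, `prevalence_threshold`); `seeds` (named integers
#' `simulate`, `network`, `replicates`, `permutations`); `out_dir`.
#'
#' @param x YAML path, named list, or `NULL` for pure defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(x = NULL) {
  defaults <- list(
    input = NULL,
    simulate = list(),
    network = list(iterations = 200, reweight_fraction = 0.25,
                   move = "spr", consensus_threshold = 0.51),
    clades = list(min_families = 40),
    linkage = list(models = names(genetic_models())),
    pvalues = list(n_replicates = 100),
    symptoms = list(n_perm = 1000, prevalence_threshold = 0.70),
    seeds = list(simulate = 1, network = 2, replicates = 3,
                 permutations = 4),
    out_dir = NULL
  )
  user <- if (is.null(x)) list()
          else if (is.character(x)) yaml::read_yaml(x)
          else x
  merge2 <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge2(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  cfg <- merge2(defaults, user)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the four-stage pipeline end to end
#'
#' Stage 1 estimates the behavioral network (ratchet search plus 51%
#' majority-rule consensus, rooted at an artificial asymptomatic outgroup);
#' stage 2 nests it into clades and applies the family-count filter; stage
#' 3 runs the clade-conditioned two-point linkage scan; stage 4 estimates
#' gene-drop empirical p-values and (when diagnostic labels are available)
#' symptom-profile likelihood-ratio tests. Results and a manifest recording
#' every seed and parameter are written to `out_dir` when set.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return list with elements `data`, `treeset`, `consensus`, `clades`,
#'   `linkage`, `linkage_summary`, `empirical`, `symptoms`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  # ---- data -------------------------------------------------------------
  if (!is.null(cfg$input)) {
    map <- read_map(cfg$input$map)
    pg <- read_ped(cfg$input$ped, map)
    traits <- read_traits(cfg$input$traits)
    if (nrow(traits) == 0 || ncol(traits) == 0)
      stop("stage 1 (network): empty trait matrix")
    diagnoses <- if (!is.null(cfg$input$diagnoses))
      read_diagnoses(cfg$input$diagnoses) else NULL
    data <- list(ped = pg$pedigree, geno = pg$genotypes, traits = traits,
                 map = map, truth = NULL)
  } else {
    kc <- do.call(kpd_config, cfg$simulate)
    data <- simulate_kpd_study(kc, seed = cfg$seeds$simulate)
    diagnoses <- data.frame(key = ped_keys(data$ped),
                            family_id = data$ped$family_id,
                            individual_id = data$ped$id,
                            diagnosis = data$ped$diagnosis,
                            stringsAsFactors = FALSE)
  }
  # ---- stage 1: network -------------------------------------------------
  aug <- add_outgroup(data$traits)
  ts <- ratchet_search(aug,
                       n_iterations = cfg$network$iterations,
                       reweight_fraction = cfg$network$reweight_fraction,
                       move = cfg$network$move,
                       seed = cfg$seeds$network)
  cons <- majority_consensus(ts, threshold = cfg$network$consensus_threshold)
  # ---- stage 2: nesting + filter ---------------------------------------
  clades_all <- nest_tree(cons)
  clades <- filter_clades(clades_all, data$ped,
                          min_families = cfg$clades$min_families)
  if (!nrow(clades$table))
    warning("no clade passes the ", cfg$clades$min_families,
            "-family filter")
  # ---- stage 3: linkage -------------------------------------------------
  models <- genetic_models()[cfg$linkage$models]
  linkage <- if (nrow(clades$table))
    run_linkage(clades, data$ped, data$geno, data$map, models = models,
                traits = data$traits) else NULL
  linkage_summary <- if (!is.null(linkage)) summary(linkage) else NULL
  # ---- stage 4: significance -------------------------------------------
  empirical <- if (!is.null(linkage))
    run_empirical_pvalues(clades, data$ped, data$geno, data$map,
                          models = models, traits = data$traits,
                          n_replicates = cfg$pvalues$n_replicates,
                          seed = cfg$seeds$replicates) else NULL
  symptoms <- if (!is.null(diagnoses) && nrow(clades$table))
    symptom_significance(clades, data$traits, diagnoses,
                         prevalence_threshold =
                           cfg$symptoms$prevalence_threshold,
                         n_perm = cfg$symptoms$n_perm,
                         seed = cfg$seeds$permutations) else NULL
  out <- list(data = data, treeset = ts, consensus = cons,
              clades_all = clades_all, clades = clades, linkage = linkage,
              linkage_summary = linkage_summary, empirical = empirical,
              symptoms = symptoms, config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(res$consensus, file.path(dir, "consensus.nwk"))
  ct <- res$clades_all$table
  ct$members <- vapply(res$clades_all$members[ct$label],
                       paste, "", collapse = ",")
  write.table(ct, file.path(dir, "clades.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  wr <- function(obj, f) if (!is.null(obj))
    write.table(as.data.frame(obj), file.path(dir, f), sep = "\t",
                row.names = FALSE, quote = FALSE)
  wr(res$linkage, "linkage.tsv")
  wr(res$linkage_summary, "linkage_summary.tsv")
  wr(res$empirical, "empirical_p.tsv")
  wr(res$symptoms, "symptoms.tsv")
  manifest <- res$config
  class(manifest) <- NULL
  manifest$package_version <- as.character(utils::packageVersion("cladelink"))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
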