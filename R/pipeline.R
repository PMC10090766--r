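#' Run the full distance-decay analysis pipeline
#'
#' Orchestrates the complete analysis on one dataset:
#' validate -> community descriptors -> similarity / p-distance /
#' geographic distance matrices -> PERMANOVA (presence and total
#' abundance), PERMDISP, pairwise PERMANOVA -> distance-decay regressions
#' (three metrics, with permutation tests) -> richness GLMs ->
#' accumulation curve. Per-stage results are written as CSV/JSON under
#' `out_dir`, together with a run manifest recording input file hashes,
#' seeds and the package version. Uninfected individuals are retained in
#' the data but excluded before the infracommunity-level multivariate
#' tests and the accumulation curve; host species must each retain at
#' least two individuals to enter PERMDISP.
#'
#' @param config either a path to a YAML file or a list. Recognised
#'   fields: `infections`, `sites`, `alignment`, `hosts` (input file
#'   paths; `hosts` optional), or `simulate: yes` with an optional
#'   `simulation` sub-list of [simulation_config()] arguments; `n_perm`
#'   (default 999), `n_perm_accumulation` (default 1000), `seed` (default
#'   1), `epsilon` (default 0), `out_dir` (default `"paradecay_results"`).
#' @return the manifest list, invisibly. Components: `stages` (named
#'   character of completed stages), `inputs` (md5 hashes), `seed`,
#'   `n_perm`, `package_version`, and the in-memory `results`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  n_perm <- config$n_perm %||% 999L
  n_perm_acc <- config$n_perm_accumulation %||% 1000L
  seed <- as.integer(config$seed %||% 1L)
  epsilon <- config$epsilon %||% 0
  out_dir <- config$out_dir %||% "paradecay_results"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  results <- list()
  input_hashes <- list()
  stage <- function(name, code) {
    message(sprintf("[paradecay] stage: %s", name))
    val <- tryCatch(force(code), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    val
  }

  if (isTRUE(config$simulate)) {
    cfg <- do.call(simulation_config,
                   c(config$simulation %||% list(), list(seed = seed)))
    ds <- stage("simulate", generate_dataset(cfg))
    infections <- ds$infections; sites <- ds$sites; aln <- ds$alignment
    hosts <- ds$hosts
    site_of_species <- ds$site_of_species
  } else {
    for (f in c("infections", "sites", "alignment")) {
      if (is.null(config[[f]])) stop("config must name input '", f, "'",
                                     call. = FALSE)
      if (!file.exists(config[[f]])) {
        stop(sprintf("input file for '%s' not found: %s", f, config[[f]]),
             call. = FALSE)
      }
      input_hashes[[f]] <- unname(tools::md5sum(config[[f]]))
    }
    infections <- stage("read", read_infection_csv(config$infections))
    sites <- read_sites_csv(config$sites)
    aln <- read_fasta_alignment(config$alignment)
    hosts <- NULL
    if (!is.null(config$hosts)) {
      input_hashes$hosts <- unname(tools::md5sum(config$hosts))
      hosts <- read_hosts_csv(config$hosts)
    }
    site_of_species <- majority_site_of_species(
      infections, override = unlist(config$site_override))
  }

  report <- stage("validate", {
    r <- validate_dataset(infections, sites, aln)
    write_validation_json(r, file.path(out_dir, "validation.json"))
    if (!r$ok) {
      stop("dataset failed validation (see validation.json): species ",
           "without sequence or individuals at unknown sites")
    }
    r
  })

  results$descriptors <- stage("descriptors", {
    infra <- infracommunity(infections)
    prof <- component_profiles(infections)
    utils::write.csv(infra, file.path(out_dir, "infracommunities.csv"),
                     row.names = FALSE)
    write_descriptors_csv(prof, file.path(out_dir, "component_descriptors.csv"))
    list(infracommunity = infra, profiles = prof)
  })

  results$distances <- stage("distances", {
    dphy <- p_distance_matrix(aln)
    dgeo <- geographic_distance_matrix(sites, site_of_species)
    write_distance_csv(dphy, file.path(out_dir, "p_distance.csv"))
    write_distance_csv(dgeo, file.path(out_dir, "geographic_km.csv"))
    list(phylo = dphy, geo = dgeo)
  })

  results$multivariate <- stage("multivariate", {
    inf2 <- drop_uninfected(infections)
    pres <- presence_matrix(inf2)
    dj <- as_dissimilarity(similarity_matrix(pres, "jaccard"))
    dbc <- as_dissimilarity(similarity_matrix(inf2$counts + 0, "braycurtis"))
    groups <- inf2$species
    keep2 <- names(groups)[groups %in% names(which(table(groups) >= 2))]
    mv <- list(
      permanova_presence = permanova(dj, groups, n_perm, seed = seed),
      permanova_abundance = permanova(dbc, groups, n_perm, seed = seed + 1L),
      permdisp_presence = permdisp(dm_subset(dj, keep2), groups[keep2],
                                   n_perm, seed = seed + 2L),
      permdisp_abundance = permdisp(dm_subset(dbc, keep2), groups[keep2],
                                    n_perm, seed = seed + 3L),
      pairwise_presence = pairwise_permanova(dm_subset(dj, keep2),
                                             groups[keep2], n_perm,
                                             seed = seed + 4L),
      ordination = pcoa(dj, n_axes = 2L),
      dendrogram_presence = hac_average_linkage(
        as_dissimilarity(similarity_matrix(
          component_profiles(infections)$presence, "jaccard"))))
    jsonlite::write_json(list(
      permanova_presence = unclass(mv$permanova_presence)[
        c("pseudo_F", "df_between", "df_within", "R2", "p_perm")],
      permanova_abundance = unclass(mv$permanova_abundance)[
        c("pseudo_F", "df_between", "df_within", "R2", "p_perm")],
      permdisp_presence = unclass(mv$permdisp_presence)[
        c("F", "df", "p_anova", "p_perm")],
      permdisp_abundance = unclass(mv$permdisp_abundance)[
        c("F", "df", "p_anova", "p_perm")]),
      file.path(out_dir, "multivariate.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    utils::write.csv(mv$pairwise_presence,
                     file.path(out_dir, "pairwise_permanova.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(mv$ordination$coordinates),
                     file.path(out_dir, "pcoa_coordinates.csv"))
    write_linkage_csv(mv$dendrogram_presence,
                      file.path(out_dir, "dendrogram_merges.csv"))
    mv
  })

  results$decay <- stage("decay", {
    fits <- list()
    for (metric in c("jaccard_presence", "braycurtis_prevalence",
                     "braycurtis_meanabundance")) {
      tb <- build_decay_table(results$descriptors$profiles, metric,
                              results$distances$phylo,
                              results$distances$geo, epsilon = epsilon)
      write_decay_table_csv(tb, file.path(out_dir,
                                          paste0("decay_", metric, ".csv")))
      fit <- permutation_regression_test(tb, n_perm = n_perm,
                                         seed = seed + 10L)
      write_decay_fit_json(fit, file.path(out_dir,
                                          paste0("decay_", metric, ".json")))
      fits[[metric]] <- fit
    }
    fits
  })

  results$richness <- stage("richness_glm", {
    glms <- richness_glms(results$descriptors$infracommunity, hosts)
    summ <- lapply(glms, function(m) {
      list(lrt = m$lrt, aic = as.list(m$aic),
           coefficients = m$poisson$coefficients)
    })
    jsonlite::write_json(summ, file.path(out_dir, "richness_glm.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    glms
  })

  results$accumulation <- stage("accumulation", {
    curve <- accumulation_curve(infections, n_perm = n_perm_acc,
                                seed = seed + 20L)
    write_accumulation_csv(curve, file.path(out_dir, "accumulation.csv"))
    curve
  })

  manifest <- list(stages = stages, inputs = input_hashes, seed = seed,
                   n_perm = n_perm, n_perm_accumulation = n_perm_acc,
                   epsilon = epsilon,
                   package_version = as.character(
                     utils::packageVersion("paradecay")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$results <- results
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
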