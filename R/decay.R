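#' Build the pairwise distance-decay table
#'
#' Assembles one row per unordered pair of host species: the community
#' similarity under the chosen metric, its natural log, and the matching
#' phylogenetic (uncorrected p-distance) and geographic (km) distances.
#' Three metrics mirror the three regressions of the analysis: Jaccard on
#' presence/absence, Bray-Curtis on prevalence, Bray-Curtis on mean
#' abundance.
#'
#' @param profiles a [component_profiles()] result.
#' @param metric one of `"jaccard_presence"`, `"braycurtis_prevalence"`,
#'   `"braycurtis_meanabundance"`.
#' @param d_phylo a [distance_matrix()] of kind `"p_distance"` labelled by
#'   species code.
#' @param d_geo a [distance_matrix()] of kind `"geographic_km"` labelled by
#'   species code.
#' @param epsilon offset passed to [log_transform_similarity()].
#' @return a `data.frame` of class `decay_table` with columns `species_a`,
#'   `species_b`, `similarity`, `log_similarity`, `d_phylo`, `d_geo`; one
#'   row per unordered pair (`S(S-1)/2` rows), plus attributes `metric` and
#'   `species`.
#' @export
build_decay_table <- function(profiles,
                              metric = c("jaccard_presence",
                                         "braycurtis_prevalence",
                                         "braycurtis_meanabundance"),
                              d_phylo, d_geo, epsilon = 0) {
  metric <- match.arg(metric)
  stopifnot(inherits(profiles, "component_profiles"),
            inherits(d_phylo, "distance_matrix"),
            inherits(d_geo, "distance_matrix"))
  sp <- profiles$species
  for (dm in list(d_phylo, d_geo)) {
    if (!setequal(dm_labels(dm), sp)) {
      stop("species sets of profiles and distance matrices differ",
           call. = FALSE)
    }
  }
  mat <- switch(metric,
                jaccard_presence = profiles$presence,
                braycurtis_prevalence = profiles$prevalence,
                braycurtis_meanabundance = profiles$mean_abundance)
  sim <- similarity_matrix(mat, if (metric == "jaccard_presence") "jaccard"
                           else "braycurtis")
  dp <- dm_subset(d_phylo, sp)
  dg <- dm_subset(d_geo, sp)
  pr <- utils::combn(sp, 2L)
  s <- unclass(sim)[cbind(pr[1, ], pr[2, ])]
  out <- data.frame(species_a = pr[1, ], species_b = pr[2, ],
                    similarity = s,
                    log_similarity = log_transform_similarity(s, epsilon),
                    d_phylo = unclass(dp)[cbind(pr[1, ], pr[2, ])],
                    d_geo = unclass(dg)[cbind(pr[1, ], pr[2, ])],
                    stringsAsFactors = FALSE)
  structure(out, metric = metric, species = sp, epsilon = epsilon,
            class = c("decay_table", "data.frame"))
}

.decay_design <- function(t) {
  x <- cbind(intercept = 1, d_phylo = t$d_phylo, d_geo = t$d_geo)
  if (qr(x)$rank < ncol(x)) {
    stop(paste0("singular design: the distance predictors are collinear or ",
                "constant (e.g. all species at one site)"), call. = FALSE)
  }
  x
}

#' Distance-decay multiple regression
#'
#' Ordinary least squares of log-similarity on phylogenetic and geographic
#' distance, with intercept. Besides the raw slopes, standardized partial
#' coefficients are reported: `beta_j * sd(x_j) / sd(y)`, whose absolute
#' values serve as effect sizes comparable across predictors. Parametric
#' p-values come from the usual t statistics; permutation p-values are
#' added by [permutation_regression_test()].
#'
#' @param t a [build_decay_table()] result (>= 4 rows).
#' @return an object of class `decay_fit`: `intercept`, `slope_phylo`,
#'   `slope_geo`, `R2`, `effect_size_phylo`, `effect_size_geo`,
#'   `t_phylo`, `t_geo`, `p_param_phylo`, `p_param_geo`, `df_residual`,
#'   and (until the permutation test is run) `p_perm_phylo = NA`,
#'   `p_perm_geo = NA`.
#' @export
fit_decay_regression <- function(t) {
  stopifnot(inherits(t, "decay_table"))
  if (nrow(t) < 4L) stop("need at least 4 pairwise rows", call. = FALSE)
  x <- .decay_design(t)
  fit <- stats::lm(log_similarity ~ d_phylo + d_geo, data = t)
  sm <- summary(fit)
  cf <- stats::coef(sm)
  sy <- stats::sd(t$log_similarity)
  structure(list(
    intercept = unname(cf["(Intercept)", 1]),
    slope_phylo = unname(cf["d_phylo", 1]),
    slope_geo = unname(cf["d_geo", 1]),
    R2 = sm$r.squared,
    effect_size_phylo = abs(unname(cf["d_phylo", 1]) * stats::sd(t$d_phylo) / sy),
    effect_size_geo = abs(unname(cf["d_geo", 1]) * stats::sd(t$d_geo) / sy),
    t_phylo = unname(cf["d_phylo", 3]), t_geo = unname(cf["d_geo", 3]),
    p_param_phylo = unname(cf["d_phylo", 4]),
    p_param_geo = unname(cf["d_geo", 4]),
    df_residual = fit$df.residual,
    p_perm_phylo = NA_real_, p_perm_geo = NA_real_,
    n_perm = NA_integer_, seed = NULL, scheme = NA_character_,
    metric = attr(t, "metric"), n_pairs = nrow(t)),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Distance-decay fit [%s], %d pairs\n", x$metric, x$n_pairs))
  cat(sprintf("  R2 = %.3f\n", x$R2))
  cat(sprintf("  phylo: slope %.4g, effect size %.3f, p(param) %.3g, p(perm) %s\n",
              x$slope_phylo, x$effect_size_phylo, x$p_param_phylo,
              format(x$p_perm_phylo, digits = 3)))
  cat(sprintf("  geo:   slope %.4g, effect size %.3f, p(param) %.3g, p(perm) %s\n",
              x$slope_geo, x$effect_size_geo, x$p_param_geo,
              format(x$p_perm_geo, digits = 3)))
  invisible(x)
}

# t statistics of the two distance slopes for a matrix of responses
# (one column per response vector), given a fixed design
.decay_t_stats <- function(x, y) {
  xtx_inv <- solve(crossprod(x))
  betas <- xtx_inv %*% crossprod(x, y)          # 3 x k
  res <- y - x %*% betas
  s2 <- colSums(res^2) / (nrow(x) - ncol(x))
  se_phylo <- sqrt(s2 * xtx_inv["d_phylo", "d_phylo"])
  se_geo <- sqrt(s2 * xtx_inv["d_geo", "d_geo"])
  rbind(phylo = betas["d_phylo", ] / se_phylo,
        geo = betas["d_geo", ] / se_geo)
}

#' Permutation test for the distance-decay regression
#'
#' Because every host species enters multiple pairwise comparisons, the
#' rows of the decay table are not independent and parametric p-values are
#' anti-conservative. Two permutation schemes are provided:
#'
#' * `"matrix_permute"` (default): Mantel-style permutation of species
#'   labels of the similarity matrix — the pairwise structure of the
#'   response is preserved while its association with the (fixed)
#'   predictors is broken;
#' * `"row_permute"`: naive shuffling of the response rows, retained for
#'   comparison.
#'
#' Two-sided p-values per predictor use the add-one convention
#' `p = (1 + #[|t_perm| >= |t_obs|]) / (1 + n_perm)`.
#'
#' @param t a [build_decay_table()] result.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @param scheme `"matrix_permute"` or `"row_permute"`.
#' @return a `decay_fit` with `p_perm_phylo`, `p_perm_geo`, `n_perm`,
#'   `seed` and `scheme` filled in.
#' @export
permutation_regression_test <- function(t, n_perm = 999, seed = NULL,
                                        scheme = c("matrix_permute",
                                                   "row_permute")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  fit <- fit_decay_regression(t)
  x <- .decay_design(t)
  n <- nrow(t)
  sp <- attr(t, "species")
  ia <- match(t$species_a, sp)
  ib <- match(t$species_b, sp)
  smat <- matrix(NA_real_, length(sp), length(sp))
  smat[cbind(ia, ib)] <- smat[cbind(ib, ia)] <- t$log_similarity
  yperm <- .with_seed(seed, {
    if (scheme == "row_permute") {
      vapply(seq_len(n_perm), function(k) t$log_similarity[sample.int(n)],
             numeric(n))
    } else {
      vapply(seq_len(n_perm), function(k) {
        p <- sample.int(length(sp))
        smat[cbind(p[ia], p[ib])]
      }, numeric(n))
    }
  })
  tp <- .decay_t_stats(x, yperm)
  fit$p_perm_phylo <- (1 + sum(abs(tp["phylo", ]) >= abs(fit$t_phylo))) /
    (1 + n_perm)
  fit$p_perm_geo <- (1 + sum(abs(tp["geo", ]) >= abs(fit$t_geo))) /
    (1 + n_perm)
  fit$n_perm <- as.integer(n_perm)
  fit$seed <- seed
  fit$scheme <- scheme
  fit
}

#' Serialize a decay table / fit
#'
#' @param t a `decay_table`.
#' @param path output path.
#' @export
write_decay_table_csv <- function(t, path) {
  utils::write.csv(as.data.frame(t), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_decay_table_csv
#' @param fit a `decay_fit`.
#' @export
write_decay_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "decay_fit"))
  jsonlite::write_json(unclass(fit)[!vapply(unclass(fit), is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
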