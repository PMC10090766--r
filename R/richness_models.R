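#' Count GLM for infracommunity species richness
#'
#' Fits a log-link generalized linear model of a count response (parasite
#' species richness per host individual) on a predictor table, with either
#' a Poisson family or a negative binomial family (variance
#' `mu + mu^2 / k`, dispersion `k` estimated by maximum likelihood).
#'
#' @param response nonnegative integer vector.
#' @param design `data.frame` of predictors (numeric and/or factor); an
#'   intercept is always included. Pass a zero-column data frame for an
#'   intercept-only model.
#' @param family `"poisson"` or `"negbinomial"`.
#' @return an object of class `count_glm_fit`: `family`, `coefficients`
#'   (estimate, std_error), `log_likelihood`, `aic`, `deviance`,
#'   `converged`, `n`, `n_params`, `theta` (NB dispersion, `NA` for
#'   Poisson), and the underlying `model` object.
#' @export
fit_count_glm <- function(response, design,
                          family = c("poisson", "negbinomial")) {
  family <- match.arg(family)
  if (any(response < 0) || any(response != round(response))) {
    stop("response must be nonnegative integers", call. = FALSE)
  }
  if (!is.data.frame(design)) stop("`design` must be a data.frame", call. = FALSE)
  if (ncol(design) > 0 && nrow(design) != length(response)) {
    stop("design and response lengths differ", call. = FALSE)
  }
  dat <- if (ncol(design)) cbind(.response = response, design)
         else data.frame(.response = response)
  fml <- stats::as.formula(
    if (ncol(design)) ".response ~ ." else ".response ~ 1")
  model <- if (family == "poisson") {
    stats::glm(fml, data = dat, family = stats::poisson())
  } else {
    MASS::glm.nb(fml, data = dat)
  }
  mm <- stats::model.matrix(model)
  if (qr(mm)$rank < ncol(mm)) {
    stop("rank-deficient design", call. = FALSE)
  }
  sm <- summary(model)
  ll <- as.numeric(stats::logLik(model))
  n_params <- attr(stats::logLik(model), "df")   # includes NB dispersion
  structure(list(
    family = family,
    coefficients = data.frame(term = rownames(sm$coefficients),
                              estimate = sm$coefficients[, 1],
                              std_error = sm$coefficients[, 2],
                              row.names = NULL),
    log_likelihood = ll,
    aic = stats::AIC(model),
    deviance = stats::deviance(model),
    converged = isTRUE(model$converged),
    n = length(response), n_params = n_params,
    theta = if (family == "negbinomial") model$theta else NA_real_,
    model = model),
    class = "count_glm_fit")
}

#' @export
print.count_glm_fit <- function(x, ...) {
  cat(sprintf("<count_glm_fit: %s, n = %d, logLik = %.3f, AIC = %.2f>\n",
              x$family, x$n, x$log_likelihood, x$aic))
  print(x$coefficients)
  invisible(x)
}

#' Likelihood-ratio test between nested count GLMs
#'
#' `chi2 = 2 (logLik_full - logLik_reduced)` on `df` = difference in
#' parameter count, with p from the upper chi-square tail. Both fits must
#' use the same family and the same observations; the reduced model's
#' terms must nest in the full model's.
#'
#' @param full,reduced `count_glm_fit` objects.
#' @return a list with `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "count_glm_fit"), inherits(reduced, "count_glm_fit"))
  if (full$family != reduced$family) {
    stop("fits use different families", call. = FALSE)
  }
  if (full$n != reduced$n ||
      !isTRUE(all.equal(full$model$y, reduced$model$y))) {
    stop("fits are on different data", call. = FALSE)
  }
  if (!all(reduced$coefficients$term %in% full$coefficients$term)) {
    stop("`reduced` is not nested in `full`", call. = FALSE)
  }
  df <- full$n_params - reduced$n_params
  if (df < 0) stop("`reduced` has more parameters than `full`", call. = FALSE)
  chi2 <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  list(chi2 = chi2, df = df,
       p = if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Richness GLM analysis: fish length and fish species
#'
#' Convenience wrapper running the two richness models: (1) richness ~ fish
#' length (individuals with missing length dropped listwise) and
#' (2) richness ~ host species, each tested against the intercept-only
#' model by likelihood ratio, each fitted under both Poisson and negative
#' binomial families and ranked by AIC.
#'
#' @param infra an [infracommunity()] data frame.
#' @param hosts optional host metadata (`individual_id`, `length`, `sex`)
#'   from [read_hosts_csv()]; required for the length model.
#' @return a list with components `length_model` and `species_model`, each
#'   holding `poisson`, `negbinomial` (`count_glm_fit` or `NULL` if the NB
#'   fit fails), `lrt` (vs intercept-only, Poisson family), and an `aic`
#'   named vector.
#' @export
richness_glms <- function(infra, hosts = NULL) {
  stopifnot(is.data.frame(infra),
            all(c("individual", "species", "richness") %in% names(infra)))
  fit_both <- function(y, design) {
    pois <- fit_count_glm(y, design, "poisson")
    nb <- tryCatch(suppressWarnings(fit_count_glm(y, design, "negbinomial")),
                   error = function(e) NULL)
    null <- fit_count_glm(y, design[, 0, drop = FALSE], "poisson")
    aic <- c(poisson = pois$aic,
             negbinomial = if (is.null(nb)) NA_real_ else nb$aic)
    list(poisson = pois, negbinomial = nb,
         lrt = likelihood_ratio_test(pois, null), aic = aic)
  }
  out <- list()
  if (!is.null(hosts)) {
    m <- merge(infra, hosts, by.x = "individual", by.y = "individual_id")
    m <- m[!is.na(m$length), ]
    if (nrow(m) >= 3L) {
      out$length_model <- fit_both(m$richness,
                                   data.frame(length = m$length))
    }
  }
  out$species_model <- fit_both(infra$richness,
                                data.frame(species = factor(infra$species)))
  out
}
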