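sim_dataset_tables <- function(seed, cfg = simulation_config(seed = seed)) {
  ds <- generate_dataset(cfg)
  prof <- component_profiles(ds$infections)
  dphy <- if (cfg$tree_depth == 0) NULL else p_distance_matrix(ds$alignment)
  dgeo <- geographic_distance_matrix(ds$sites, ds$site_of_species)
  list(ds = ds, prof = prof, dphy = dphy, dgeo = dgeo)
}

test_that("decay table has one row per unordered pair, matching element ops", {
  x <- sim_dataset_tables(2)
  tb <- build_decay_table(x$prof, "jaccard_presence", x$dphy, x$dgeo,
                          epsilon = 0.01)
  expect_equal(nrow(tb), choose(8, 2))
  expect_false(any(duplicated(paste(tb$species_a, tb$species_b))))
  # spot-check rows against element-wise calls
  for (r in c(1, 10, 28)) {
    a <- tb$species_a[r]; b <- tb$species_b[r]
    expect_equal(tb$similarity[r],
                 jaccard_similarity(x$prof$presence[a, ], x$prof$presence[b, ]))
    expect_equal(tb$d_phylo[r], unclass(x$dphy)[a, b])
    expect_equal(tb$d_geo[r], unclass(x$dgeo)[a, b])
    expect_equal(tb$log_similarity[r], log(tb$similarity[r] + 0.01))
  }
  # brute-force reconstruction over all pairs and metrics
  for (metric in c("braycurtis_prevalence", "braycurtis_meanabundance")) {
    tbm <- build_decay_table(x$prof, metric, x$dphy, x$dgeo, epsilon = 0.01)
    mat <- if (metric == "braycurtis_prevalence") x$prof$prevalence else
      x$prof$mean_abundance
    ref <- apply(tbm, 1, function(row) {
      bray_curtis_similarity(mat[row[["species_a"]], ],
                             mat[row[["species_b"]], ])
    })
    expect_equal(tbm$similarity, unname(ref))
  }
  # species set mismatch is rejected
  expect_error(build_decay_table(x$prof, "jaccard_presence",
                                 dm_subset(x$dphy, x$prof$species[1:5]),
                                 x$dgeo), "species sets")
})

test_that("noiseless linear decay is recovered exactly", {
  sp <- sprintf("s%d", 1:6)
  set.seed(10)
  dp <- runif(choose(6, 2), 0, 0.2)
  dg <- runif(choose(6, 2), 0, 400)
  y <- 1 - 2 * dp + 0 * dg
  tb <- make_decay_table(sp, exp(y), dp, dg)
  fit <- suppressWarnings(fit_decay_regression(tb))  # exact fit warns
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$slope_phylo, -2, tolerance = 1e-10)
  expect_equal(fit$slope_geo, 0, tolerance = 1e-8)
  expect_equal(fit$R2, 1, tolerance = 1e-10)
})

test_that("constant predictors give a singular-design error", {
  sp <- sprintf("s%d", 1:5)
  n <- choose(5, 2)
  set.seed(3)
  tb <- make_decay_table(sp, runif(n, 0.3, 0.9), runif(n, 0, 0.2),
                         rep(0, n))  # all species at one site
  expect_error(fit_decay_regression(tb), "singular")
})

test_that("adding a constant to log-similarity shifts only the intercept", {
  x <- sim_dataset_tables(5)
  tb <- build_decay_table(x$prof, "braycurtis_meanabundance", x$dphy, x$dgeo,
                          epsilon = 0.01)
  f1 <- fit_decay_regression(tb)
  tb2 <- tb
  tb2$log_similarity <- tb$log_similarity + 3
  f2 <- fit_decay_regression(tb2)
  expect_equal(f2$intercept, f1$intercept + 3, tolerance = 1e-10)
  expect_equal(f2$slope_phylo, f1$slope_phylo, tolerance = 1e-10)
  expect_equal(f2$slope_geo, f1$slope_geo, tolerance = 1e-10)
  expect_equal(f2$R2, f1$R2, tolerance = 1e-10)
  expect_equal(f2$p_param_phylo, f1$p_param_phylo, tolerance = 1e-10)
})

test_that("slope estimates fall within 3 SE of truth in simulation", {
  sp <- sprintf("s%d", 1:8)
  n <- choose(8, 2)
  set.seed(14)
  dp <- runif(n, 0, 0.2); dg <- runif(n, 0, 400)
  hit_p <- hit_g <- logical(300)
  for (r in 1:300) {
    y <- -0.5 - 3 * dp - 0.002 * dg + rnorm(n, 0, 0.1)
    tb <- make_decay_table(sp, exp(y), dp, dg)
    fit <- fit_decay_regression(tb)
    se_p <- abs(fit$slope_phylo / fit$t_phylo)
    se_g <- abs(fit$slope_geo / fit$t_geo)
    hit_p[r] <- abs(fit$slope_phylo - (-3)) <= 3 * se_p
    hit_g[r] <- abs(fit$slope_geo - (-0.002)) <= 3 * se_g
  }
  expect_gte(mean(hit_p), 0.95)
  expect_gte(mean(hit_g), 0.95)
})

test_that("permutation regression test is deterministic and scheme-aware", {
  x <- sim_dataset_tables(8)
  tb <- build_decay_table(x$prof, "jaccard_presence", x$dphy, x$dgeo,
                          epsilon = 0.01)
  f1 <- permutation_regression_test(tb, n_perm = 199, seed = 42)
  f2 <- permutation_regression_test(tb, n_perm = 199, seed = 42)
  expect_identical(f1$p_perm_phylo, f2$p_perm_phylo)
  expect_identical(f1$p_perm_geo, f2$p_perm_geo)
  expect_gte(f1$p_perm_phylo, 1 / 200)
  f3 <- permutation_regression_test(tb, n_perm = 199, seed = 42,
                                    scheme = "row_permute")
  expect_equal(f3$scheme, "row_permute")
  expect_error(permutation_regression_test(tb, n_perm = 0), "n_perm")
})

test_that("strong phylogenetic decay yields small permutation p", {
  # decay tables with R2 about 0.5, mirroring a strong presence/absence
  # signal at 28 pairwise comparisons
  sp <- sprintf("s%d", 1:8)
  n <- choose(8, 2)
  set.seed(19)
  dp <- runif(n, 0, 0.2); dg <- runif(n, 0, 400)
  hits <- logical(60)
  for (r in 1:60) {
    y <- -0.5 - 6 * dp + rnorm(n, 0, 0.35)
    tb <- make_decay_table(sp, pmin(1, exp(y)), dp, dg)
    fit <- permutation_regression_test(tb, n_perm = 999, seed = r)
    hits[r] <- fit$p_perm_phylo <= 0.01
  }
  expect_gte(mean(hits), 0.8)
})

test_that("matrix and row permutation agree under full exchangeability", {
  sp <- sprintf("s%d", 1:8)
  n <- choose(8, 2)
  set.seed(23)
  dp <- runif(n, 0, 0.2); dg <- runif(n, 0, 400)
  p_mat <- p_row <- numeric(60)
  for (r in 1:60) {
    y <- rnorm(n)                      # no structure at all
    tb <- make_decay_table(sp, pmin(1, exp(y - max(y))), dp, dg)
    p_mat[r] <- permutation_regression_test(tb, 199, seed = r)$p_perm_phylo
    p_row[r] <- permutation_regression_test(tb, 199, seed = r,
                                            scheme = "row_permute")$p_perm_phylo
  }
  expect_lt(abs(mean(p_mat) - mean(p_row)), 0.12)
})
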