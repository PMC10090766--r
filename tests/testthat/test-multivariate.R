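euclid_dm <- function(y) {
  m <- as.matrix(dist(y))
  dimnames(m) <- list(sprintf("i%d", seq_along(y)), sprintf("i%d", seq_along(y)))
  distance_matrix(m, "dissimilarity")
}

test_that("PERMANOVA pseudo-F equals classical ANOVA F on univariate data", {
  set.seed(21)
  for (rep in 1:10) {
    y <- rnorm(12)
    g <- rep(c("a", "b", "c"), each = 4)
    res <- permanova(euclid_dm(y), setNames(g, sprintf("i%d", 1:12)),
                     n_perm = 0)
    expect_equal(res$pseudo_F, anova_f_oracle(y, g), tolerance = 1e-10)
    expect_equal(res$SS_between + res$SS_within, res$SS_total,
                 tolerance = 1e-10)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 and is relabel-invariant", {
  skip_if_not_installed("vegan")
  set.seed(4)
  m <- matrix(rpois(18 * 6, 2), 18, 6)
  g <- rep(c("a", "b", "c"), each = 6)
  dmat <- as.matrix(vegan::vegdist(m + 1, method = "bray"))
  dimnames(dmat) <- list(sprintf("i%d", 1:18), sprintf("i%d", 1:18))
  d <- distance_matrix(dmat, "dissimilarity")
  res <- permanova(d, setNames(g, rownames(dmat)), n_perm = 99, seed = 5)
  ref <- vegan::adonis2(as.dist(dmat) ~ g, permutations = 99)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(res$df_between, ref$Df[1])

  perm <- sample(18)
  d2 <- distance_matrix(dmat[perm, perm], "dissimilarity")
  res2 <- permanova(d2, setNames(g, rownames(dmat)), n_perm = 0)
  expect_equal(res2$pseudo_F, res$pseudo_F, tolerance = 1e-12)
})

test_that("sampled permutation p converges to the exhaustive value", {
  set.seed(31)
  y <- c(rnorm(3), rnorm(3, 1.5))
  g <- rep(c("a", "b"), each = 3)
  d <- euclid_dm(y)
  d2 <- unclass(d)^2
  n <- 6
  ss_t <- sum(d2) / (2 * n)
  f_of <- function(idx) {
    ssw <- sum(d2[idx[1:3], idx[1:3]]) / 6 + sum(d2[idx[4:6], idx[4:6]]) / 6
    ((ss_t - ssw) / 1) / (ssw / 4)
  }
  f_obs <- f_of(1:6)
  f_all <- vapply(all_perms(6L), f_of, numeric(1))
  p_exact <- mean(f_all >= f_obs - 1e-12)
  res <- permanova(d, setNames(g, rownames(d)), n_perm = 999, seed = 2)
  expect_equal(res$pseudo_F, f_obs, tolerance = 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$p_perm - p_exact), 4 * se + 2 / 999)
  expect_gte(res$p_perm, 1 / 1000)
})

test_that("permutation p-values are deterministic under a fixed seed", {
  d <- random_distance_matrix(12, 8)
  g <- setNames(rep(c("x", "y", "z"), each = 4), dm_labels(d))
  r1 <- permanova(d, g, n_perm = 199, seed = 99)
  r2 <- permanova(d, g, n_perm = 199, seed = 99)
  expect_identical(r1$p_perm, r2$p_perm)
  p1 <- permdisp(d, g, n_perm = 199, seed = 99)
  p2 <- permdisp(d, g, n_perm = 199, seed = 99)
  expect_identical(p1$p_perm, p2$p_perm)
})

test_that("PERMANOVA rejects degenerate designs", {
  d <- random_distance_matrix(4, 1)
  expect_error(permanova(d, setNames(rep("a", 4), dm_labels(d)), 99),
               "two groups")
  expect_error(permanova(d, setNames(c("a", "b", "c", "d"), dm_labels(d)), 99),
               "degenerate")
})

test_that("pairwise PERMANOVA tests every pair with Bonferroni clamping", {
  d <- random_distance_matrix(12, 13)
  g <- setNames(rep(c("x", "y", "z"), each = 4), dm_labels(d))
  pw <- pairwise_permanova(d, g, n_perm = 99, seed = 1)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_adj, pmin(1, pw$p_perm * 3))
  # identical point clouds: all pairwise p high even before adjustment
  set.seed(77)
  pts <- matrix(rnorm(18 * 2), 18)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(sprintf("i%d", 1:18), sprintf("i%d", 1:18))
  g2 <- setNames(rep(c("a", "b", "c"), 6), rownames(m))
  pw2 <- pairwise_permanova(distance_matrix(m, "dissimilarity"), g2,
                            n_perm = 199, seed = 3)
  expect_true(all(pw2$p_perm > 0.05))
  expect_true(all(pw2$p_adj >= pw2$p_perm))
})

test_that("PERMDISP matches vegan::betadisper centroid distances and F", {
  skip_if_not_installed("vegan")
  set.seed(15)
  m <- matrix(rpois(20 * 8, 3), 20, 8)
  dmat <- as.matrix(vegan::vegdist(m + 1, method = "bray"))
  dimnames(dmat) <- list(sprintf("i%d", 1:20), sprintf("i%d", 1:20))
  g <- setNames(rep(c("a", "b"), each = 10), rownames(dmat))
  res <- permdisp(distance_matrix(dmat, "dissimilarity"), g, n_perm = 99,
                  seed = 1)
  bd <- vegan::betadisper(as.dist(dmat), factor(g), type = "centroid")
  expect_equal(unname(res$centroid_distances), unname(bd$distances),
               tolerance = 1e-8)
  ref_f <- anova(bd)$`F value`[1]
  expect_equal(res$F, ref_f, tolerance = 1e-8)
  expect_equal(res$p_anova, anova(bd)$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("PERMDISP detects inflated dispersion and not a mere shift", {
  set.seed(100)
  reject <- logical(40)
  for (r in 1:40) {
    a <- matrix(rnorm(20 * 2), 20)
    b <- matrix(rnorm(20 * 2, sd = 3), 20)
    m <- as.matrix(dist(rbind(a, b)))
    dimnames(m) <- list(sprintf("i%d", 1:40), sprintf("i%d", 1:40))
    g <- setNames(rep(c("a", "b"), each = 20), rownames(m))
    res <- permdisp(distance_matrix(m, "dissimilarity"), g, n_perm = 199,
                    seed = r)
    reject[r] <- res$p_perm <= 0.05
  }
  expect_gte(mean(reject), 0.8)
  # equal dispersions, shifted centroids: F stays small
  a <- matrix(rnorm(20 * 2), 20)
  b <- matrix(rnorm(20 * 2, mean = 5), 20)
  m <- as.matrix(dist(rbind(a, b)))
  dimnames(m) <- list(sprintf("i%d", 1:40), sprintf("i%d", 1:40))
  g <- setNames(rep(c("a", "b"), each = 20), rownames(m))
  res <- permdisp(distance_matrix(m, "dissimilarity"), g, n_perm = 199,
                  seed = 1)
  expect_gt(res$p_perm, 0.05)
})

test_that("PERMDISP rejects singleton groups", {
  d <- random_distance_matrix(5, 2)
  g <- setNames(c("a", "a", "a", "a", "b"), dm_labels(d))
  expect_error(permdisp(d, g, 99), "two members")
})

test_that("PCoA is an isometry for Euclidean input", {
  set.seed(6)
  pts <- matrix(rnorm(5 * 2), 5)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(sprintf("p%d", 1:5), sprintf("p%d", 1:5))
  ord <- pcoa(distance_matrix(m, "dissimilarity"), n_axes = 4)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(m), tolerance = 1e-8)
  neg <- ord$eigenvalues[ord$eigenvalues < 0]
  expect_lt(max(abs(neg), 0), 1e-8 * max(ord$eigenvalues))
  expect_lt(ord$stress, 1e-8)
  # axes ordered by decreasing eigenvalue
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))

  skip_if_not_installed("vegan")
  ref <- cmdscale(m, k = 2)
  expect_equal(abs(ord$coordinates[, 1:2]), abs(ref), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCoA of equidistant points is a regular simplex", {
  n <- 5
  m <- matrix(1, n, n) - diag(n)
  dimnames(m) <- list(sprintf("p%d", 1:n), sprintf("p%d", 1:n))
  ord <- pcoa(distance_matrix(m, "dissimilarity"), n_axes = n)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-9]
  expect_equal(length(pos), n - 1L)
  expect_equal(max(pos) / min(pos), 1, tolerance = 1e-8)
})

test_that("PCoA handles duplicated and degenerate configurations", {
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m["a", "c"] <- m["c", "a"] <- 1
  m["b", "c"] <- m["c", "b"] <- 1    # a and b coincide
  ord <- pcoa(distance_matrix(m, "dissimilarity"), n_axes = 2)
  expect_equal(ord$coordinates["a", ], ord$coordinates["b", ],
               tolerance = 1e-10)
  z <- matrix(0, 3, 3, dimnames = dimnames(m))
  ordz <- pcoa(distance_matrix(z, "dissimilarity"), n_axes = 2)
  expect_true(ordz$degenerate)
  expect_true(all(ordz$coordinates == 0))
})

test_that("UPGMA reproduces the hand-run example and brute-force oracle", {
  m <- as.matrix(dist(c(a = 0, b = 1, c = 10)))
  dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
  dend <- hac_average_linkage(distance_matrix(m, "dissimilarity"))
  expect_equal(dend$merges$height, c(1, 9.5))
  expect_equal(dend$merges$child_a[1], "a")
  expect_equal(dend$merges$child_b[1], "b")

  # identical leaves merge first at height zero
  m2 <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  d2 <- hac_average_linkage(distance_matrix(m2, "dissimilarity"))
  expect_equal(d2$merges$height[1], 0)

  for (seed in 1:5) {
    d <- random_distance_matrix(6, seed + 40)
    mine <- hac_average_linkage(d)
    oracle <- upgma_oracle(d)
    expect_equal(mine$merges$height, vapply(oracle, `[[`, numeric(1),
                                            "height"),
                 tolerance = 1e-12)
    # same merge composition at every step
    seen <- lapply(seq_len(5), function(k) {
      labs <- mine$labels
      members <- function(id) if (id < 0) labs[-id] else
        unlist(lapply(mine$merge[id, ], members))
      sort(unlist(lapply(mine$merge[k, ], members)))
    })
    expect_equal(seen, lapply(oracle, `[[`, "members"))
    # heights monotone along the merge sequence
    expect_true(all(diff(mine$height) >= -1e-12))
  }
})

test_that("UPGMA heights agree with stats::hclust average linkage", {
  d <- random_distance_matrix(8, 77)
  mine <- hac_average_linkage(d)
  ref <- hclust(as.dist(unclass(d)), method = "average")
  expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-12)
  hc <- as.hclust(mine)
  expect_s3_class(hc, "hclust")
  expect_setequal(hc$order, 1:8)
})
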