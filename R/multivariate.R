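# run code under a local, restorable RNG state when a seed is given
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

.check_groups <- function(d, groups) {
  labels <- dm_labels(d)
  if (!is.null(names(groups))) {
    missing <- setdiff(labels, names(groups))
    if (length(missing)) {
      stop("no group for label(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    groups <- groups[labels]
  } else if (length(groups) != length(labels)) {
    stop("`groups` must be named or match the matrix order", call. = FALSE)
  }
  factor(as.character(groups))
}

# within-group sum of squares from a squared-dissimilarity matrix, for a
# given assignment of matrix rows to groups (indices permuted under the null)
.ss_within <- function(d2, idx_by_group) {
  s <- 0
  for (idx in idx_by_group) {
    s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix. Sums of squares are computed directly from squared
#' dissimilarities: `SS_T = sum_{i<j} d_ij^2 / N`,
#' `SS_W = sum_g sum_{i<j in g} d_ij^2 / n_g`, `SS_A = SS_T - SS_W`, and
#' `pseudo-F = (SS_A / (a-1)) / (SS_W / (N-a))`. The p-value is obtained by
#' random relabelling of individuals, with the add-one convention
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`, so the smallest
#' attainable p at 999 permutations is 0.001.
#'
#' @param d a [distance_matrix()] of kind `"dissimilarity"`.
#' @param groups factor or named vector assigning each label to a group.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed; identical seeds give identical results.
#' @return an object of class `permanova_result` with `pseudo_F`,
#'   `df_between` (a-1), `df_within` (N-a), `SS_total`, `SS_between`,
#'   `SS_within`, `R2`, `p_perm`, `n_permutations`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  stopifnot(inherits(d, "distance_matrix"))
  if (dm_kind(d) == "similarity") {
    stop("pass a dissimilarity (use as_dissimilarity())", call. = FALSE)
  }
  g <- .check_groups(d, groups)
  a <- nlevels(g)
  n <- nrow(d)
  if (a < 2L) stop("PERMANOVA needs at least two groups", call. = FALSE)
  if (n - a <= 0L) stop("degenerate design: no within-group df", call. = FALSE)
  d2 <- unclass(d)^2
  ss_t <- sum(d2) / (2 * n)
  idx_by_group <- split(seq_len(n), g)
  ss_w <- .ss_within(d2, idx_by_group)
  ss_a <- ss_t - ss_w
  f_obs <- (ss_a / (a - 1)) / (ss_w / (n - a))
  sizes <- lengths(idx_by_group)
  p <- NA_real_
  if (n_perm > 0) {
    f_perm <- .with_seed(seed, {
      vapply(seq_len(n_perm), function(k) {
        perm <- sample.int(n)
        splits <- split(perm, rep.int(seq_along(sizes), sizes))
        ssw <- .ss_within(d2, splits)
        ((ss_t - ssw) / (a - 1)) / (ssw / (n - a))
      }, numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  }
  structure(list(pseudo_F = f_obs, df_between = a - 1L, df_within = n - a,
                 SS_total = ss_t, SS_between = ss_a, SS_within = ss_w,
                 R2 = ss_a / ss_t, p_perm = p, n_permutations = n_perm,
                 groups = g, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d,%d) = %.4g, R2 = %.3f, p(perm) = %s [%d perms]\n",
              x$df_between, x$df_within, x$pseudo_F, x$R2,
              format(x$p_perm, digits = 3), x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA with Bonferroni correction
#'
#' Runs [permanova()] on the submatrix of every unordered pair of groups
#' and applies the Bonferroni adjustment
#' `p_adj = min(1, p * number_of_pairs)`.
#'
#' @inheritParams permanova
#' @param adjust multiplicity correction; only `"bonferroni"`.
#' @return a `data.frame` with one row per pair: `group_a`, `group_b`,
#'   `pseudo_F`, `df_between`, `df_within`, `p_perm`, `p_adj`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = NULL,
                               adjust = "bonferroni") {
  adjust <- match.arg(adjust, "bonferroni")
  g <- .check_groups(d, groups)
  lv <- levels(g)
  if (length(lv) < 2L) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(lv, 2L)
  npairs <- ncol(pairs)
  labels <- dm_labels(d)
  rows <- lapply(seq_len(npairs), function(k) {
    keep <- labels[g %in% pairs[, k]]
    sub <- dm_subset(d, keep)
    res <- permanova(sub, stats::setNames(as.character(g[g %in% pairs[, k]]),
                                          keep),
                     n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else seed + k)
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               pseudo_F = res$pseudo_F, df_between = res$df_between,
               df_within = res$df_within, p_perm = res$p_perm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_perm * npairs)
  out
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of the squared dissimilarities,
#' `B = -1/2 J D^2 J`, followed by an eigendecomposition. Coordinates are
#' returned for up to `n_axes` positive-eigenvalue axes, scaled by the
#' square root of the eigenvalue. Negative eigenvalues (non-Euclidean
#' input) are reported, and Kruskal stress-1 of the retained configuration
#' is computed as a diagnostic.
#'
#' @param d a [distance_matrix()] of a dissimilarity kind.
#' @param n_axes number of axes to retain (>= 1).
#' @return an object of class `pcoa_ordination`: `coordinates`
#'   (points x axes), `eigenvalues` (all, descending), `goodness`
#'   (fraction of positive-eigenvalue variance on the retained axes; `NA`
#'   with `degenerate = TRUE` for an all-zero input), `stress`.
#' @export
pcoa <- function(d, n_axes = 2L) {
  stopifnot(inherits(d, "distance_matrix"))
  if (dm_kind(d) == "similarity") {
    stop("pass a dissimilarity (use as_dissimilarity())", call. = FALSE)
  }
  if (n_axes < 1L) stop("n_axes must be >= 1", call. = FALSE)
  n <- nrow(d)
  d2 <- unclass(d)^2
  cs <- colMeans(d2); rs <- rowMeans(d2); gm <- mean(d2)
  b <- -0.5 * (d2 - outer(rs, cs, function(r, c) r + c) + gm)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  ev <- e$values
  tol <- 1e-9 * max(abs(ev), 1e-300)
  pos <- which(ev > tol)
  if (!length(pos)) {
    coords <- matrix(0, n, n_axes,
                     dimnames = list(dm_labels(d), paste0("PCo", seq_len(n_axes))))
    return(structure(list(coordinates = coords, eigenvalues = ev,
                          goodness = NA_real_, stress = NA_real_,
                          degenerate = TRUE), class = "pcoa_ordination"))
  }
  k <- min(n_axes, length(pos))
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ev[pos[seq_len(k)]]), k)
  dimnames(coords) <- list(dm_labels(d), paste0("PCo", seq_len(k)))
  dhat <- as.matrix(stats::dist(coords))
  num <- sum((unclass(d) - dhat)[upper.tri(dhat)]^2)
  den <- sum(unclass(d)[upper.tri(dhat)]^2)
  structure(list(coordinates = coords, eigenvalues = ev,
                 goodness = sum(ev[pos[seq_len(k)]]) / sum(ev[pos]),
                 stress = if (den > 0) sqrt(num / den) else NA_real_,
                 degenerate = FALSE),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("<pcoa_ordination: %d points, %d axes, goodness %.3f, stress %.4g>\n",
              nrow(x$coordinates), ncol(x$coordinates), x$goodness, x$stress))
  invisible(x)
}

# full PCoA embedding split into real axes (positive eigenvalues) and
# imaginary axes (negative eigenvalues), used by permdisp
.pcoa_embed_full <- function(d) {
  n <- nrow(d)
  d2 <- unclass(d)^2
  cs <- colMeans(d2); rs <- rowMeans(d2); gm <- mean(d2)
  b <- -0.5 * (d2 - outer(rs, cs, function(r, c) r + c) + gm)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values), 1e-300)
  pos <- e$values > tol
  neg <- e$values < -tol
  real <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  imag <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))
  list(real = real, imag = imag)
}

# one-way ANOVA F for a response vector (or matrix of permuted responses,
# one column per permutation) against a fixed grouping
.anova_f <- function(z, g) {
  z <- as.matrix(z)
  n <- nrow(z); a <- nlevels(g)
  ng <- as.vector(table(g))
  gs <- rowsum(z, g)                      # group sums, a x k
  tot <- colSums(z)
  ssb <- colSums(gs^2 / ng) - tot^2 / n
  ssw <- colSums(z^2) - colSums(gs^2 / ng)
  (ssb / (a - 1)) / (ssw / (n - a))
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Anderson's distance-based dispersion test. The dissimilarity matrix is
#' embedded by principal coordinates keeping negative-eigenvalue axes; the
#' distance of each point to its group centroid is
#' `sqrt(max(0, delta2_real - delta2_imag))`, where the two terms are the
#' squared Euclidean distances to the centroid in the real and imaginary
#' parts of the embedding. Group differences in these distances are tested
#' both by a classical one-way ANOVA F (parametric p) and by permuting the
#' centroid distances across groups (permutation p, add-one convention).
#'
#' @inheritParams permanova
#' @return an object of class `permdisp_result`: `centroid_distances`
#'   (named), `F`, `df`, `p_anova`, `p_perm`, `n_permutations`.
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = NULL) {
  stopifnot(inherits(d, "distance_matrix"))
  if (dm_kind(d) == "similarity") {
    stop("pass a dissimilarity (use as_dissimilarity())", call. = FALSE)
  }
  g <- .check_groups(d, groups)
  a <- nlevels(g); n <- nrow(d)
  if (a < 2L) stop("PERMDISP needs at least two groups", call. = FALSE)
  if (any(table(g) < 2L)) {
    stop("every group needs at least two members", call. = FALSE)
  }
  emb <- .pcoa_embed_full(d)
  z <- numeric(n)
  for (lv in levels(g)) {
    idx <- which(g == lv)
    cr <- colMeans(emb$real[idx, , drop = FALSE])
    d2r <- rowSums(sweep(emb$real[idx, , drop = FALSE], 2, cr)^2)
    d2i <- 0
    if (ncol(emb$imag)) {
      ci <- colMeans(emb$imag[idx, , drop = FALSE])
      d2i <- rowSums(sweep(emb$imag[idx, , drop = FALSE], 2, ci)^2)
    }
    z[idx] <- sqrt(pmax(0, d2r - d2i))
  }
  names(z) <- dm_labels(d)
  f_obs <- .anova_f(z, g)
  p_anova <- stats::pf(f_obs, a - 1, n - a, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0) {
    zperm <- .with_seed(seed, {
      vapply(seq_len(n_perm), function(k) z[sample.int(n)], numeric(n))
    })
    f_perm <- .anova_f(zperm, g)
    p_perm <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  }
  structure(list(centroid_distances = z, F = unname(f_obs),
                 df = c(a - 1L, n - a), p_anova = unname(p_anova),
                 p_perm = p_perm, n_permutations = n_perm, groups = g),
            class = "permdisp_result")
}

#' @export
print.permdisp_result <- function(x, ...) {
  cat(sprintf("PERMDISP: F(%d,%d) = %.4g, p(anova) = %s, p(perm) = %s\n",
              x$df[1], x$df[2], x$F, format(x$p_anova, digits = 3),
              format(x$p_perm, digits = 3)))
  invisible(x)
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering that repeatedly merges the pair of clusters
#' with the smallest mean inter-cluster dissimilarity (arithmetic average
#' over all cross pairs of original observations). Ties are broken by the
#' lexicographically smallest pair of cluster labels, a cluster being
#' labelled by its smallest member. Merge heights are monotone
#' non-decreasing.
#'
#' @param d a [distance_matrix()] of a dissimilarity kind with >= 2 labels.
#' @return an object of class `upgma_dendrogram` with `merge` and `height`
#'   in [stats::hclust()] convention, `labels`, and a `merges` data frame
#'   (`child_a`, `child_b`, `height`, `size`) where children are cluster
#'   labels. Convert with [as.hclust()].
#' @export
hac_average_linkage <- function(d) {
  stopifnot(inherits(d, "distance_matrix"))
  if (dm_kind(d) == "similarity") {
    stop("pass a dissimilarity (use as_dissimilarity())", call. = FALSE)
  }
  labels <- dm_labels(d)
  n <- length(labels)
  if (n < 2L) stop("need at least two labels", call. = FALSE)
  dd <- unclass(d)
  active <- seq_len(n)
  size <- rep(1L, n)
  clab <- labels                   # lexicographic cluster label = min member
  node <- -seq_len(n)              # hclust ids: negative leaf, positive merge
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  merges <- data.frame(child_a = character(n - 1L), child_b = character(n - 1L),
                       height = numeric(n - 1L), size = integer(n - 1L),
                       stringsAsFactors = FALSE)
  cur <- dd
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- NULL
    best_val <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        v <- cur[i, j]
        key <- sort(c(clab[i], clab[j]))
        if (v < best_val - 1e-12 ||
            (abs(v - best_val) <= 1e-12 && !is.null(best) &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, key = key)
          best_val <- v
        }
      }
    }
    i <- best$i; j <- best$j
    h <- cur[i, j]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- h
    merges$child_a[step] <- min(clab[i], clab[j])
    merges$child_b[step] <- max(clab[i], clab[j])
    merges$height[step] <- h
    merges$size[step] <- size[i] + size[j]
    # Lance-Williams update for average linkage
    newrow <- (size[i] * cur[i, ] + size[j] * cur[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(m), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newrow[keep]),
                 c(newrow[keep], 0))
    size <- c(size[keep], size[i] + size[j])
    clab <- c(clab[keep], min(clab[i], clab[j]))
    node <- c(node[keep], step)
    active <- seq_along(size)
  }
  structure(list(merge = merge, height = height, labels = labels,
                 merges = merges),
            class = "upgma_dendrogram")
}

#' @export
as.hclust.upgma_dendrogram <- function(x, ...) {
  ord_rec <- function(k) {
    if (k < 0) return(-k)
    c(ord_rec(x$merge[k, 1]), ord_rec(x$merge[k, 2]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = ord_rec(nrow(x$merge)), labels = x$labels,
                 method = "average", call = match.call(),
                 dist.method = "user"),
            class = "hclust")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("<upgma_dendrogram: %d leaves, root height %.4g>\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' Export a dendrogram merge table as CSV (linkage format)
#'
#' @param x an `upgma_dendrogram`.
#' @param path output CSV path.
#' @export
write_linkage_csv <- function(x, path) {
  stopifnot(inherits(x, "upgma_dendrogram"))
  utils::write.csv(x$merges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
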