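# shared fixture builders and independent oracles

# four individuals, two host species, three taxa
tiny_table <- function() {
  counts <- matrix(
    c(2L, 0L, 1L,
      0L, 3L, 0L,
      0L, 0L, 0L,
      1L, 1L, 4L),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("i1", "i2", "i3", "i4"), c("t1", "t2", "t3")))
  infection_table(
    counts,
    species = c(i1 = "A", i2 = "A", i3 = "B", i4 = "B"),
    site = c(i1 = "S1", i2 = "S1", i3 = "S2", i4 = "S2"),
    taxon_group = c(t1 = "digenean", t2 = "cestode", t3 = "nematode"))
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

write_temp_fasta <- function(...) {
  f <- tempfile(fileext = ".fasta")
  writeLines(unlist(list(...)), f)
  f
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(sprintf("L%d", 1:n), sprintf("L%d", 1:n))
  distance_matrix(m, "dissimilarity")
}

# independent UPGMA: clusters as explicit member sets, inter-cluster
# dissimilarity recomputed each step as the mean over all original pairs
upgma_oracle <- function(d) {
  m <- unclass(d)
  clusters <- as.list(rownames(m))
  out <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        v <- mean(m[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        better <- is.null(best) || v < best$v - 1e-12 ||
          (abs(v - best$v) <= 1e-12 &&
             (key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2])))
        if (better) best <- list(i = i, j = j, v = v, key = key)
      }
    }
    out[[length(out) + 1L]] <- list(
      members = sort(c(clusters[[best$i]], clusters[[best$j]])),
      height = best$v)
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  out
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# classical one-way ANOVA F computed from first principles
anova_f_oracle <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  a <- nlevels(g); n <- length(y)
  (ssb / (a - 1)) / (ssw / (n - a))
}

# decay table assembled by hand for regression tests
make_decay_table <- function(species, sim, d_phylo, d_geo, epsilon = 0) {
  pr <- combn(species, 2)
  structure(data.frame(species_a = pr[1, ], species_b = pr[2, ],
                       similarity = sim,
                       log_similarity = log(sim + epsilon),
                       d_phylo = d_phylo, d_geo = d_geo,
                       stringsAsFactors = FALSE),
            metric = "jaccard_presence", species = species,
            epsilon = epsilon, class = c("decay_table", "data.frame"))
}

null_sim_config <- function(seed) {
  simulation_config(seed = seed, lambda_phylo = 0, lambda_geo = 0,
                    p_uninfected_host = 0)
}

recovery_sim_config <- function(seed) {
  simulation_config(seed = seed, p0 = 0.7, lambda_phylo = 25,
                    lambda_geo = 0, specificity_shape = Inf,
                    p_uninfected_host = 0)
}
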