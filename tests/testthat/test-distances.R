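test_that("Jaccard similarity matches the a/(a+b+c) formula", {
  expect_equal(jaccard_similarity(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_equal(jaccard_similarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(jaccard_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(jaccard_similarity(c(0, 0), c(0, 0)), 1)  # empty == empty
  expect_error(jaccard_similarity(c(1, 0), c(1, 0, 1)), "length")
})

test_that("Bray-Curtis similarity matches its formula and contracts", {
  expect_equal(bray_curtis_similarity(c(2, 2), c(0, 2)), 1 - 2 / 6)
  expect_equal(bray_curtis_similarity(c(1, 3), c(1, 3)), 1)
  expect_equal(bray_curtis_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(bray_curtis_similarity(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis_similarity(c(-1, 1), c(1, 1)), "negative")
})

test_that("similarity matrices agree with element-wise calls and vegan", {
  skip_if_not_installed("vegan")
  set.seed(42)
  m <- matrix(rpois(8 * 10, 2), 8, 10,
              dimnames = list(sprintf("sp%d", 1:8), NULL))
  pres <- (m > 0) * 1
  for (metric in c("jaccard", "braycurtis")) {
    prof <- if (metric == "jaccard") pres else m
    s <- similarity_matrix(prof, metric)
    expect_equal(dm_kind(s), "similarity")
    fn <- if (metric == "jaccard") jaccard_similarity else bray_curtis_similarity
    for (pair in list(c(1, 2), c(3, 7), c(5, 8))) {
      expect_equal(s[pair[1], pair[2]], fn(prof[pair[1], ], prof[pair[2], ]))
    }
    # vegan computes the companion dissimilarities; note vegan's binary
    # jaccard = 2bc/(1+bc) relation does not apply - it is 1 - a/(a+b+c)
    vd <- as.matrix(vegan::vegdist(prof, method = if (metric == "jaccard")
      "jaccard" else "bray", binary = metric == "jaccard"))
    expect_equal(unclass(as_dissimilarity(s)), vd, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  # relabeling invariance
  perm <- sample(8)
  s1 <- similarity_matrix(pres, "jaccard")
  s2 <- similarity_matrix(pres[perm, ], "jaccard")
  expect_equal(unclass(s2)[rownames(s1), rownames(s1)], unclass(s1),
               ignore_attr = TRUE)
})

test_that("1 - Jaccard satisfies the triangle inequality (metric property)", {
  set.seed(7)
  for (rep in 1:50) {
    v <- matrix(rbinom(3 * 12, 1, 0.5), 3, 12)
    d12 <- 1 - jaccard_similarity(v[1, ], v[2, ])
    d13 <- 1 - jaccard_similarity(v[1, ], v[3, ])
    d23 <- 1 - jaccard_similarity(v[2, ], v[3, ])
    expect_lte(d12, d13 + d23 + 1e-12)
    expect_lte(d13, d12 + d23 + 1e-12)
    expect_lte(d23, d12 + d13 + 1e-12)
  }
})

test_that("p-distance uses pairwise deletion and matches ape", {
  aln <- seq_alignment(rbind(A = c("A", "C", "G", "T"),
                             B = c("A", "C", "G", "T"),
                             C = c("A", "C", "G", "A"),
                             D = c("A", "C", "-", "T")))
  d <- p_distance_matrix(aln)
  expect_equal(d["A", "B"], 0)
  expect_equal(d["A", "C"], 0.25)
  expect_equal(d["A", "D"], 0)       # 3 comparable sites, 0 mismatches
  expect_equal(d["C", "D"], 1 / 3)   # sites 1,2,4 compared

  skip_if_not_installed("ape")
  set.seed(5)
  chars <- c("A", "C", "G", "T", "N", "-")
  m <- matrix(sample(chars, 6 * 60, replace = TRUE, prob = c(rep(1, 4), .05, .05)),
              6, 60, dimnames = list(sprintf("s%d", 1:6), NULL))
  mine <- p_distance_matrix(seq_alignment(m))
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(m)), model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(unclass(mine), ref[rownames(mine), rownames(mine)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("p-distance equals k/L for k planted substitutions", {
  base <- rep(c("A", "C", "G", "T"), 25)
  mut <- base
  mut[c(3, 10, 44)] <- c("T", "A", "C")  # 3 substitutions over L = 100
  d <- p_distance_matrix(seq_alignment(rbind(X = base, Y = mut)))
  expect_equal(d["X", "Y"], 3 / 100)
})

test_that("all-gap overlap raises an undefined-distance error", {
  aln <- seq_alignment(rbind(A = c("A", "-"), B = c("-", "T")))
  expect_error(p_distance_matrix(aln), "no comparable sites")
})

test_that("haversine matches analytic arcs, law of cosines and geosphere", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-9)
  expect_equal(haversine_km(0, 0, 1, 0), 6371.0088 * pi / 180,
               tolerance = 1e-9)
  set.seed(9)
  lat1 <- runif(40, -80, 80); lon1 <- runif(40, -180, 180)
  lat2 <- runif(40, -80, 80); lon2 <- runif(40, -180, 180)
  hav <- haversine_km(lat1, lon1, lat2, lon2)
  rad <- pi / 180
  loc <- 6371.0088 * acos(pmin(1, sin(lat1 * rad) * sin(lat2 * rad) +
    cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)))
  keep <- hav >= 1
  expect_true(all(abs(hav[keep] - loc[keep]) < 1e-6))
  skip_if_not_installed("geosphere")
  ref <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                  r = 6371008.8) / 1000
  expect_equal(hav, ref, tolerance = 1e-9)
})

test_that("species-site assignment uses majority rule with override", {
  counts <- matrix(1L, 3, 1, dimnames = list(c("a1", "a2", "a3"), "t1"))
  tab <- infection_table(counts,
                         species = c(a1 = "A", a2 = "A", a3 = "A"),
                         site = c(a1 = "S1", a2 = "S2", a3 = "S2"))
  expect_equal(majority_site_of_species(tab), c(A = "S2"))
  expect_equal(majority_site_of_species(tab, override = c(A = "S9")),
               c(A = "S9"))
})

test_that("geographic distance matrix built from species-site assignment", {
  sites <- site_table(data.frame(site_id = c("S1", "S2"),
                                 latitude = c(0, 0), longitude = c(0, 1)))
  d <- geographic_distance_matrix(sites, c(A = "S1", B = "S1", C = "S2"))
  expect_equal(d["A", "B"], 0)
  expect_equal(d["A", "C"], 6371.0088 * pi / 180, tolerance = 1e-9)
  expect_error(geographic_distance_matrix(sites, c(A = "S9")), "unknown site")
})

test_that("log transform of similarity makes zero handling explicit", {
  expect_equal(log_transform_similarity(1), 0)
  expect_equal(log_transform_similarity(0.5), log(0.5))
  expect_error(log_transform_similarity(0), "zero similarity")
  expect_equal(log_transform_similarity(0, epsilon = 0.01), log(0.01))
  expect_error(log_transform_similarity(1.2), "\\[0, 1\\]")
})
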