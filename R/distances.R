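#' Jaccard similarity between two presence/absence vectors
#'
#' `J = a / (a + b + c)` where `a` is the number of taxa shared and `b`,
#' `c` the numbers unique to each community. Two entirely empty communities
#' are defined as identical (`J = 1`); downstream analyses normally exclude
#' uninfected hosts before this situation can arise.
#'
#' @param x,y equal-length 0/1 vectors.
#' @return similarity in `[0, 1]`.
#' @examples
#' jaccard_similarity(c(1, 1, 1, 0), c(0, 1, 1, 1)) # 0.5
#' @export
jaccard_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("inputs must be 0/1 presence vectors", call. = FALSE)
  }
  a <- sum(x == 1 & y == 1)
  u <- sum(x == 1 | y == 1)
  if (u == 0L) return(1)
  a / u
}

#' Bray-Curtis similarity between two nonnegative abundance vectors
#'
#' `S = 1 - sum(|x - y|) / sum(x + y)`. Used with prevalence or mean
#' abundance profiles as well as raw counts.
#'
#' @param x,y equal-length nonnegative numeric vectors, not both all-zero.
#' @return similarity in `[0, 1]`.
#' @examples
#' bray_curtis_similarity(c(2, 2), c(0, 2)) # 1 - 2/6
#' @export
bray_curtis_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("negative entries", call. = FALSE)
  tot <- sum(x) + sum(y)
  if (tot == 0) {
    stop("Bray-Curtis similarity undefined for two all-zero vectors",
         call. = FALSE)
  }
  1 - sum(abs(x - y)) / tot
}

#' Similarity matrix across communities
#'
#' Applies [jaccard_similarity()] or [bray_curtis_similarity()] to every
#' pair of rows of a community profile matrix (communities x taxa).
#'
#' @param profiles numeric matrix with row names (community labels):
#'   0/1 for `metric = "jaccard"`, nonnegative for `"braycurtis"`.
#' @param metric `"jaccard"` or `"braycurtis"`.
#' @return a [distance_matrix()] of kind `"similarity"`. Use
#'   [as_dissimilarity()] for ordination/PERMANOVA.
#' @export
similarity_matrix <- function(profiles, metric = c("jaccard", "braycurtis")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  n <- nrow(profiles)
  fn <- if (metric == "jaccard") jaccard_similarity else bray_curtis_similarity
  s <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s[i, j] <- s[j, i] <- fn(profiles[i, ], profiles[j, ])
    }
  }
  dimnames(s) <- list(rownames(profiles), rownames(profiles))
  distance_matrix(s, "similarity")
}

#' Uncorrected p-distance matrix from an alignment
#'
#' For each pair of sequences, alignment columns where either sequence has
#' a gap (`-`) or ambiguity (`N`) are excluded (pairwise deletion); the
#' distance is the proportion of the remaining sites that differ.
#'
#' @param aln a [seq_alignment()].
#' @return a [distance_matrix()] of kind `"p_distance"`.
#' @export
p_distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  n <- nrow(aln)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  valid <- aln == "A" | aln == "C" | aln == "G" | aln == "T"
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- valid[i, ] & valid[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        stop(sprintf("no comparable sites between %s and %s",
                     rownames(aln)[i], rownames(aln)[j]), call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(aln[i, comp] != aln[j, comp]) / nc
    }
  }
  distance_matrix(d, "p_distance")
}

# mean Earth radius (km), as used by great-circle calculators
.EARTH_RADIUS_KM <- 6371.0088

#' Great-circle (haversine) distance in kilometres
#'
#' Spherical Earth with mean radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  phi1 <- lat1 * rad; phi2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * .EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Assign each host species to a single capture site
#'
#' Species are assigned the site at which most of their individuals were
#' captured (majority rule; ties broken by the lexicographically smallest
#' site id). This generalises the practice of treating a stray individual
#' as captured at the same location as its conspecifics. Individual
#' assignments can be overridden.
#'
#' @param x an [infection_table()].
#' @param override named character vector, species code -> site id, applied
#'   after the majority rule.
#' @return named character vector, species code -> site id.
#' @export
majority_site_of_species <- function(x, override = NULL) {
  stopifnot(inherits(x, "infection_table"))
  sp <- sort(unique(x$species))
  out <- vapply(sp, function(s) {
    tab <- sort(table(x$site[x$species == s]), decreasing = TRUE)
    names(tab)[tab == max(tab)][1L]
  }, character(1))
  if (!is.null(override)) out[names(override)] <- override
  out
}

#' Geographic distance matrix between host species
#'
#' Great-circle distances between the sites assigned to each species.
#' Co-located species are at distance 0.
#'
#' @param sites a `site_table`.
#' @param site_of_species named character vector, species code -> site id
#'   (see [majority_site_of_species()]).
#' @return a [distance_matrix()] of kind `"geographic_km"` labelled by
#'   species code.
#' @export
geographic_distance_matrix <- function(sites, site_of_species) {
  stopifnot(inherits(sites, "site_table"))
  missing <- setdiff(unname(site_of_species), sites$site_id)
  if (length(missing)) {
    stop("species mapped to unknown site(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sp <- names(site_of_species)
  idx <- match(site_of_species, sites$site_id)
  lat <- sites$latitude[idx]; lon <- sites$longitude[idx]
  n <- length(sp)
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n)) {
    d[i, ] <- haversine_km(lat[i], lon[i], lat, lon)
  }
  d[abs(d) < 1e-12] <- 0
  diag(d) <- 0
  distance_matrix((d + t(d)) / 2, "geographic_km")
}

#' Log-transform similarity values
#'
#' `log(S + epsilon)`, natural log, applied before the distance-decay
#' regressions to meet normality assumptions. The default `epsilon = 0`
#' raises a hard error if any similarity is exactly zero, so the handling
#' of zero-similarity pairs is an explicit user decision rather than a
#' silent offset.
#'
#' @param s numeric vector of similarities in `[0, 1]`.
#' @param epsilon nonnegative offset added before taking logs.
#' @return numeric vector `log(s + epsilon)`.
#' @export
log_transform_similarity <- function(s, epsilon = 0) {
  if (any(s < 0 | s > 1)) stop("similarities must lie in [0, 1]", call. = FALSE)
  if (epsilon < 0) stop("epsilon must be nonnegative", call. = FALSE)
  if (any(s + epsilon <= 0)) {
    stop(paste0("zero similarity with epsilon = 0: supply a positive ",
                "epsilon (e.g. half the smallest nonzero similarity) or ",
                "drop the zero-similarity pairs"), call. = FALSE)
  }
  log(s + epsilon)
}
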