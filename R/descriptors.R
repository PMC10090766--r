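#' Infracommunity descriptors
#'
#' One record per host individual: parasite species richness (number of
#' taxa present) and total abundance (number of parasite individuals).
#' Uninfected hosts are included with richness 0.
#'
#' @param x an [infection_table()].
#' @return a `data.frame` with columns `individual`, `species`, `site`,
#'   `richness`, `total_abundance`.
#' @examples
#' tab <- infection_table(
#'   matrix(c(2L, 0L, 3L, 0L), 2, 2,
#'          dimnames = list(c("i1", "i2"), c("t1", "t2"))),
#'   species = c(i1 = "A", i2 = "A"), site = c(i1 = "S1", i2 = "S1"))
#' infracommunity(tab)
#' @export
infracommunity <- function(x) {
  stopifnot(inherits(x, "infection_table"))
  data.frame(
    individual = individuals(x),
    species = unname(x$species),
    site = unname(x$site),
    richness = as.integer(rowSums(x$counts > 0L)),
    total_abundance = as.integer(rowSums(x$counts)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Presence/absence matrix at the infracommunity level
#'
#' @param x an [infection_table()].
#' @return integer 0/1 matrix, individuals x taxa.
#' @export
presence_matrix <- function(x) {
  stopifnot(inherits(x, "infection_table"))
  m <- (x$counts > 0L) * 1L
  dimnames(m) <- dimnames(x$counts)
  m
}

#' Component-community profiles per host species
#'
#' Descriptors sensu Bush et al.: for each host species and parasite taxon,
#' presence (0/1), prevalence (proportion of examined conspecific hosts
#' infected) and mean abundance (parasite individuals per examined host —
#' the denominator includes uninfected hosts; dividing by infected hosts
#' only would give mean intensity, which is not computed here).
#'
#' @param x an [infection_table()].
#' @return a list of class `component_profiles` with elements `species`
#'   (codes), `n_hosts` (named integer), and species-by-taxa matrices
#'   `presence`, `prevalence`, `mean_abundance`.
#' @export
component_profiles <- function(x) {
  stopifnot(inherits(x, "infection_table"))
  sp <- sort(unique(x$species))
  f <- factor(x$species, levels = sp)
  n_hosts <- as.integer(table(f))
  names(n_hosts) <- sp
  if (any(n_hosts == 0L)) stop("species with zero individuals", call. = FALSE)
  inf_counts <- rowsum((x$counts > 0L) * 1L, f)        # infected hosts per taxon
  sum_counts <- rowsum(x$counts + 0, f)                # total parasites per taxon
  prevalence <- inf_counts / n_hosts
  mean_abundance <- sum_counts / n_hosts
  presence <- (prevalence > 0) * 1L
  dn <- list(sp, taxa(x))
  dimnames(prevalence) <- dimnames(mean_abundance) <- dimnames(presence) <- dn
  structure(list(species = sp, n_hosts = n_hosts, presence = presence,
                 prevalence = prevalence, mean_abundance = mean_abundance),
            class = "component_profiles")
}

#' @export
print.component_profiles <- function(x, ...) {
  cat(sprintf("<component_profiles: %d species x %d taxa>\n",
              length(x$species), ncol(x$presence)))
  invisible(x)
}

#' Export component-community descriptors as tidy CSV
#'
#' One row per (host species, parasite taxon) with prevalence and mean
#' abundance.
#'
#' @param profiles a [component_profiles()] result.
#' @param path output CSV path.
#' @export
write_descriptors_csv <- function(profiles, path) {
  stopifnot(inherits(profiles, "component_profiles"))
  df <- expand.grid(species = profiles$species,
                    taxon = colnames(profiles$presence),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(match(df$species, profiles$species),
               match(df$taxon, colnames(profiles$presence)))
  df$presence <- profiles$presence[idx]
  df$prevalence <- profiles$prevalence[idx]
  df$mean_abundance <- profiles$mean_abundance[idx]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
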