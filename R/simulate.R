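#' Configuration for the synthetic host-parasite assemblage generator
#'
#' Defaults emulate a survey of deep-sea fish at the scale of the system
#' the package targets: 8 host species with per-species sample sizes
#' `(3, 5, 6, 8, 7, 12, 4, 7)` (52 individuals), 35 parasite taxa, a
#' 585 bp marker alignment, one trawling site per species inside a
#' Chatham-Rise-like bounding box, overdispersed counts and a fraction of
#' uninfected hosts. Parasite occurrence decays exponentially with host
#' phylogenetic and geographic distance from a taxon-specific affinity
#' host/site, at rates `lambda_phylo` (per unit p-distance) and
#' `lambda_geo` (per km).
#'
#' @param n_species number of host species.
#' @param n_individuals_per_species integer scalar or per-species vector.
#' @param n_sites number of trawling sites; species `i` is assigned site
#'   `((i - 1) %% n_sites) + 1` (species are site-segregated).
#' @param bounding_box list with `lat` and `lon` ranges (decimal degrees).
#' @param seq_length alignment length in positions.
#' @param tree_depth expected root-to-tip substitutions/site of the Yule
#'   host tree; 0 gives identical sequences.
#' @param n_parasites number of parasite taxa.
#' @param p0 baseline occurrence probability in the affinity host.
#' @param lambda_phylo occurrence decay rate per unit p-distance (>= 0).
#' @param lambda_geo occurrence decay rate per km (>= 0).
#' @param specificity_shape shape of the Gamma(shape, rate = shape)
#'   multiplier (mean 1) applied per taxon to `lambda_phylo`: real parasite
#'   faunas mix host specialists with near-generalists (e.g. anisakid
#'   larvae found in almost every host species), and this heterogeneity in
#'   host range keeps every species pair sharing at least some taxa, as
#'   observed. Small values = strong heterogeneity; `Inf` collapses to a
#'   single common decay rate.
#' @param mu0 mean count per host individual where a taxon occurs.
#' @param k negative-binomial dispersion (variance `mu + mu^2/k`); large
#'   `k` approaches Poisson.
#' @param p_uninfected_host probability that a host individual is forced
#'   uninfected (all counts zeroed).
#' @param seed integer seed driving the whole generator.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 8L,
                              n_individuals_per_species = c(3L, 5L, 6L, 8L,
                                                            7L, 12L, 4L, 7L),
                              n_sites = 8L,
                              bounding_box = list(lat = c(-44.5, -42.5),
                                                  lon = c(174, 180)),
                              seq_length = 585L,
                              tree_depth = 0.08,
                              n_parasites = 35L,
                              p0 = 0.6,
                              lambda_phylo = 10,
                              lambda_geo = 0.001,
                              specificity_shape = 0.4,
                              mu0 = 1.7,
                              k = 0.7,
                              p_uninfected_host = 6 / 52,
                              seed = 1L) {
  if (length(n_individuals_per_species) == 1L) {
    n_individuals_per_species <- rep(as.integer(n_individuals_per_species),
                                     n_species)
  }
  stopifnot(n_species >= 2L,
            length(n_individuals_per_species) == n_species,
            all(n_individuals_per_species >= 1L),
            n_sites >= 1L, seq_length >= 1L, tree_depth >= 0,
            n_parasites >= 1L, p0 >= 0, p0 <= 1,
            lambda_phylo >= 0, lambda_geo >= 0, specificity_shape > 0,
            mu0 > 0, k > 0,
            p_uninfected_host >= 0, p_uninfected_host <= 1)
  structure(list(n_species = as.integer(n_species),
                 n_individuals_per_species = as.integer(n_individuals_per_species),
                 n_sites = as.integer(n_sites),
                 bounding_box = bounding_box,
                 seq_length = as.integer(seq_length),
                 tree_depth = tree_depth,
                 n_parasites = as.integer(n_parasites),
                 p0 = p0, lambda_phylo = lambda_phylo,
                 lambda_geo = lambda_geo,
                 specificity_shape = specificity_shape,
                 mu0 = mu0, k = k,
                 p_uninfected_host = p_uninfected_host,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.species_codes <- function(cfg) sprintf("SP%02d", seq_len(cfg$n_species))

#' Simulate a host phylogeny and marker alignment
#'
#' A Yule (pure-birth) tree over the host species is rescaled so the mean
#' root-to-tip path equals `tree_depth` expected substitutions/site, and
#' sequences are evolved along it under the Jukes-Cantor model.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return a list with `alignment` (a [seq_alignment()]) and `tree` (an
#'   `ape::phylo` with species-code tip labels).
#' @export
simulate_host_phylogeny <- function(cfg, seed = cfg$seed) {
  codes <- .species_codes(cfg)
  .with_seed(seed, {
    tr <- ape::rphylo(cfg$n_species, birth = 1, death = 0)
    tr$tip.label <- codes
    depth <- mean(ape::node.depth.edgelength(tr)[seq_len(cfg$n_species)])
    tr$edge.length <- if (cfg$tree_depth == 0 || depth == 0) {
      rep(0, length(tr$edge.length))
    } else {
      tr$edge.length * cfg$tree_depth / depth
    }
    sim <- phangorn::simSeq(tr, l = cfg$seq_length, type = "DNA")
    m <- toupper(as.character(sim))
    list(alignment = seq_alignment(m[codes, , drop = FALSE]), tree = tr)
  })
}

#' Simulate trawling sites and the species-to-site assignment
#'
#' Coordinates are uniform in the bounding box; species are
#' site-segregated, species `i` at site `((i - 1) %% n_sites) + 1`.
#'
#' @inheritParams simulate_host_phylogeny
#' @return a list with `sites` (a `site_table`) and `site_of_species`
#'   (named character vector).
#' @export
simulate_sites <- function(cfg, seed = cfg$seed) {
  .with_seed(seed, {
    ids <- sprintf("S%d", seq_len(cfg$n_sites))
    sites <- site_table(data.frame(
      site_id = ids,
      latitude = stats::runif(cfg$n_sites, cfg$bounding_box$lat[1],
                              cfg$bounding_box$lat[2]),
      longitude = stats::runif(cfg$n_sites, cfg$bounding_box$lon[1],
                               cfg$bounding_box$lon[2])))
    site_of <- ids[(seq_len(cfg$n_species) - 1L) %% cfg$n_sites + 1L]
    names(site_of) <- .species_codes(cfg)
    list(sites = sites, site_of_species = site_of)
  })
}

#' Simulate parasite assemblages over hosts
#'
#' Each parasite taxon draws an affinity host species, an affinity site
#' and a host-specificity multiplier
#' `e ~ Gamma(specificity_shape, rate = specificity_shape)` (mean 1). Its
#' occurrence probability in host species `s` is
#' `p0 * exp(-lambda_phylo * e * d_phylo(s, affinity)) *
#' exp(-lambda_geo * d_geo(site_s, affinity_site))`. Hosts forced
#' uninfected (probability `p_uninfected_host` each) are chosen first and
#' receive no parasites. Where a taxon occurs in a species, each remaining
#' conspecific host receives a negative binomial count (mean `mu0`,
#' dispersion `k`), with one host bumped to a zero-truncated draw if all
#' counts came out zero — occurrence is presence in the component
#' community, so the injected decay acts directly on the presence/absence
#' pattern and abundance rides on occurrence. Taxon groups are drawn with
#' weights 14:11:10 for digenean:cestode:nematode.
#'
#' @inheritParams simulate_host_phylogeny
#' @param aln a [seq_alignment()] of the host species.
#' @param sites a `site_table`.
#' @param site_of_species named character vector, species -> site.
#' @return an [infection_table()].
#' @export
simulate_assemblages <- function(cfg, aln, sites, site_of_species,
                                 seed = cfg$seed) {
  codes <- .species_codes(cfg)
  stopifnot(all(codes %in% rownames(aln)),
            all(codes %in% names(site_of_species)))
  dphy <- if (cfg$tree_depth == 0) {
    m <- matrix(0, length(codes), length(codes), dimnames = list(codes, codes))
    distance_matrix(m, "p_distance")
  } else {
    p_distance_matrix(aln)
  }
  site_d <- matrix(0, nrow(sites), nrow(sites),
                   dimnames = list(sites$site_id, sites$site_id))
  for (i in seq_len(nrow(sites))) {
    site_d[i, ] <- haversine_km(sites$latitude[i], sites$longitude[i],
                                sites$latitude, sites$longitude)
  }
  .with_seed(seed, {
    txs <- sprintf("PT%02d", seq_len(cfg$n_parasites))
    grp <- sample(c("digenean", "cestode", "nematode"), cfg$n_parasites,
                  replace = TRUE, prob = c(14, 11, 10))
    names(grp) <- txs
    inds <- unlist(lapply(seq_along(codes), function(i) {
      sprintf("%s_%02d", codes[i], seq_len(cfg$n_individuals_per_species[i]))
    }))
    sp_of_ind <- rep(codes, cfg$n_individuals_per_species)
    counts <- matrix(0L, length(inds), cfg$n_parasites,
                     dimnames = list(inds, txs))
    forced <- stats::runif(length(inds)) < cfg$p_uninfected_host
    rtrunc_nb <- function() {
      repeat {
        v <- stats::rnbinom(1L, size = cfg$k, mu = cfg$mu0)
        if (v > 0L) return(v)
      }
    }
    for (t in seq_len(cfg$n_parasites)) {
      aff_sp <- sample(codes, 1L)
      aff_site <- sample(sites$site_id, 1L)
      e_t <- if (is.finite(cfg$specificity_shape)) {
        stats::rgamma(1L, shape = cfg$specificity_shape,
                      rate = cfg$specificity_shape)
      } else 1
      p_occ <- cfg$p0 *
        exp(-cfg$lambda_phylo * e_t * unclass(dphy)[codes, aff_sp]) *
        exp(-cfg$lambda_geo * site_d[site_of_species[codes], aff_site])
      occ <- stats::rbinom(length(codes), 1L, p_occ) == 1L
      for (s in which(occ)) {
        rows <- which(sp_of_ind == codes[s] & !forced)
        if (!length(rows)) next
        cnt <- stats::rnbinom(length(rows), size = cfg$k, mu = cfg$mu0)
        if (all(cnt == 0L)) cnt[sample.int(length(cnt), 1L)] <- rtrunc_nb()
        counts[rows, t] <- cnt
      }
    }
    site_of_ind <- site_of_species[sp_of_ind]
    names(site_of_ind) <- inds
    sp_named <- sp_of_ind
    names(sp_named) <- inds
    infection_table(counts, sp_named, site_of_ind, grp)
  })
}

#' Generate a complete synthetic dataset
#'
#' Bundles [simulate_host_phylogeny()], [simulate_sites()] and
#' [simulate_assemblages()] (with sub-seeds derived deterministically from
#' the config seed), simulates host lengths (species-level mean lengths
#' uniform on 25-75 cm, individual lognormal variation) and sex
#' (female-biased, 3:1), and optionally writes everything in the formats
#' the readers accept plus a ground-truth JSON for recovery tests.
#'
#' @param cfg a [simulation_config()].
#' @param dir optional output directory; created if needed. Files written:
#'   `infections.csv`, `sites.csv`, `alignment.fasta`, `hosts.csv`,
#'   `truth.json`.
#' @return a list with `infections`, `sites`, `site_of_species`,
#'   `alignment`, `tree`, `hosts`, `truth` (the generative parameters).
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  sub <- .with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, 4L))
  phy <- simulate_host_phylogeny(cfg, seed = sub[1])
  geo <- simulate_sites(cfg, seed = sub[2])
  inf <- simulate_assemblages(cfg, phy$alignment, geo$sites,
                              geo$site_of_species, seed = sub[3])
  hosts <- .with_seed(sub[4], {
    codes <- .species_codes(cfg)
    mean_len <- stats::runif(cfg$n_species, 25, 75)
    names(mean_len) <- codes
    ml <- mean_len[inf$species]
    data.frame(
      individual_id = individuals(inf),
      length = round(stats::rlnorm(n_individuals(inf),
                                   log(ml) - 0.005, 0.1), 1),
      sex = sample(c("F", "M"), n_individuals(inf), replace = TRUE,
                   prob = c(3, 1)),
      stringsAsFactors = FALSE)
  })
  truth <- c(unclass(cfg)[setdiff(names(unclass(cfg)), "bounding_box")],
             list(bounding_box = cfg$bounding_box,
                  total_parasites = sum(inf$counts)))
  out <- list(infections = inf, sites = geo$sites,
              site_of_species = geo$site_of_species,
              alignment = phy$alignment, tree = phy$tree,
              hosts = hosts, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_infection_csv(inf, file.path(dir, "infections.csv"))
    write_sites_csv(geo$sites, file.path(dir, "sites.csv"))
    write_fasta_alignment(phy$alignment, file.path(dir, "alignment.fasta"))
    utils::write.csv(hosts, file.path(dir, "hosts.csv"), row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
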