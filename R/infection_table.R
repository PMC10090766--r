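#' Infection table: parasite counts per host individual
#'
#' The central data container: an individuals-by-taxa matrix of nonnegative
#' integer counts, together with the host species and capture site of every
#' individual, and (optionally) a higher taxonomic group for every parasite
#' taxon (digenean, cestode, nematode, other). Uninfected individuals
#' (all-zero rows) are first-class citizens: they are retained here and only
#' excluded by downstream analyses that call for it (e.g. infracommunity
#' PERMANOVA and accumulation curves).
#'
#' @param counts integer matrix, individuals in rows, parasite taxa in
#'   columns, with dimnames. Values must be nonnegative integers.
#' @param species named character vector mapping individual id to host
#'   species code; names must cover the rows of `counts`.
#' @param site named character vector mapping individual id to site id.
#' @param taxon_group optional named character vector mapping taxon to one of
#'   `"digenean"`, `"cestode"`, `"nematode"`, `"other"`.
#' @return an object of class `infection_table` (a list with elements
#'   `counts`, `species`, `site`, `taxon_group`).
#' @export
infection_table <- function(counts, species, site, taxon_group = NULL) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have individual and taxon dimnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate individual ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon ids", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  inds <- rownames(counts)
  for (nm in c("species", "site")) {
    v <- get(nm)
    if (is.null(names(v)) || !all(inds %in% names(v))) {
      stop(sprintf("`%s` must be named and cover every individual", nm),
           call. = FALSE)
    }
  }
  species <- species[inds]
  site <- site[inds]
  if (any(is.na(species)) || any(is.na(site))) {
    stop("species/site assignments contain NA", call. = FALSE)
  }
  if (!is.null(taxon_group)) {
    taxon_group <- taxon_group[colnames(counts)]
    names(taxon_group) <- colnames(counts)
    bad <- !is.na(taxon_group) &
      !taxon_group %in% c("digenean", "cestode", "nematode", "other")
    if (any(bad)) {
      stop("taxon_group values must be digenean/cestode/nematode/other",
           call. = FALSE)
    }
  }
  structure(list(counts = counts, species = as.character(species) |>
                   stats::setNames(inds),
                 site = as.character(site) |> stats::setNames(inds),
                 taxon_group = taxon_group),
            class = "infection_table")
}

#' @export
print.infection_table <- function(x, ...) {
  cat(sprintf(paste0("<infection_table: %d individuals, %d host species, ",
                     "%d sites, %d parasite taxa, %d parasites>\n"),
              n_individuals(x), length(unique(x$species)),
              length(unique(x$site)), n_taxa(x), sum(x$counts)))
  invisible(x)
}

#' Accessors for infection tables
#'
#' @param x an `infection_table`.
#' @return `individuals` and `taxa` return character vectors; `n_individuals`
#'   and `n_taxa` integer counts; `uninfected_individuals` the ids of hosts
#'   with no parasites at all.
#' @export
individuals <- function(x) rownames(x$counts)

#' @rdname individuals
#' @export
taxa <- function(x) colnames(x$counts)

#' @rdname individuals
#' @export
n_individuals <- function(x) nrow(x$counts)

#' @rdname individuals
#' @export
n_taxa <- function(x) ncol(x$counts)

#' @rdname individuals
#' @export
uninfected_individuals <- function(x) {
  individuals(x)[rowSums(x$counts) == 0L]
}

#' Drop uninfected individuals from an infection table
#'
#' Mirrors the convention of excluding hosts with no parasites before
#' infracommunity-level multivariate tests and accumulation curves.
#'
#' @param x an `infection_table`.
#' @return an `infection_table` restricted to infected individuals.
#' @export
drop_uninfected <- function(x) {
  keep <- rowSums(x$counts) > 0L
  if (all(keep)) return(x)
  infection_table(x$counts[keep, , drop = FALSE], x$species[keep],
                  x$site[keep], x$taxon_group)
}

#' Merge morphologically indistinguishable parasite taxa
#'
#' Some taxa cannot be told apart for every specimen; analyses then treat
#' them as a single taxon. The merge is explicit: a named list mapping the
#' merged taxon name to the constituent taxon ids. Counts are summed.
#'
#' @param x an `infection_table`.
#' @param merge_map named list, e.g. `list(AB = c("A", "B"))`.
#' @return an `infection_table` with merged taxa. The group of a merged
#'   taxon is kept only if all constituents agree.
#' @export
merge_taxa <- function(x, merge_map) {
  stopifnot(inherits(x, "infection_table"), is.list(merge_map))
  counts <- x$counts
  grp <- x$taxon_group
  for (new in names(merge_map)) {
    olds <- merge_map[[new]]
    missing <- setdiff(olds, colnames(counts))
    if (length(missing)) {
      stop("cannot merge unknown taxa: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    summed <- rowSums(counts[, olds, drop = FALSE])
    counts <- counts[, setdiff(colnames(counts), olds), drop = FALSE]
    counts <- cbind(counts, matrix(as.integer(summed), ncol = 1,
                                   dimnames = list(NULL, new)))
    if (!is.null(grp)) {
      g <- unique(grp[olds])
      grp <- grp[setdiff(names(grp), olds)]
      grp[new] <- if (length(g) == 1L) g else NA_character_
    }
  }
  infection_table(counts, x$species, x$site, grp)
}
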