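#' Read a long-format infection CSV
#'
#' Expects a header `individual_id,host_species,site_id,parasite_taxon,count`
#' with an optional trailing `taxon_group` column. One row per host
#' individual and parasite taxon; duplicate `(individual, taxon)` rows are
#' summed. Individuals with no parasites can be declared with `count = 0`
#' rows (any taxon id) and are retained. The long layout supports sparse
#' tables and per-taxon group annotation.
#'
#' @param path CSV file path (RFC 4180, UTF-8, header required).
#' @return an [infection_table()].
#' @export
read_infection_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("individual_id", "host_species", "site_id", "parasite_taxon",
                "count")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("infection CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  if (any(is.na(cnt))) stop("non-numeric count value", call. = FALSE)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  # one species and one site per individual
  for (col in c("host_species", "site_id")) {
    tab <- unique(df[, c("individual_id", col)])
    dup <- tab$individual_id[duplicated(tab$individual_id)]
    if (length(dup)) {
      stop(sprintf("individual(s) mapped to more than one %s: %s", col,
                   paste(unique(dup), collapse = ", ")), call. = FALSE)
    }
  }
  inds <- unique(df$individual_id)
  txs <- unique(df$parasite_taxon)
  counts <- matrix(0L, length(inds), length(txs), dimnames = list(inds, txs))
  agg <- stats::aggregate(cnt, by = list(ind = df$individual_id,
                                         tax = df$parasite_taxon), FUN = sum)
  counts[cbind(match(agg$ind, inds), match(agg$tax, txs))] <- as.integer(agg$x)
  meta <- unique(df[, c("individual_id", "host_species", "site_id")])
  species <- stats::setNames(meta$host_species, meta$individual_id)
  site <- stats::setNames(as.character(meta$site_id), meta$individual_id)
  grp <- NULL
  if ("taxon_group" %in% names(df)) {
    gt <- unique(df[, c("parasite_taxon", "taxon_group")])
    gt <- gt[!is.na(gt$taxon_group) & gt$taxon_group != "", ]
    if (anyDuplicated(gt$parasite_taxon)) {
      stop("taxon assigned to more than one taxon_group", call. = FALSE)
    }
    grp <- stats::setNames(gt$taxon_group, gt$parasite_taxon)[txs]
    names(grp) <- txs
  }
  infection_table(counts, species, site, grp)
}

#' @rdname read_infection_csv
#' @param x an `infection_table`.
#' @return `write_infection_csv` returns `path` invisibly. Uninfected
#'   individuals are written as a single `count = 0` row so a round trip
#'   reproduces the table exactly.
#' @export
write_infection_csv <- function(x, path) {
  stopifnot(inherits(x, "infection_table"))
  pos <- which(x$counts > 0L, arr.ind = TRUE)
  rows <- data.frame(
    individual_id = individuals(x)[pos[, 1]],
    host_species = unname(x$species[pos[, 1]]),
    site_id = unname(x$site[pos[, 1]]),
    parasite_taxon = taxa(x)[pos[, 2]],
    count = x$counts[pos], stringsAsFactors = FALSE)
  un <- uninfected_individuals(x)
  if (length(un) && n_taxa(x) > 0L) {
    rows <- rbind(rows, data.frame(
      individual_id = un, host_species = unname(x$species[un]),
      site_id = unname(x$site[un]), parasite_taxon = taxa(x)[1L], count = 0L))
  }
  if (!is.null(x$taxon_group)) {
    rows$taxon_group <- unname(x$taxon_group[rows$parasite_taxon])
  }
  rows <- rows[order(rows$individual_id, rows$parasite_taxon), ]
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a site coordinate CSV
#'
#' Header `site_id,latitude,longitude`; decimal degrees, latitude in
#' `[-90, 90]` and longitude in `[-180, 180]`.
#'
#' @param path CSV file path.
#' @return a `data.frame` of class `site_table` with columns `site_id`,
#'   `latitude`, `longitude`.
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  site_table(df)
}

#' @rdname read_sites_csv
#' @param df data frame with columns `site_id`, `latitude`, `longitude`.
#' @export
site_table <- function(df) {
  required <- c("site_id", "latitude", "longitude")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("site table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id)) stop("duplicate site_id", call. = FALSE)
  if (any(is.na(df$latitude)) || any(is.na(df$longitude))) {
    stop("missing coordinate", call. = FALSE)
  }
  if (any(df$latitude < -90 | df$latitude > 90)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if (any(df$longitude < -180 | df$longitude > 180)) {
    stop("longitude outside [-180, 180]", call. = FALSE)
  }
  structure(df[, required], class = c("site_table", "data.frame"))
}

#' @rdname read_sites_csv
#' @param x a `site_table`.
#' @export
write_sites_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an aligned FASTA of host marker sequences
#'
#' Record ids are host species codes. Sequences are uppercased, `U` is
#' mapped to `T`, and all records must have equal length (the alignment is
#' assumed already trimmed, e.g. to a 585 bp cox1 fragment). Allowed
#' characters after normalisation: `A C G T N -`.
#'
#' @param path FASTA file path.
#' @return a `seq_alignment`: character matrix (species x positions).
#' @export
read_fasta_alignment <- function(path) {
  recs <- seqinr::read.fasta(path, forceDNAtolower = FALSE)
  if (!length(recs)) stop("empty FASTA", call. = FALSE)
  ids <- names(recs)
  if (anyDuplicated(ids)) stop("duplicate species codes in FASTA", call. = FALSE)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("ragged alignment: lengths %s", paste(unique(lens), collapse = ", ")),
         call. = FALSE)
  }
  m <- do.call(rbind, lapply(recs, function(s) toupper(as.character(s))))
  m[m == "U"] <- "T"
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    stop("characters outside alignment alphabet: ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  rownames(m) <- ids
  seq_alignment(m)
}

#' @rdname read_fasta_alignment
#' @param m character matrix of aligned sequences (rows = species codes).
#' @export
seq_alignment <- function(m) {
  stopifnot(is.matrix(m), is.character(m), !is.null(rownames(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate species codes", call. = FALSE)
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    stop("characters outside alignment alphabet: ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  structure(m, class = c("seq_alignment", "matrix", "array"))
}

#' @rdname read_fasta_alignment
#' @param aln a `seq_alignment`.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "seq_alignment"))
  seqinr::write.fasta(lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
                      names = rownames(aln), file.out = path)
  invisible(path)
}

#' Read host individual metadata (length, sex)
#'
#' Header `individual_id,length,sex`. Length in cm, positive when present
#' (blank = missing); sex `F`/`M` or blank.
#'
#' @param path CSV file path.
#' @return a `data.frame` with columns `individual_id`, `length`, `sex`.
#' @export
read_hosts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  required <- c("individual_id", "length", "sex")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("host metadata CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$individual_id)) {
    stop("duplicate individual_id in host metadata", call. = FALSE)
  }
  df$length <- as.numeric(df$length)
  if (any(!is.na(df$length) & df$length <= 0)) {
    stop("host length must be positive when present", call. = FALSE)
  }
  bad <- !is.na(df$sex) & !df$sex %in% c("F", "M")
  if (any(bad)) stop("sex must be F, M or missing", call. = FALSE)
  df[, required]
}

#' Cross-validate an assembled dataset
#'
#' Report-only consistency check across the infection table, site table and
#' host sequence alignment: host species with no sequence (allowed at load
#' time, rejected only by phylogenetic operations), individuals captured at
#' sites absent from the site table, and fully uninfected individuals
#' (retained in the table; excluded downstream where analyses call for it).
#'
#' @param infections an `infection_table`.
#' @param sites a `site_table`.
#' @param aln a `seq_alignment`.
#' @return a list of class `validation_report` with elements
#'   `species_without_sequence`, `individuals_at_unknown_sites`,
#'   `uninfected_individuals`, and logical `ok` (no issues of the first two
#'   kinds; uninfected hosts are informational).
#' @export
validate_dataset <- function(infections, sites, aln) {
  stopifnot(inherits(infections, "infection_table"),
            inherits(sites, "site_table"), inherits(aln, "seq_alignment"))
  sp_missing <- setdiff(unique(infections$species), rownames(aln))
  unknown_sites <- individuals(infections)[
    !infections$site %in% sites$site_id]
  rep <- structure(list(
    species_without_sequence = sp_missing,
    individuals_at_unknown_sites = unknown_sites,
    uninfected_individuals = uninfected_individuals(infections),
    ok = length(sp_missing) == 0L && length(unknown_sites) == 0L),
    class = "validation_report")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("  species without sequence:", paste(x$species_without_sequence,
                                           collapse = ", "), "\n")
  cat("  individuals at unknown sites:",
      paste(x$individuals_at_unknown_sites, collapse = ", "), "\n")
  cat("  uninfected individuals:",
      paste(x$uninfected_individuals, collapse = ", "), "\n")
  cat("  ok:", x$ok, "\n")
  invisible(x)
}

#' @rdname validate_dataset
#' @param report a `validation_report`.
#' @param path output JSON path.
#' @export
write_validation_json <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
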