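#' Load litter mass records
#'
#' Reads a CSV of per-microcosm litter dry masses with mandatory header
#' `unit_id,M_t0,M_ti`: `M_t0` is the initial dry mass and `M_ti` the dry
#' mass remaining at harvest, both in grams. Records violating the physical
#' invariants (`M_t0 > 0`, `0 <= M_ti <= M_t0`) are rejected at load: litter
#' bags cannot gain dry mass in these microcosms, so an apparent gain is a
#' data error, not a measurement to propagate.
#'
#' @param path CSV file path.
#' @return data.frame with columns `unit_id`, `M_t0`, `M_ti`, row order
#'   preserved (possibly zero rows).
#' @export
load_mass_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_mass_records(df)
}

validate_mass_records <- function(df) {
  req <- c("unit_id", "M_t0", "M_ti")
  if (!all(req %in% names(df)))
    schema_error(sprintf("mass records must have columns %s",
                         paste(req, collapse = ", ")))
  df <- df[req]
  if (nrow(df) == 0L) return(df)
  if (any(is.na(df$unit_id) | df$unit_id == ""))
    schema_error("mass record with missing unit_id")
  if (!is.numeric(df$M_t0) || !is.numeric(df$M_ti) || anyNA(df$M_t0) || anyNA(df$M_ti))
    schema_error("M_t0 and M_ti must be numeric and non-missing")
  if (any(df$M_t0 <= 0))
    schema_error(sprintf("non-positive M_t0 for unit(s): %s",
                         paste(df$unit_id[df$M_t0 <= 0], collapse = ", ")))
  if (any(df$M_ti < 0))
    schema_error(sprintf("negative M_ti for unit(s): %s",
                         paste(df$unit_id[df$M_ti < 0], collapse = ", ")))
  gain <- df$M_ti > df$M_t0
  if (any(gain))
    mass_gain_error(sprintf(
      "remaining mass exceeds initial mass for unit(s): %s",
      paste(df$unit_id[gain], collapse = ", ")))
  rownames(df) <- NULL
  df
}

#' Write litter mass records
#' @param records data.frame as returned by [load_mass_records()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mass_records <- function(records, path) {
  records <- validate_mass_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an OTU table
#'
#' Container for a samples-by-OTU fungal community table: a non-negative
#' integer count matrix (OTUs in rows, samples in columns), a ranked
#' taxonomy for every OTU, and an optional trophic-guild lookup. OTUs absent
#' from the taxonomy are filled in as `"unclassified"` at every rank, with a
#' warning.
#'
#' @param counts integer matrix, OTUs x samples, with dimnames.
#' @param taxonomy data.frame with column `otu_id` plus ranked lineage
#'   columns (`kingdom`, `phylum`, `class`, `order`, `family`, `genus`; any
#'   subset, in order).
#' @param guilds optional data.frame with columns `taxon`, `trophic_mode`,
#'   `confidence` (a FUNGuild-style lookup keyed by genus).
#' @return object of class `"otu_table"`: list with elements `counts`,
#'   `taxonomy`, `guilds`.
#' @export
otu_table <- function(counts, taxonomy, guilds = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    schema_error("counts must have OTU rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    schema_error("duplicate OTU ids in counts")
  if (anyDuplicated(colnames(counts)))
    schema_error("duplicate sample ids in counts")
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    schema_error("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  if (!"otu_id" %in% names(taxonomy))
    schema_error("taxonomy must have an otu_id column")
  if (anyDuplicated(taxonomy$otu_id))
    schema_error("duplicate otu_id in taxonomy")
  ranks <- setdiff(names(taxonomy), "otu_id")
  if (length(ranks) == 0L)
    schema_error("taxonomy must have at least one rank column")
  missing <- setdiff(rownames(counts), taxonomy$otu_id)
  if (length(missing) > 0L) {
    warning(sprintf("%d OTU(s) missing from taxonomy, filled as 'unclassified': %s",
                    length(missing), paste(utils::head(missing, 5), collapse = ", ")),
            call. = FALSE)
    fill <- as.data.frame(c(list(otu_id = missing),
                            stats::setNames(rep(list("unclassified"), length(ranks)), ranks)),
                          stringsAsFactors = FALSE)
    taxonomy <- rbind(taxonomy[c("otu_id", ranks)], fill)
  }
  taxonomy <- taxonomy[match(rownames(counts), taxonomy$otu_id), c("otu_id", ranks)]
  rownames(taxonomy) <- NULL
  if (!is.null(guilds)) {
    guilds <- as.data.frame(guilds, stringsAsFactors = FALSE)
    req <- c("taxon", "trophic_mode", "confidence")
    if (!all(req %in% names(guilds)))
      schema_error("guilds must have columns taxon, trophic_mode, confidence")
    guilds <- guilds[req]
  }
  structure(list(counts = counts, taxonomy = taxonomy, guilds = guilds),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "OTUs x", ncol(x$counts), "samples;",
      "ranks:", paste(setdiff(names(x$taxonomy), "otu_id"), collapse = "/"),
      if (!is.null(x$guilds)) sprintf("; %d guild entries", nrow(x$guilds)) else "",
      "\n")
  invisible(x)
}

#' Load an OTU table from TSV files
#'
#' @param counts_path TSV, rows = OTUs (first column `otu_id`), remaining
#'   columns = samples.
#' @param taxonomy_path TSV with `otu_id` plus ranked lineage columns.
#' @param guilds_path optional TSV with `taxon`, `trophic_mode`, `confidence`.
#' @return an [otu_table()].
#' @export
load_otu_table <- function(counts_path, taxonomy_path, guilds_path = NULL) {
  cts <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"otu_id" %in% names(cts))
    schema_error("counts TSV must have an otu_id column")
  if (anyDuplicated(cts$otu_id))
    schema_error("duplicate otu_id in counts TSV")
  m <- as.matrix(cts[setdiff(names(cts), "otu_id")])
  rownames(m) <- cts$otu_id
  tax <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
  guilds <- if (!is.null(guilds_path))
    utils::read.delim(guilds_path, stringsAsFactors = FALSE) else NULL
  otu_table(m, tax, guilds)
}

#' Write an OTU table to TSV files
#'
#' Inverse of [load_otu_table()]; round-trips exactly.
#'
#' @param table an [otu_table()].
#' @param counts_path,taxonomy_path,guilds_path output TSV paths
#'   (`guilds_path` only written when the table carries guilds).
#' @return `counts_path`, invisibly.
#' @export
write_otu_table <- function(table, counts_path, taxonomy_path,
                            guilds_path = NULL) {
  stopifnot(inherits(table, "otu_table"))
  cts <- data.frame(otu_id = rownames(table$counts), table$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cts, counts_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(table$taxonomy, taxonomy_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(table$guilds) && !is.null(guilds_path))
    utils::write.table(table$guilds, guilds_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}
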