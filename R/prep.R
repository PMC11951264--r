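#' Read quality-filter parameters
#'
#' Defaults follow the reference protocol for 350-bp ITS amplicon reads:
#' truncate at the first 50-bp sliding window (1-bp step) whose mean Phred
#' quality drops below 20, discard reads truncated shorter than 50 bp, and
#' discard reads containing ambiguous characters. The minimum pair overlap is
#' recorded for completeness but only applies when paired reads are merged,
#' which is upstream of this pipeline.
#'
#' @param window sliding-window width (bp).
#' @param min_mean_quality mean Phred threshold per window.
#' @param min_length_after_truncation shortest read kept after truncation (bp).
#' @param min_overlap minimum pair overlap (bp, recorded only).
#' @param drop_ambiguous discard reads containing `N`?
#' @return object of class `"filter_params"`.
#' @export
filter_params <- function(window = 50L, min_mean_quality = 20,
                          min_length_after_truncation = 50L,
                          min_overlap = 10L, drop_ambiguous = TRUE) {
  if (window <= 0 || min_mean_quality <= 0 ||
      min_length_after_truncation <= 0 || min_overlap <= 0)
    value_error("all filter thresholds must be positive")
  structure(list(window = as.integer(window),
                 min_mean_quality = min_mean_quality,
                 min_length_after_truncation = as.integer(min_length_after_truncation),
                 min_overlap = as.integer(min_overlap),
                 drop_ambiguous = isTRUE(drop_ambiguous)),
            class = "filter_params")
}

decode_phred <- function(qual) utf8ToInt(qual) - 33L

# truncation length under the sliding-window rule: windows advance 1 bp;
# the cut point is the first base of the first failing window. Reads shorter
# than one window are judged as a single whole-read window.
window_truncation_length <- function(q, window, min_mean) {
  n <- length(q)
  if (n < window) return(if (mean(q) < min_mean) 0L else n)
  cs <- cumsum(c(0, q))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  bad <- which(means < min_mean)
  if (length(bad) == 0L) n else bad[1] - 1L
}

#' Quality-filter amplicon reads
#'
#' Applies the sliding-window truncation rule of [filter_params()] to each
#' read and returns the surviving (possibly truncated) reads together with a
#' per-read disposition log. Dispositions are `"kept"`, `"ambiguous"`
#' (contains `N` and `drop_ambiguous` is on) and `"short"` (truncated below
#' the minimum length).
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (Phred+33), as
#'   from [simulate_reads()].
#' @param params a [filter_params()].
#' @return list with elements `reads` (kept reads, truncated) and `log`
#'   (data.frame `id`, `disposition`, `kept_length`).
#' @export
quality_filter <- function(reads, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  n <- nrow(reads)
  disposition <- character(n)
  kept_len <- integer(n)
  out_seq <- character(n)
  out_qual <- character(n)
  for (i in seq_len(n)) {
    q <- decode_phred(reads$qual[i])
    if (nchar(reads$seq[i]) != length(q))
      format_error(sprintf("read %s: sequence and quality lengths differ",
                           reads$id[i]))
    if (params$drop_ambiguous && grepl("[^ACGTacgt]", reads$seq[i])) {
      disposition[i] <- "ambiguous"; kept_len[i] <- 0L; next
    }
    len <- window_truncation_length(q, params$window, params$min_mean_quality)
    if (len < params$min_length_after_truncation) {
      disposition[i] <- "short"; kept_len[i] <- len
    } else {
      disposition[i] <- "kept"; kept_len[i] <- len
      out_seq[i] <- substr(reads$seq[i], 1L, len)
      out_qual[i] <- substr(reads$qual[i], 1L, len)
    }
  }
  keep <- disposition == "kept"
  list(reads = data.frame(id = reads$id[keep], seq = out_seq[keep],
                          qual = out_qual[keep], stringsAsFactors = FALSE),
       log = data.frame(id = reads$id, disposition = disposition,
                        kept_length = kept_len, stringsAsFactors = FALSE))
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads (multivariate hypergeometric draw). Samples whose total is below
#' the depth are dropped with a warning; a sample whose total equals the
#' depth is returned unchanged. The reference analysis rarefies to 57,742
#' reads per sample.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample.
#' @param seed integer seed for the subsampling.
#' @return a rarefied [otu_table()] (possibly with fewer samples).
#' @export
rarefy <- function(table, depth = 57742L, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (depth <= 0) value_error("rarefaction depth must be positive")
  depth <- as.integer(depth)
  totals <- colSums(table$counts)
  drop <- totals < depth
  if (any(drop))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(colnames(table$counts)[drop], collapse = ", ")),
            call. = FALSE)
  kept <- which(!drop)
  counts <- table$counts[, kept, drop = FALSE]
  with_seed(seed, {
    for (j in seq_along(kept)) {
      if (totals[kept[j]] == depth) next
      x <- counts[, j]
      picked <- sample.int(sum(x), depth)  # positions among the pooled reads
      breaks <- c(0L, cumsum(x))
      counts[, j] <- as.integer(tabulate(findInterval(picked, breaks,
                                                      left.open = TRUE),
                                         nbins = length(x)))
    }
    counts
  }) -> counts
  otu_table(counts, table$taxonomy, table$guilds)
}

#' Convert counts to relative abundances
#'
#' @param table an [otu_table()] or a non-negative numeric matrix
#'   (taxa x samples).
#' @return numeric matrix of the same shape with each column summing to 1.
#' @export
to_relative_abundance <- function(table) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  totals <- colSums(m)
  if (any(totals == 0))
    empty_sample_error(sprintf("sample(s) with zero total: %s",
                               paste(colnames(m)[totals == 0], collapse = ", ")))
  sweep(m, 2, totals, "/")
}

#' Aggregate an OTU table to a taxonomic rank
#'
#' Sums counts (or abundances) over OTUs sharing the same lineage value at
#' `rank`; OTUs unclassified at that rank are kept as their own
#' `"unclassified"` taxon. Per-sample totals are conserved exactly.
#'
#' @param table an [otu_table()].
#' @param rank `"phylum"` or `"class"`.
#' @return numeric matrix, taxa x samples.
#' @export
aggregate_taxa <- function(table, rank = c("class", "phylum")) {
  stopifnot(inherits(table, "otu_table"))
  rank <- match.arg(rank)
  if (!rank %in% names(table$taxonomy))
    value_error(sprintf("taxonomy has no '%s' rank", rank))
  lineage <- table$taxonomy[[rank]]
  lineage[is.na(lineage) | lineage == ""] <- "unclassified"
  if (nrow(table$counts) == 0L)
    return(matrix(numeric(), 0, ncol(table$counts),
                  dimnames = list(NULL, colnames(table$counts))))
  out <- rowsum(table$counts, group = lineage)
  out[order(rownames(out)), , drop = FALSE]
}

#' Trophic-guild assignment rule
#'
#' Guild calls are accepted only at the stated confidence levels (defaults:
#' "highly probable" and "probable"); anything else is left unassigned. With
#' saprotroph precedence on, any taxon whose trophic mode string contains a
#' saprotrophic component (e.g. "Saprotroph-Symbiotroph") is classified as a
#' saprotroph.
#'
#' @param accepted_confidences confidence levels accepted from the lookup.
#' @param saprotroph_precedence classify mixed-mode saprotroph-containing
#'   taxa as saprotrophs?
#' @return object of class `"guild_rule"`.
#' @export
guild_rule <- function(accepted_confidences = c("highly probable", "probable"),
                       saprotroph_precedence = TRUE) {
  if (length(accepted_confidences) == 0L)
    value_error("accepted_confidences must be non-empty")
  structure(list(accepted_confidences = accepted_confidences,
                 saprotroph_precedence = isTRUE(saprotroph_precedence)),
            class = "guild_rule")
}

#' Assign trophic guilds to OTUs
#'
#' Matches each OTU's genus against a guild lookup (`taxon`, `trophic_mode`,
#' `confidence`) under a [guild_rule()]. OTUs absent from the lookup or with
#' unaccepted confidence become `"unassigned"`; modes are collapsed to
#' `saprotroph` / `pathotroph` / `symbiotroph` with saprotroph precedence.
#'
#' @param table an [otu_table()].
#' @param guild_db guild lookup data.frame; defaults to the table's own
#'   `guilds` element.
#' @param rule a [guild_rule()].
#' @return character vector of guilds, one per OTU (named by otu_id).
#' @export
assign_guilds <- function(table, guild_db = table$guilds,
                          rule = guild_rule()) {
  stopifnot(inherits(table, "otu_table"), inherits(rule, "guild_rule"))
  if (is.null(guild_db)) schema_error("no guild lookup supplied")
  key <- if ("genus" %in% names(table$taxonomy))
    table$taxonomy$genus else table$taxonomy$otu_id
  idx <- match(key, guild_db$taxon)
  guild <- rep("unassigned", nrow(table$counts))
  hit <- !is.na(idx)
  ok <- hit & guild_db$confidence[idx] %in% rule$accepted_confidences
  mode <- tolower(guild_db$trophic_mode[idx[ok]])
  g <- rep("unassigned", sum(ok))
  g[grepl("symbiotroph", mode)] <- "symbiotroph"
  g[grepl("pathotroph", mode)] <- "pathotroph"
  if (rule$saprotroph_precedence) {
    g[grepl("saprotroph", mode)] <- "saprotroph"
  } else {
    only <- grepl("saprotroph", mode) & !grepl("symbiotroph|pathotroph", mode)
    g[only] <- "saprotroph"
  }
  guild[ok] <- g
  stats::setNames(guild, table$taxonomy$otu_id)
}

#' Select dominant classes by cumulative share
#'
#' Orders classes by mean relative abundance across samples (descending,
#' ties broken alphabetically) and returns the smallest prefix whose
#' cumulative mean share exceeds `cumulative_target`.
#'
#' @param class_table relative-abundance matrix, classes x samples (columns
#'   summing to 1), or a named vector of mean shares.
#' @param cumulative_target cumulative share to exceed (default 0.95).
#' @return character vector of class names, most abundant first.
#' @export
dominant_classes <- function(class_table, cumulative_target = 0.95) {
  means <- if (is.matrix(class_table)) rowMeans(class_table) else class_table
  if (length(means) == 0L) value_error("empty class table")
  ord <- order(-means, names(means))
  means <- means[ord]
  k <- which(cumsum(means) > cumulative_target)
  k <- if (length(k) == 0L) length(means) else k[1]
  names(means)[seq_len(k)]
}
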