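#' Bray-Curtis dissimilarity between two community vectors
#'
#' `1 - 2 * sum(min(u, v)) / (sum(u) + sum(v))`, in `[0, 1]`: 0 for
#' identical communities, 1 for disjoint supports.
#'
#' @param u,v non-negative abundance vectors on the same taxon index.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v))
    value_error("abundance vectors must have equal length")
  if (any(u < 0) || any(v < 0))
    value_error("abundances must be non-negative")
  tot <- sum(u) + sum(v)
  if (tot == 0)
    undefined_ratio_error("Bray-Curtis undefined for two all-zero vectors")
  1 - 2 * sum(pmin(u, v)) / tot
}

#' Bray-Curtis distance matrix over samples
#'
#' @param m abundance matrix, taxa x samples.
#' @return symmetric distance matrix, samples x samples, zero diagonal.
#' @export
bray_curtis_matrix <- function(m) {
  m <- as.matrix(m)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- bray_curtis(m[, i], m[, j])
  d
}

#' Per-taxon dissimilarity abundance
#'
#' Absolute binary-log fold difference of a taxon's relative abundance
#' between the paired home and away communities:
#' `|log2((x_home + pc) / (x_away + pc))|`. The pseudocount keeps the
#' statistic finite when a taxon is absent on one side; by convention it is
#' half the smallest non-zero relative abundance in the table. The statistic
#' is symmetric in its two arguments and non-negative.
#'
#' @param x_home,x_away relative abundances of the taxon in the two samples.
#' @param pseudocount non-negative pseudocount added to both sides.
#' @return dissimilarity abundance (>= 0). Vectorised.
#' @export
dissimilarity_abundance <- function(x_home, x_away, pseudocount = 0) {
  if (any(x_home < 0) || any(x_away < 0) || pseudocount < 0)
    value_error("abundances and pseudocount must be non-negative")
  if (any(x_home + pseudocount == 0 & x_away + pseudocount == 0))
    undefined_ratio_error(
      "dissimilarity abundance undefined: both abundances zero with zero pseudocount")
  abs(log2((x_home + pseudocount) / (x_away + pseudocount)))
}

half_min_pseudocount <- function(m) {
  pos <- m[m > 0]
  if (length(pos) == 0L) return(0)
  min(pos) / 2
}

#' Pair home and away samples
#'
#' For each species stream, pairs the sample of its litter decomposing in
#' the home soil with the sample of the same litter in the away soil, within
#' the same harvest event and replicate — mirroring the mean-HFA contrast.
#' The alternative `"site_fixed"` contrast holds the soil fixed and varies
#' the litter instead.
#'
#' @param units data.frame from [expand_design()] (two-species reciprocal).
#' @param contrast `"litter_fixed"` (default) or `"site_fixed"`.
#' @return data.frame with columns `species`, `harvest_id`, `month`,
#'   `treatment`, `replicate`, `home_sample`, `away_sample`.
#' @export
pair_samples <- function(units, contrast = c("litter_fixed", "site_fixed")) {
  contrast <- match.arg(contrast)
  species <- sort(unique(units$litter_species))
  if (!setequal(species, unique(units$soil_source)))
    design_error("pair_samples requires a reciprocal design")
  out <- list()
  keys <- unique(units[c("harvest_id", "month", "treatment", "replicate")])
  for (sp in species) {
    other <- setdiff(species, sp)
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      pick <- function(litter, soil) {
        id <- units$unit_id[units$harvest_id == k$harvest_id &
                              units$replicate == k$replicate &
                              units$litter_species == litter &
                              units$soil_source == soil]
        if (length(id) != 1L)
          incomplete_design_error(sprintf(
            "missing sample: litter %s in soil %s at harvest %s replicate %s",
            litter, soil, k$harvest_id, k$replicate))
        id
      }
      home <- pick(sp, sp)
      away <- if (contrast == "litter_fixed") {
        # same litter, foreign soil (one away partner per species when |species| = 2)
        pick(sp, other[1])
      } else {
        pick(other[1], sp)
      }
      out[[length(out) + 1L]] <- data.frame(
        species = sp, harvest_id = k$harvest_id, month = k$month,
        treatment = k$treatment, replicate = k$replicate,
        home_sample = home, away_sample = away, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$species, res$month, res$treatment, res$replicate), ]
  rownames(res) <- NULL
  res
}

#' Home/away dissimilarity table
#'
#' For every home/away sample pair: OTU-level Bray-Curtis dissimilarity,
#' per-class dissimilarity abundance for each dominant class, and the
#' dissimilarity abundance of the summed saprotroph share. Bray-Curtis is
#' computed on OTU counts; the log-ratio statistics on class-rank relative
#' abundances, with a table-wide half-minimum pseudocount by default.
#'
#' @param table an [otu_table()] (ideally rarefied).
#' @param pairs data.frame from [pair_samples()].
#' @param dominant character vector of dominant class names; defaults to
#'   [dominant_classes()] on the table's class-rank profile.
#' @param guild character guild vector from [assign_guilds()], or `NULL` to
#'   derive it from the table's own guild lookup (skipped if absent).
#' @param pseudocount pseudocount for the log-ratios; default half the
#'   smallest non-zero class relative abundance.
#' @return data.frame: one row per pair with `bray_curtis`, one
#'   `dis_<class>` column per dominant class, and `dis_saprotroph`.
#' @export
dissimilarity_table <- function(table, pairs, dominant = NULL, guild = NULL,
                                pseudocount = NULL) {
  stopifnot(inherits(table, "otu_table"))
  samp <- unique(c(pairs$home_sample, pairs$away_sample))
  missing <- setdiff(samp, colnames(table$counts))
  if (length(missing) > 0L)
    incomplete_design_error(sprintf("pairs reference missing sample(s): %s",
                                    paste(utils::head(missing, 5), collapse = ", ")))
  cls <- aggregate_taxa(table, "class")
  cls_rel <- to_relative_abundance(cls)
  if (is.null(dominant)) dominant <- dominant_classes(cls_rel)
  absent <- setdiff(dominant, rownames(cls_rel))
  if (length(absent) > 0L)
    message("dominant class(es) absent from table, using pseudocount only: ",
            paste(absent, collapse = ", "))
  if (is.null(pseudocount)) pseudocount <- half_min_pseudocount(cls_rel)
  if (is.null(guild) && !is.null(table$guilds))
    guild <- assign_guilds(table)
  rel <- to_relative_abundance(table$counts)
  res <- pairs
  res$bray_curtis <- mapply(function(h, a)
    bray_curtis(table$counts[, h], table$counts[, a]),
    pairs$home_sample, pairs$away_sample)
  get_cls <- function(cl, ids) {
    if (cl %in% rownames(cls_rel)) cls_rel[cl, ids] else rep(0, length(ids))
  }
  for (cl in dominant)
    res[[paste0("dis_", cl)]] <- dissimilarity_abundance(
      get_cls(cl, pairs$home_sample), get_cls(cl, pairs$away_sample),
      pseudocount)
  if (!is.null(guild)) {
    sap <- guild == "saprotroph"
    sap_share <- colSums(rel[sap, , drop = FALSE])
    res$dis_saprotroph <- dissimilarity_abundance(
      sap_share[pairs$home_sample], sap_share[pairs$away_sample], pseudocount)
    res$saprotroph_share_home <- unname(sap_share[pairs$home_sample])
  }
  rownames(res) <- NULL
  res
}
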