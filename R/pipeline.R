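#' Shannon diversity of a count vector
#'
#' `-sum(p_k log p_k)` over non-zero proportions, in nats by default.
#'
#' @param counts non-negative count (or abundance) vector.
#' @param base logarithm base; `exp(1)` (nats) by default, 2 for bits.
#' @return Shannon diversity.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (sum(counts) <= 0) empty_sample_error("empty sample")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Observed richness of a count vector
#'
#' @param counts non-negative count vector.
#' @return number of taxa with count > 0.
#' @export
observed_richness <- function(counts) sum(counts > 0)

#' Two-phase analysis plan
#'
#' Phase I covers the control (CK) harvests across the decomposition time
#' course; phase II is the late-stage contrast between the control and
#' glucose-amended batches of the final harvest month. Statistical settings
#' shared by both phases live here.
#'
#' @param phase1_months harvest months analysed in phase I (CK units only).
#' @param phase2_month the single month of the phase-II contrast.
#' @param pairing replicate pairing policy for [hfa_table()].
#' @param alpha significance level.
#' @param n_perm PERMANOVA permutations.
#' @param rarefaction_depth reads per sample for [rarefy()].
#' @param pseudocount log-ratio pseudocount, or `NULL` for half-minimum.
#' @param seed integer seed for all stochastic steps.
#' @return object of class `"phase_plan"`.
#' @export
phase_plan <- function(phase1_months = c(1L, 2L, 4L, 6L), phase2_month = 6L,
                       pairing = "replicate_index", alpha = 0.05,
                       n_perm = 999, rarefaction_depth = 57742L,
                       pseudocount = NULL, seed = 1L) {
  structure(list(phase1_months = as.integer(phase1_months),
                 phase2_month = as.integer(phase2_month),
                 pairing = pairing, alpha = alpha, n_perm = n_perm,
                 rarefaction_depth = as.integer(rarefaction_depth),
                 pseudocount = pseudocount, seed = as.integer(seed)),
            class = "phase_plan")
}

# shared community workflow for a unit subset
community_block <- function(otu, units, plan, terms) {
  keep <- intersect(colnames(otu$counts), units$unit_id)
  if (length(keep) < nrow(units))
    incomplete_design_error(sprintf(
      "community samples missing for %d unit(s)", nrow(units) - length(keep)))
  sub <- otu_table(otu$counts[, units$unit_id, drop = FALSE],
                   otu$taxonomy, otu$guilds)
  rar <- rarefy(sub, depth = plan$rarefaction_depth, seed = plan$seed)
  units <- units[units$unit_id %in% colnames(rar$counts), ]
  alpha_df <- data.frame(
    unit_id = colnames(rar$counts),
    richness = apply(rar$counts, 2, observed_richness),
    shannon = apply(rar$counts, 2, shannon_index),
    stringsAsFactors = FALSE)
  alpha_df <- merge(alpha_df, units, by = "unit_id", sort = FALSE)
  alpha_tests <- lapply(c(richness = "richness", shannon = "shannon"),
                        function(v) {
    lapply(stats::setNames(terms, terms), function(trm) {
      g <- alpha_df[[trm]]
      if (length(unique(g)) < 2L) return(NULL)
      gate <- assumption_gate(alpha_df[[v]], g, alpha = plan$alpha)
      one_way_anova_bonferroni(gate$values, g, alpha = plan$alpha)
    })
  })
  bc <- bray_curtis_matrix(rar$counts)
  ord <- pcoa(bc)
  fac <- units[match(colnames(bc), units$unit_id), terms, drop = FALSE]
  perm <- permanova(bc, fac, terms = terms, n_perm = plan$n_perm,
                    seed = plan$seed)
  cls_rel <- to_relative_abundance(aggregate_taxa(rar, "class"))
  dom <- dominant_classes(cls_rel)
  pairs <- pair_samples(units)
  diss <- dissimilarity_table(rar, pairs, dominant = dom,
                              pseudocount = plan$pseudocount)
  list(rarefied = rar, units = units, alpha = alpha_df,
       alpha_tests = alpha_tests, bray_curtis = bc, pcoa = ord,
       permanova = perm, dominant = dom, dissimilarity = diss)
}

# regressions of per-pair mean HFA on dissimilarity predictors
linkage_block <- function(mean_hfa_df, diss, dominant) {
  key <- c("species", "harvest_id", "replicate")
  m <- merge(mean_hfa_df, diss, by = key, sort = FALSE)
  y <- m$mean_hfa
  res <- list(community = tryCatch(simple_linkage(y, m$bray_curtis),
                                   error = function(e) e))
  res$per_class <- lapply(stats::setNames(dominant, dominant), function(cl)
    tryCatch(simple_linkage(y, m[[paste0("dis_", cl)]]),
             error = function(e) e))
  if ("dis_saprotroph" %in% names(m))
    res$saprotroph <- tryCatch(simple_linkage(y, m$dis_saprotroph),
                               error = function(e) e)
  pred <- m[paste0("dis_", dominant)]
  names(pred) <- dominant
  res$multi_taxon <- tryCatch(multi_taxon_linkage(y, pred),
                              error = function(e) e, warning = function(w) {
                                suppressWarnings(multi_taxon_linkage(y, pred))
                              })
  res$data <- m
  res
}

#' Run the phase-I analysis (HFA and fungal community over time)
#'
#' Restricts the experiment to control (CK) units at the phase-I harvest
#' months and computes: the HFA index per harvest with a one-way ANOVA and
#' Bonferroni letters across months; and, when a community table is
#' supplied, rarefied alpha diversity (richness, Shannon) with
#' assumption-gated ANOVAs, PCoA and PERMANOVA (soil source + litter
#' species + month), home/away dissimilarity tables, and the mean-HFA
#' linkage regressions (whole-community Bray-Curtis, per dominant class,
#' saprotrophs, and the eight-taxon multiple regression).
#'
#' @param mass mass-record data.frame.
#' @param units unit table from [expand_design()].
#' @param otu an [otu_table()], or `NULL` for a mass-only analysis.
#' @param plan a [phase_plan()].
#' @return list report: `units`, `hfa`, `hfa_anova`, and (with communities)
#'   `community` and `linkage`.
#' @export
run_phase1 <- function(mass, units, otu = NULL, plan = phase_plan()) {
  stopifnot(inherits(plan, "phase_plan"))
  u1 <- units[units$treatment == "CK" & units$month %in% plan$phase1_months, ]
  missing <- setdiff(plan$phase1_months, unique(u1$month))
  if (length(missing) > 0L)
    incomplete_design_error(sprintf("phase-1 harvest month(s) absent: %s",
                                    paste(missing, collapse = ", ")))
  hfa <- hfa_table(mass, u1, pairing = plan$pairing)
  # HFA can be negative, so the gate transform is a min-shifted log
  gate <- assumption_gate(hfa$hfa$hfa, hfa$hfa$month, alpha = plan$alpha,
                          transform = function(x) log(x - min(x) + 1))
  hfa_anova <- one_way_anova_bonferroni(gate$values, hfa$hfa$month,
                                        alpha = plan$alpha)
  report <- list(units = u1, hfa = hfa, hfa_gate = gate,
                 hfa_anova = hfa_anova)
  if (!is.null(otu)) {
    report$community <- community_block(otu, u1, plan,
                                        terms = c("soil_source",
                                                  "litter_species", "month"))
    report$linkage <- linkage_block(hfa$mean_hfa,
                                    report$community$dissimilarity,
                                    report$community$dominant)
  }
  report
}

#' Run the phase-II analysis (glucose contrast at the final harvest)
#'
#' Restricts the experiment to the final-month control and glucose batches
#' and computes: the HFA index per treatment with a two-sample t-test
#' (Welch, with a warning if the arms are unbalanced); and, when a
#' community table is supplied, alpha-diversity ANOVAs by treatment and
#' soil, PERMANOVA (soil source + litter species + treatment), and the
#' dissimilarity/linkage tables for the glucose contrast.
#'
#' @inheritParams run_phase1
#' @return list report: `units`, `hfa`, `hfa_t_test`,
#'   `hfa_difference` (mean glucose HFA minus mean CK HFA, percentage
#'   points), and (with communities) `community` and `linkage`.
#' @export
run_phase2 <- function(mass, units, otu = NULL, plan = phase_plan()) {
  stopifnot(inherits(plan, "phase_plan"))
  u2 <- units[units$month == plan$phase2_month, ]
  if (!all(c("CK", "glucose") %in% u2$treatment))
    incomplete_design_error("phase 2 needs both CK and glucose units at the contrast month")
  hfa <- hfa_table(mass, u2, pairing = plan$pairing)
  g <- hfa$hfa$hfa[hfa$hfa$treatment == "glucose"]
  ck <- hfa$hfa$hfa[hfa$hfa$treatment == "CK"]
  if (length(g) != length(ck))
    warning("unbalanced treatment arms; Welch t-test used", call. = FALSE)
  tt <- two_sample_t(g, ck, variant = "welch")
  report <- list(units = u2, hfa = hfa, hfa_t_test = tt,
                 hfa_difference = mean(g) - mean(ck))
  if (!is.null(otu)) {
    report$community <- community_block(otu, u2, plan,
                                        terms = c("soil_source",
                                                  "litter_species",
                                                  "treatment"))
    report$linkage <- linkage_block(hfa$mean_hfa,
                                    report$community$dissimilarity,
                                    report$community$dominant)
  }
  report
}
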