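#' Dominant fungal classes of the reference system
#'
#' The eight class-level taxa (including the pooled unclassified fraction)
#' that together dominate conifer-litter soil fungal communities in this
#' system, used as the default dominant set throughout.
#' @export
DOMINANT_CLASSES <- c("Sordariomycetes", "Eurotiomycetes", "Tremellomycetes",
                      "Mortierellomycotina", "Agaricomycetes",
                      "Orbiliomycetes", "Leotiomycetes", "unclassified")

# phylum lookup for simulated classes (minor classes included)
CLASS_PHYLUM <- c(
  Sordariomycetes = "Ascomycota", Eurotiomycetes = "Ascomycota",
  Orbiliomycetes = "Ascomycota", Leotiomycetes = "Ascomycota",
  Tremellomycetes = "Basidiomycota", Agaricomycetes = "Basidiomycota",
  Mortierellomycotina = "Mortierellomycota", unclassified = "unclassified",
  Pezizomycetes = "Ascomycota", Dothideomycetes = "Ascomycota",
  Microbotryomycetes = "Basidiomycota", Glomeromycetes = "Glomeromycota")

#' Fungal community model for the synthetic experiment
#'
#' Generates soil fungal OTU tables with the compositional structure the
#' reciprocal-transplant system exhibits: strong soil-source separation,
#' temporal succession (Ascomycota classes declining, Basidiomycota classes
#' rising, an r- to K-strategist shift), and a glucose-driven boost of
#' Basidiomycota under the labile-carbon treatment.
#'
#' Composition is modelled at class level. Each class `c` has a baseline
#' share `base_shares[c]`; per sample the log-share is shifted by
#' `source_effect/2 * s_c` with a fixed alternating sign pattern `s_c` whose
#' direction depends on the soil source, by `succession_slope * month`
#' (negative for Ascomycota classes, positive for Basidiomycota), and by
#' `glucose_shift` for Basidiomycota classes in glucose-treated units.
#' Shifted log-shares are renormalised (softmax), spread over the class's
#' OTUs via fixed within-class base proportions, jittered with a Dirichlet
#' draw (`dirichlet_concentration` total), and counts drawn multinomially at
#' a library size uniform on `library_size` — i.e. OTU counts are
#' Dirichlet-multinomial around structured class expectations.
#'
#' Default baseline shares give the eight dominant classes a combined 0.96
#' expected share, with four minor classes holding the remainder. The
#' default library-size range (60,000–100,000) keeps rarefaction at the
#' reference depth of 57,742 feasible for every sample.
#'
#' @param n_otus_dominant OTUs simulated per dominant class.
#' @param n_otus_minor OTUs per minor class.
#' @param base_shares named baseline class shares, summing to 1; the eight
#'   dominant classes' combined share is the expected dominant fraction.
#' @param source_effect log-scale class shift separating the two soil
#'   sources.
#' @param succession_slope per-month log-share trend applied negatively to
#'   Ascomycota and positively to Basidiomycota classes.
#' @param glucose_shift log-share boost for Basidiomycota classes under
#'   glucose.
#' @param dirichlet_concentration total Dirichlet concentration for
#'   within-sample OTU jitter (larger = less overdispersion).
#' @param library_size length-2 integer range of per-sample read totals.
#' @param p_saprotroph named per-class probability that a simulated genus is
#'   saprotrophic (used to build the synthetic guild lookup).
#' @return object of class `"community_model"`.
#' @export
community_model <- function(
    n_otus_dominant = 12L,
    n_otus_minor = 10L,
    base_shares = c(Sordariomycetes = 0.30, Eurotiomycetes = 0.14,
                    Tremellomycetes = 0.12, Mortierellomycotina = 0.10,
                    Agaricomycetes = 0.12, Orbiliomycetes = 0.07,
                    Leotiomycetes = 0.06, unclassified = 0.05,
                    Pezizomycetes = 0.015, Dothideomycetes = 0.012,
                    Microbotryomycetes = 0.008, Glomeromycetes = 0.005),
    source_effect = 1.0,
    succession_slope = 0.08,
    glucose_shift = 0.5,
    dirichlet_concentration = 300,
    library_size = c(60000L, 100000L),
    p_saprotroph = c(Sordariomycetes = 0.85, Eurotiomycetes = 0.7,
                     Tremellomycetes = 0.5, Mortierellomycotina = 0.8,
                     Agaricomycetes = 0.6, Orbiliomycetes = 0.4,
                     Leotiomycetes = 0.6, unclassified = 0,
                     Pezizomycetes = 0.5, Dothideomycetes = 0.5,
                     Microbotryomycetes = 0.3, Glomeromycetes = 0.1)) {
  if (abs(sum(base_shares) - 1) > 1e-8)
    value_error("base_shares must sum to 1")
  if (any(base_shares <= 0)) value_error("base_shares must be positive")
  if (!all(names(base_shares) %in% names(CLASS_PHYLUM)))
    value_error("base_shares names must be known simulated classes")
  if (length(library_size) != 2L || any(library_size < 1))
    value_error("library_size must be a range of positive integers")
  if (dirichlet_concentration <= 0)
    value_error("dirichlet_concentration must be positive")
  structure(list(
    n_otus_dominant = as.integer(n_otus_dominant),
    n_otus_minor = as.integer(n_otus_minor),
    base_shares = base_shares,
    source_effect = source_effect,
    succession_slope = succession_slope,
    glucose_shift = glucose_shift,
    dirichlet_concentration = dirichlet_concentration,
    library_size = as.integer(library_size),
    p_saprotroph = p_saprotroph
  ), class = "community_model")
}

rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# expected class shares for one unit (soil source, month, treatment)
class_shares_for_unit <- function(model, classes, soil_sources,
                                  soil, month, treatment) {
  lg <- log(model$base_shares[classes])
  sgn <- rep_len(c(1, -1), length(classes))          # fixed per-class pattern
  dir <- if (soil == soil_sources[1]) 1 else -1      # direction per source
  lg <- lg + dir * model$source_effect / 2 * sgn
  phy <- CLASS_PHYLUM[classes]
  lg <- lg - model$succession_slope * month * (phy == "Ascomycota") +
    model$succession_slope * month * (phy == "Basidiomycota")
  if (treatment == "glucose")
    lg <- lg + model$glucose_shift * (phy == "Basidiomycota")
  p <- exp(lg)
  p / sum(p)
}

#' Simulate soil fungal communities for a design
#'
#' Draws one Dirichlet-multinomial OTU community per microcosm unit of
#' `design` under a [community_model()], and emits the matching taxonomy
#' (kingdom/phylum/class/genus) and a synthetic genus-level guild lookup in
#' which each genus is saprotrophic with a class-dependent probability
#' (confidence levels drawn from "highly probable" / "probable" /
#' "possible", so the guild confidence filter is exercised).
#'
#' @param design an [experiment_design()].
#' @param model a [community_model()].
#' @param seed integer seed; identical (design, model, seed) give identical
#'   tables.
#' @return an [otu_table()] whose samples are the design's unit ids.
#' @export
simulate_communities <- function(design, model = community_model(),
                                 seed = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(model, "community_model"))
  units <- expand_design(design)
  classes <- names(model$base_shares)
  n_per <- ifelse(classes %in% DOMINANT_CLASSES,
                  model$n_otus_dominant, model$n_otus_minor)
  otu_class <- rep(classes, n_per)
  otu_ids <- paste0("OTU", sprintf("%04d", seq_along(otu_class)))
  with_seed(seed, {
    # fixed within-class OTU base proportions for this run
    base_prop <- unlist(lapply(n_per, function(k) rdirichlet(rep(1.5, k))))
    lib <- sample(model$library_size[1]:model$library_size[2],
                  nrow(units), replace = TRUE)
    counts <- matrix(0L, nrow = length(otu_ids), ncol = nrow(units),
                     dimnames = list(otu_ids, units$unit_id))
    for (i in seq_len(nrow(units))) {
      cs <- class_shares_for_unit(model, classes, design$soil_sources,
                                  units$soil_source[i], units$month[i],
                                  units$treatment[i])
      p <- base_prop * cs[otu_class]
      p <- p / sum(p)
      pj <- rdirichlet(p * model$dirichlet_concentration)
      counts[, i] <- stats::rmultinom(1, size = lib[i], prob = pj)
    }
    genus <- paste0("g__", otu_class, "_", unlist(lapply(n_per, seq_len)))
    taxonomy <- data.frame(
      otu_id = otu_ids, kingdom = "Fungi",
      phylum = unname(CLASS_PHYLUM[otu_class]),
      class = otu_class, genus = genus, stringsAsFactors = FALSE)
    sap <- stats::runif(length(genus)) < model$p_saprotroph[otu_class]
    guilds <- data.frame(
      taxon = genus,
      trophic_mode = ifelse(sap,
                            sample(c("Saprotroph", "Saprotroph-Symbiotroph"),
                                   length(genus), replace = TRUE),
                            sample(c("Symbiotroph", "Pathotroph"),
                                   length(genus), replace = TRUE)),
      confidence = sample(c("highly probable", "probable", "possible"),
                          length(genus), replace = TRUE,
                          prob = c(0.5, 0.35, 0.15)),
      stringsAsFactors = FALSE)
    otu_table(counts, taxonomy, guilds)
  })
}

#' Simulate a complete two-phase experiment
#'
#' Convenience wrapper drawing both the mass records and the fungal
#' communities for a design under one seed.
#'
#' @param design an [experiment_design()].
#' @param decay a [decay_model()].
#' @param community a [community_model()], or `NULL` to skip communities.
#' @param seed integer seed.
#' @return list with elements `units`, `mass`, `otu` (NULL if skipped).
#' @export
simulate_experiment <- function(design = default_design(),
                                decay = decay_model(),
                                community = community_model(),
                                seed = NULL) {
  list(units = expand_design(design),
       mass = simulate_mass_loss(design, decay, seed = seed),
       otu = if (!is.null(community))
         simulate_communities(design, community,
                              seed = if (is.null(seed)) NULL else seed + 1L))
}

#' Simulate amplicon reads with controllable quality structure
#'
#' Fixture generator for the read quality filter: constant-length reads with
#' per-base Phred qualities around `base_quality`, optionally with a
#' low-quality block (`dip_quality` from `dip_start` onward) and a given
#' rate of reads containing an ambiguous base (`N`).
#'
#' @param n_reads number of reads.
#' @param length read length (bp).
#' @param base_quality mean Phred score outside the dip.
#' @param quality_sd per-base Phred jitter (rounded, clamped to \[2, 41\]).
#' @param dip_start 1-based position where the low-quality block starts, or
#'   `NULL` for none.
#' @param dip_quality Phred score inside the block.
#' @param ambiguous_rate fraction of reads given one `N`.
#' @param seed integer seed.
#' @return data.frame with columns `id`, `seq`, `qual` (Sanger Phred+33
#'   quality string); zero rows when `n_reads = 0`.
#' @export
simulate_reads <- function(n_reads, length = 350L, base_quality = 38,
                           quality_sd = 2, dip_start = NULL,
                           dip_quality = 10, ambiguous_rate = 0,
                           seed = NULL) {
  if (length <= 0) value_error("read length must be positive")
  if (n_reads == 0)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- quals <- character(n_reads)
    for (i in seq_len(n_reads)) {
      s <- sample(bases, length, replace = TRUE)
      q <- round(stats::rnorm(length, base_quality, quality_sd))
      if (!is.null(dip_start) && dip_start <= length)
        q[dip_start:length] <- round(stats::rnorm(length - dip_start + 1,
                                                  dip_quality, quality_sd))
      q <- pmin(pmax(q, 2), 41)
      if (stats::runif(1) < ambiguous_rate)
        s[sample.int(length, 1)] <- "N"
      seqs[i] <- paste(s, collapse = "")
      quals[i] <- intToUtf8(q + 33L)
    }
    data.frame(id = paste0("read_", seq_len(n_reads)), seq = seqs,
               qual = quals, stringsAsFactors = FALSE)
  })
}
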