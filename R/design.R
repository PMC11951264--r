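#' Define a reciprocal litter-transplant experiment
#'
#' Describes the factorial layout of a reciprocal transplant microcosm
#' experiment: every litter species is decomposed in the soil of every
#' species, across a schedule of destructive harvests with a fixed number of
#' replicate microcosms per cell. The design is *reciprocal*: the litter
#' species set and soil source set must be identical, which is what makes
#' home/away contrasts (and hence a home-field advantage) well defined.
#'
#' A harvest is keyed jointly by `(month, treatment)`: a late harvest split
#' into control and glucose-amended batches counts as two sampling events,
#' which is how the reference design reaches five harvests from four harvest
#' months.
#'
#' @param litter_species character vector of species labels.
#' @param soil_sources character vector of species labels; must equal
#'   `litter_species` as a set.
#' @param harvests data.frame with columns `month` (integer months since the
#'   start of decomposition) and `treatment` (`"CK"` for control or
#'   `"glucose"`); one row per harvest event.
#' @param replicates number of replicate microcosms per factorial cell.
#' @param initial_litter_mass initial litter dry mass per microcosm (g).
#' @param soil_mass soil mass per microcosm (g).
#' @param glucose_month month at which glucose is added; `treatment ==
#'   "glucose"` harvests must not precede it.
#'
#' @return An object of class `"experiment_design"`.
#' @seealso [expand_design()], [default_design()]
#' @export
experiment_design <- function(litter_species, soil_sources,
                              harvests, replicates = 4L,
                              initial_litter_mass = 1.6, soil_mass = 100,
                              glucose_month = 4L) {
  litter_species <- as.character(litter_species)
  soil_sources <- as.character(soil_sources)
  if (length(litter_species) == 0L || length(soil_sources) == 0L)
    design_error("litter_species and soil_sources must be non-empty")
  if (anyDuplicated(litter_species) || anyDuplicated(soil_sources))
    design_error("duplicate species labels in design")
  if (!setequal(litter_species, soil_sources))
    design_error(sprintf(
      "design is not reciprocal: litter species {%s} != soil sources {%s}",
      paste(sort(litter_species), collapse = ", "),
      paste(sort(soil_sources), collapse = ", ")))
  harvests <- as.data.frame(harvests)
  if (!all(c("month", "treatment") %in% names(harvests)))
    design_error("harvests must have columns 'month' and 'treatment'")
  if (!all(harvests$treatment %in% c("CK", "glucose")))
    design_error("treatment must be 'CK' or 'glucose'")
  if (anyDuplicated(harvests[c("month", "treatment")]))
    design_error("duplicate (month, treatment) harvest events")
  if (any(harvests$month < 0))
    design_error("harvest months must be non-negative")
  if (any(harvests$treatment == "glucose" & harvests$month < glucose_month))
    design_error("glucose-treated harvests must not precede glucose_month")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    design_error("replicates must be a positive integer")
  if (initial_litter_mass <= 0 || soil_mass <= 0)
    design_error("initial_litter_mass and soil_mass must be positive")
  harvests <- harvests[order(harvests$month, harvests$treatment), , drop = FALSE]
  harvests$harvest_id <- paste0("m", harvests$month,
                                ifelse(harvests$treatment == "glucose", "G", ""))
  rownames(harvests) <- NULL
  structure(list(
    litter_species = sort(litter_species),
    soil_sources = sort(soil_sources),
    harvests = harvests[c("harvest_id", "month", "treatment")],
    replicates = replicates,
    initial_litter_mass = initial_litter_mass,
    soil_mass = soil_mass,
    glucose_month = as.integer(glucose_month)
  ), class = "experiment_design")
}

#' The reference two-species, two-phase design
#'
#' Two conifer litters (`"P"` and `"C"`) decomposed reciprocally in both
#' soils; harvests at 1, 2 and 4 months (phase I), and at 6 months in two
#' batches — control and glucose-amended (phase II) — for five harvest events;
#' four replicates; 1.6 g litter on 100 g soil. Expands to 80 microcosms.
#'
#' @return An `"experiment_design"` object.
#' @export
default_design <- function() {
  experiment_design(
    litter_species = c("P", "C"),
    soil_sources = c("P", "C"),
    harvests = data.frame(
      month = c(1L, 2L, 4L, 6L, 6L),
      treatment = c("CK", "CK", "CK", "CK", "glucose")),
    replicates = 4L,
    initial_litter_mass = 1.6,
    soil_mass = 100,
    glucose_month = 4L)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Reciprocal transplant design:",
      length(x$litter_species), "litter species x",
      length(x$soil_sources), "soil sources x",
      nrow(x$harvests), "harvests x", x$replicates, "replicates =",
      length(x$litter_species) * length(x$soil_sources) *
        nrow(x$harvests) * x$replicates, "microcosms\n")
  cat("Harvest events:", paste(x$harvests$harvest_id, collapse = ", "), "\n")
  invisible(x)
}

#' Expand a design into its microcosm units
#'
#' Enumerates every factorial cell (litter species x soil source x harvest
#' event x replicate) as one microcosm unit. `is_home` is derived as
#' `litter_species == soil_source`. Unit ids are synthesized as
#' `{litter}_{soil}_{harvest_id}_{replicate}` so the same design always
#' yields the same ids, giving deterministic joins across tables.
#'
#' @param design an [experiment_design()].
#' @return data.frame with one row per unit and columns `unit_id`,
#'   `litter_species`, `soil_source`, `harvest_id`, `month`, `treatment`,
#'   `replicate`, `is_home`, ordered by (litter, soil, harvest, replicate).
#' @examples
#' nrow(expand_design(default_design()))  # 80
#' @export
expand_design <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  h <- design$harvests
  grid <- expand.grid(
    replicate = seq_len(design$replicates),
    harvest_idx = seq_len(nrow(h)),
    soil_source = design$soil_sources,
    litter_species = design$litter_species,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("litter_species", "soil_source", "harvest_idx", "replicate")]
  units <- data.frame(
    litter_species = grid$litter_species,
    soil_source = grid$soil_source,
    harvest_id = h$harvest_id[grid$harvest_idx],
    month = h$month[grid$harvest_idx],
    treatment = h$treatment[grid$harvest_idx],
    replicate = grid$replicate,
    stringsAsFactors = FALSE)
  units$is_home <- units$litter_species == units$soil_source
  units$unit_id <- paste(units$litter_species, units$soil_source,
                         units$harvest_id, units$replicate, sep = "_")
  units <- units[order(units$litter_species, units$soil_source,
                       units$harvest_id, units$replicate), ]
  rownames(units) <- NULL
  units[c("unit_id", "litter_species", "soil_source", "harvest_id",
          "month", "treatment", "replicate", "is_home")]
}

#' Glucose dose bookkeeping
#'
#' A labile-carbon amendment is specified as a solution volume and a
#' mass-percent concentration; the delivered glucose mass is
#' `volume * concentration / 100` grams (mass percent is treated as g per
#' 100 mL). The reference dose, 8 mL of a 3.4% solution, delivers 0.272 g,
#' sized to emulate the root-exudate carbon flux of a root system
#' accompanying the litter.
#'
#' @param solution_volume solution volume (mL).
#' @param concentration glucose concentration (mass percent, 0-100].
#' @param root_mass_equiv root mass the dose emulates (g).
#' @param exudate_fraction fraction of root organic carbon exuded.
#' @return An object of class `"glucose_dose"`.
#' @export
glucose_dose <- function(solution_volume = 8, concentration = 3.4,
                         root_mass_equiv = 0.8, exudate_fraction = 0.3) {
  for (v in c(solution_volume, concentration, root_mass_equiv, exudate_fraction))
    if (!is.finite(v) || v <= 0)
      value_error("all glucose_dose fields must be positive")
  structure(list(solution_volume = solution_volume,
                 concentration = concentration,
                 root_mass_equiv = root_mass_equiv,
                 exudate_fraction = exudate_fraction),
            class = "glucose_dose")
}

#' Glucose mass delivered by a dose
#'
#' @param dose a [glucose_dose()].
#' @return delivered glucose mass (g).
#' @examples
#' glucose_mass(glucose_dose(8, 3.4))  # 0.272
#' @export
glucose_mass <- function(dose) {
  stopifnot(inherits(dose, "glucose_dose"))
  dose$solution_volume * dose$concentration / 100
}
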