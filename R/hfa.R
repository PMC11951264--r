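#' Litter mass loss
#'
#' Percent litter dry mass lost between deployment and harvest:
#' `(M_t0 - M_ti) / M_t0 * 100`.
#'
#' @param M_t0 initial dry mass (g), > 0.
#' @param M_ti remaining dry mass at harvest (g), in `[0, M_t0]`.
#' @return mass loss in percent (0-100). Vectorised.
#' @export
mass_loss <- function(M_t0, M_ti) {
  if (any(M_t0 <= 0)) value_error("M_t0 must be positive")
  if (any(M_ti < 0)) value_error("M_ti must be non-negative")
  if (any(M_ti > M_t0))
    mass_gain_error("remaining mass exceeds initial mass")
  (M_t0 - M_ti) / M_t0 * 100
}

#' Relative mass loss
#'
#' The share of a site's total decomposition attributable to one litter:
#' `own / (own + other) * 100`, where `own` and `other` are the percent mass
#' losses of the two litters decomposing at the same site. This is the
#' building block of the net home-field advantage index.
#'
#' @param own percent mass loss of the focal litter at the site.
#' @param other percent mass loss of the other litter at the same site.
#' @return relative mass loss in percent (0-100). Vectorised.
#' @export
relative_mass_loss <- function(own, other) {
  if (any(own < 0) || any(other < 0))
    value_error("mass losses must be non-negative")
  tot <- own + other
  if (any(tot == 0))
    undefined_ratio_error("relative mass loss undefined when both losses are 0")
  own / tot * 100
}

#' Net home-field advantage index for a species pair
#'
#' For a reciprocal pair of litters A and B with home sites a and b, the
#' index is the percent excess of the mean home-side relative mass loss over
#' the mean away-side relative mass loss:
#'
#'   `HFA = [ (A_RMLa + B_RMLb)/2  /  (A_RMLb + B_RMLa)/2 ] * 100 - 100`
#'
#' where `A_RMLa = A_a/(A_a+B_a)*100` etc. A positive value means litter
#' decomposes faster at its native site; the index is a single net value for
#' the pair. It is scale-invariant in the four mass losses and antisymmetric
#' under a home/away role swap: `(H + 100)(H' + 100) = 100^2`.
#'
#' @param A_a percent mass loss of litter A at its home site a.
#' @param B_a percent mass loss of litter B at site a (away).
#' @param A_b percent mass loss of litter A at site b (away).
#' @param B_b percent mass loss of litter B at its home site b.
#' @return the net HFA index in percent.
#' @examples
#' hfa_index(A_a = 40, B_a = 30, A_b = 20, B_b = 35)  # 52.459
#' @export
hfa_index <- function(A_a, B_a, A_b, B_b) {
  A_RMLa <- relative_mass_loss(A_a, B_a)
  B_RMLa <- relative_mass_loss(B_a, A_a)
  A_RMLb <- relative_mass_loss(A_b, B_b)
  B_RMLb <- relative_mass_loss(B_b, A_b)
  home <- (A_RMLa + B_RMLb) / 2
  away <- (A_RMLb + B_RMLa) / 2
  if (any(away == 0))
    undefined_ratio_error("HFA undefined: away-side mean relative mass loss is 0")
  home / away * 100 - 100
}

#' Per-species mean home-field advantage
#'
#' Percent increase in a species' mass loss at the home site relative to the
#' away site: `(ML_home - ML_away) / ML_away * 100`.
#'
#' @param ML_home percent mass loss at the home site.
#' @param ML_away percent mass loss at the away site, > 0.
#' @return mean HFA in percent. Vectorised.
#' @export
mean_hfa <- function(ML_home, ML_away) {
  if (any(ML_home < 0) || any(ML_away < 0))
    value_error("mass losses must be non-negative")
  if (any(ML_away == 0))
    undefined_ratio_error("mean HFA undefined when away mass loss is 0")
  (ML_home - ML_away) / ML_away * 100
}

# join mass records onto units and compute per-unit mass loss
unit_mass_loss <- function(mass_records, units) {
  mass_records <- validate_mass_records(mass_records)
  idx <- match(units$unit_id, mass_records$unit_id)
  if (anyNA(idx))
    incomplete_design_error(sprintf(
      "no mass record for unit(s): %s",
      paste(utils::head(units$unit_id[is.na(idx)], 5), collapse = ", ")))
  units$mass_loss <- mass_loss(mass_records$M_t0[idx], mass_records$M_ti[idx])
  units
}

#' Per-harvest HFA and mean-HFA tables
#'
#' Joins mass records onto the microcosm units of a reciprocal two-species
#' design and computes, per harvest event: the net HFA index per replicate
#' quartet and the per-species mean HFA per home/away replicate pair.
#'
#' Replicate pairing: under `"replicate_index"` (default), replicate k of
#' all four (litter, soil) cells forms quartet k, so a harvest with r
#' replicates yields r HFA values and 2r mean-HFA records — matching
#' per-harvest mean ± SE error bars with n = r. Under `"all_pairs"` every
#' combination of the two home-cell replicates with the two away-cell
#' replicates forms a quartet (a sensitivity option; r^2... quartets per
#' harvest formed from every 4-way replicate combination).
#'
#' @param mass_records data.frame from [load_mass_records()] or
#'   [simulate_mass_loss()].
#' @param units data.frame from [expand_design()] (exactly two species).
#' @param pairing `"replicate_index"` or `"all_pairs"`.
#' @return list with elements `hfa` (data.frame `harvest_id`, `month`,
#'   `treatment`, `replicate`, `hfa`), `mean_hfa` (data.frame `species`,
#'   `harvest_id`, `month`, `treatment`, `replicate`, `ml_home`, `ml_away`,
#'   `mean_hfa`) and `summary` (per-harvest mean ± SE of the HFA index).
#' @export
hfa_table <- function(mass_records, units,
                      pairing = c("replicate_index", "all_pairs")) {
  pairing <- match.arg(pairing)
  species <- sort(unique(units$litter_species))
  if (length(species) != 2L)
    design_error("hfa_table requires exactly two litter species")
  if (!setequal(species, unique(units$soil_source)))
    design_error("hfa_table requires a reciprocal design")
  units <- unit_mass_loss(mass_records, units)
  A <- species[1]; B <- species[2]
  cell <- function(h, litter, soil) {
    rows <- units[units$harvest_id == h & units$litter_species == litter &
                    units$soil_source == soil, ]
    if (nrow(rows) == 0L)
      incomplete_design_error(sprintf(
        "missing cell: litter %s in soil %s at harvest %s", litter, soil, h))
    rows[order(rows$replicate), ]
  }
  hfa_rows <- list(); mh_rows <- list()
  harvests <- unique(units[c("harvest_id", "month", "treatment")])
  harvests <- harvests[order(harvests$month, harvests$treatment), ]
  for (i in seq_len(nrow(harvests))) {
    h <- harvests$harvest_id[i]
    Aa <- cell(h, A, A); Ba <- cell(h, B, A)
    Ab <- cell(h, A, B); Bb <- cell(h, B, B)
    reps <- if (pairing == "replicate_index") {
      r <- Reduce(intersect, list(Aa$replicate, Ba$replicate,
                                  Ab$replicate, Bb$replicate))
      data.frame(ia = match(r, Aa$replicate), ib = match(r, Ba$replicate),
                 ja = match(r, Ab$replicate), jb = match(r, Bb$replicate),
                 label = as.character(r))
    } else {
      g <- expand.grid(ia = seq_len(nrow(Aa)), ib = seq_len(nrow(Ba)),
                       ja = seq_len(nrow(Ab)), jb = seq_len(nrow(Bb)))
      g$label <- paste(Aa$replicate[g$ia], Ba$replicate[g$ib],
                       Ab$replicate[g$ja], Bb$replicate[g$jb], sep = ".")
      g
    }
    hfa_rows[[h]] <- data.frame(
      harvest_id = h, month = harvests$month[i],
      treatment = harvests$treatment[i], replicate = reps$label,
      hfa = hfa_index(Aa$mass_loss[reps$ia], Ba$mass_loss[reps$ib],
                      Ab$mass_loss[reps$ja], Bb$mass_loss[reps$jb]),
      stringsAsFactors = FALSE)
    # mean HFA pairs each home replicate with the same-index away replicate
    r <- intersect(Aa$replicate, Ab$replicate)
    mhA <- data.frame(species = A, harvest_id = h, month = harvests$month[i],
                      treatment = harvests$treatment[i], replicate = r,
                      ml_home = Aa$mass_loss[match(r, Aa$replicate)],
                      ml_away = Ab$mass_loss[match(r, Ab$replicate)],
                      stringsAsFactors = FALSE)
    r <- intersect(Bb$replicate, Ba$replicate)
    mhB <- data.frame(species = B, harvest_id = h, month = harvests$month[i],
                      treatment = harvests$treatment[i], replicate = r,
                      ml_home = Bb$mass_loss[match(r, Bb$replicate)],
                      ml_away = Ba$mass_loss[match(r, Ba$replicate)],
                      stringsAsFactors = FALSE)
    mh_rows[[h]] <- rbind(mhA, mhB)
  }
  hfa <- do.call(rbind, hfa_rows); rownames(hfa) <- NULL
  mh <- do.call(rbind, mh_rows); rownames(mh) <- NULL
  mh$mean_hfa <- mean_hfa(mh$ml_home, mh$ml_away)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  summ <- do.call(rbind, lapply(split(hfa, hfa$harvest_id), function(d)
    data.frame(harvest_id = d$harvest_id[1], month = d$month[1],
               treatment = d$treatment[1], n = nrow(d),
               hfa_mean = mean(d$hfa), hfa_se = se(d$hfa),
               stringsAsFactors = FALSE)))
  summ <- summ[order(summ$month, summ$treatment), ]; rownames(summ) <- NULL
  list(hfa = hfa, mean_hfa = mh, summary = summ)
}
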