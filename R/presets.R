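#' Bundled regimen presets
#'
#' The four strategies of the bundled endometrial-cancer scenarios, with
#' 2024 USD costs per administration:
#'
#' * `"TC"` — carboplatin + paclitaxel, $1,126/cycle q3w for 6 cycles,
#'   no maintenance.
#' * `"PEM-TC"` — pembrolizumab 200 mg q3w + TC for 6 cycles
#'   ($13,464/cycle), then pembrolizumab 400 mg q6w maintenance
#'   ($24,676/administration) for a maximum total of 2 years.
#' * `"DOS-TC-3y"` — dostarlimab 500 mg q3w + TC for 6 cycles
#'   ($14,462/cycle), then dostarlimab 1000 mg q6w maintenance
#'   ($26,672/administration) for up to 3 years or 42 additional
#'   administrations. `"DOS-TC-2y"` is the 2-year variant.
#' * `"DUO-TC"` — durvalumab 1120 mg q3w + TC for 6 cycles
#'   ($10,146/cycle), then durvalumab 1500 mg q4w maintenance
#'   ($12,081/administration) until progression; `"DUO-TC-2y"` and
#'   `"DUO-TC-3y"` cap maintenance at 2 and 3 years.
#'
#' The chemotherapy backbone is $1,126 per induction cycle in every
#' regimen, so each immunotherapy's per-administration price is the
#' triplet cost minus the backbone: $12,338 (pembrolizumab), $13,336
#' (dostarlimab), $9,020 (durvalumab). Maintenance administrations are
#' priced as multiples of that price (2x for the doubled
#' pembrolizumab/dostarlimab maintenance dose; 12,081/9,020 ~ the
#' 1500/1120 dose ratio for durvalumab), which reproduces the quoted
#' maintenance costs exactly and keeps total drug cost linear in one
#' price per drug.
#'
#' Grade >= 3 toxicity probabilities are 0.71 / 0.63 / 0.54 / 0.53 for
#' DOS-TC / PEM-TC / DUO-TC / TC, costed at $9,784 per event for the
#' immunotherapy triplets and $9,163 for chemotherapy alone, with a
#' utility multiplier of 0.70 over an 18-week window.
#'
#' @param name preset name: `"TC"`, `"PEM-TC"`, `"DOS-TC-2y"`,
#'   `"DOS-TC-3y"`, `"DUO-TC"`, `"DUO-TC-2y"`, `"DUO-TC-3y"`.
#' @return a [regimen()].
#' @export
#' @examples
#' regimen_preset("PEM-TC")
regimen_preset <- function(name) {
  backbone <- 1126
  tox_immuno_cost <- 9784
  tox_tc_cost <- 9163
  tox_util <- 0.70
  q3w <- weeks(3); q4w <- weeks(4); q6w <- weeks(6)
  ind <- function(price_units)
    dose_phase(q3w, max_doses = 6, fixed_cost = backbone,
               price_units = price_units)
  switch(
    name,
    "TC" = regimen(
      "TC", induction = ind(0), maintenance = NULL,
      toxicity = toxicity_profile(0.53, tox_tc_cost, tox_util)),
    "PEM-TC" = regimen(
      "PEM-TC", induction = ind(1),
      maintenance = dose_phase(q6w, price_units = 2),
      toxicity = toxicity_profile(0.63, tox_immuno_cost, tox_util),
      drug_price = 12338, max_treatment_years = 2),
    "DOS-TC-2y" = regimen(
      "DOS-TC-2y", induction = ind(1),
      maintenance = dose_phase(q6w, max_doses = 42, price_units = 2),
      toxicity = toxicity_profile(0.71, tox_immuno_cost, tox_util),
      drug_price = 13336, max_treatment_years = 2),
    "DOS-TC-3y" = regimen(
      "DOS-TC-3y", induction = ind(1),
      maintenance = dose_phase(q6w, max_doses = 42, price_units = 2),
      toxicity = toxicity_profile(0.71, tox_immuno_cost, tox_util),
      drug_price = 13336, max_treatment_years = 3),
    "DUO-TC" = regimen(
      "DUO-TC", induction = ind(1),
      maintenance = dose_phase(q4w, price_units = 12081 / 9020),
      toxicity = toxicity_profile(0.54, tox_immuno_cost, tox_util),
      drug_price = 9020),
    "DUO-TC-2y" = regimen(
      "DUO-TC-2y", induction = ind(1),
      maintenance = dose_phase(q4w, price_units = 12081 / 9020),
      toxicity = toxicity_profile(0.54, tox_immuno_cost, tox_util),
      drug_price = 9020, max_treatment_years = 2),
    "DUO-TC-3y" = regimen(
      "DUO-TC-3y", induction = ind(1),
      maintenance = dose_phase(q4w, price_units = 12081 / 9020),
      toxicity = toxicity_profile(0.54, tox_immuno_cost, tox_util),
      drug_price = 9020, max_treatment_years = 3),
    stop("unknown regimen preset: ", name, call. = FALSE)
  )
}

#' Names of the bundled regimen presets
#' @return character vector of preset names.
#' @export
regimen_presets <- function() {
  c("TC", "PEM-TC", "DOS-TC-2y", "DOS-TC-3y", "DUO-TC", "DUO-TC-2y",
    "DUO-TC-3y")
}
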