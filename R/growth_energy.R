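#' Dilution rate from daily overflow volume
#'
#' In a turbidostat the culture density is constant, so the division rate
#' equals the dilution rate; the daily overflow volume divided by the
#' culture volume therefore estimates both.
#'
#' @param overflow_volume Daily overflow volume(s), L/day. Must be >= 0.
#' @param culture_volume Culture volume, L (> 0).
#' @return Dilution rate(s) in 1/day; also the division-rate estimate.
#' @export
#' @examples
#' estimate_dilution_rate(0.5, 1)  # 0.5 per day
estimate_dilution_rate <- function(overflow_volume, culture_volume) {
  check_number(overflow_volume, "overflow_volume", 0, allow_zero_len = TRUE)
  check_number(culture_volume, "culture_volume", 0, strict_lower = TRUE)
  overflow_volume / culture_volume
}

#' Daily dilution/division-rate series of a simulated run
#'
#' @param traj A [simulate_turbidostat()] trajectory.
#' @return data.frame with `day`, `overflow_L`, `dilution_rate` and
#'   `division_rate` (equal by the turbidostat identity).
#' @export
dilution_series <- function(traj) {
  stopifnot(inherits(traj, "turbidostat_trajectory"))
  ov <- traj$overflow
  d <- estimate_dilution_rate(ov$overflow_L, traj$config$culture_volume)
  data.frame(day = ov$day, overflow_L = ov$overflow_L,
             dilution_rate = d, division_rate = d)
}

# Combustion-energy equivalents, mJ per microgram (39,500 / 24,000 /
# 17,500 mJ per mg for lipids, proteins and carbohydrates).
COMBUSTION_MJ_PER_UG <- c(lipid = 39.5, protein = 24.0, carbohydrate = 17.5)

#' Stored biochemical energy from macromolecule quotas
#'
#' Converts neutral-lipid, soluble-protein and carbohydrate cell quotas
#' into combustion-energy equivalents and sums them into the total
#' available stored energy Ea. Quotas are in micrograms per 1e6 cells;
#' energies come out in mJ per 1e6 cells (combustion constants 39,500,
#' 24,000 and 17,500 mJ/mg, i.e. 39.5, 24.0 and 17.5 mJ per microgram).
#'
#' @param lipid_quota,protein_quota,carb_quota Quotas in micrograms per
#'   1e6 cells; vectors are recycled to a common length. `NA` values
#'   propagate into the corresponding energies.
#' @return data.frame with `e_lipid`, `e_protein`, `e_carb` and their sum
#'   `ea`, in mJ per 1e6 cells.
#' @export
#' @examples
#' stored_energy(0.5, 5.08, 3.8)$ea  # 208.17
stored_energy <- function(lipid_quota, protein_quota, carb_quota) {
  for (q in list(lipid_quota, protein_quota, carb_quota)) {
    if (!is.numeric(q)) stop_input("quotas must be numeric")
    if (any(q < 0, na.rm = TRUE)) stop_input("quotas must be >= 0")
  }
  n <- max(length(lipid_quota), length(protein_quota), length(carb_quota))
  e_l <- rep_len(lipid_quota, n) * COMBUSTION_MJ_PER_UG[["lipid"]]
  e_p <- rep_len(protein_quota, n) * COMBUSTION_MJ_PER_UG[["protein"]]
  e_c <- rep_len(carb_quota, n) * COMBUSTION_MJ_PER_UG[["carbohydrate"]]
  data.frame(e_lipid = e_l, e_protein = e_p, e_carb = e_c,
             ea = e_l + e_p + e_c)
}

#' Stored-energy time course from a trait table
#'
#' @param trait_table A data.frame with a `day` column and quota columns
#'   `neutral_lipid`, `protein` and `carbohydrate` (as produced by
#'   [generate_trait_table()] or read from file).
#' @return data.frame: `day` plus the [stored_energy()] breakdown per row.
#'   Missing quota values propagate as `NA`.
#' @export
energy_timecourse <- function(trait_table) {
  need <- c("neutral_lipid", "protein", "carbohydrate")
  missing_cols <- setdiff(need, names(trait_table))
  if (length(missing_cols)) {
    stop_input("trait table lacks quota column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  e <- stored_energy(trait_table$neutral_lipid, trait_table$protein,
                     trait_table$carbohydrate)
  cbind(day = trait_table$day, e)
}
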