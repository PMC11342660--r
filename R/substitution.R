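#' Displacement-factor parameters for substitution credits
#'
#' Displacement factors (DF) express avoided fossil emissions per unit of
#' carbon in wood: 1.5 tC avoided per tC of product for material
#' substitution and 0.67 tC per tC burned for fuel substitution. A fuel DF
#' below 1 means burning 1 tC of wood emits 1 tC while the displaced energy
#' source would have emitted 0.67 tC.
#'
#' @param df_material material displacement factor, tC/tC.
#' @param df_fuel fuel displacement factor, tC/tC.
#' @return list of class `substitution_params`.
#' @export
substitution_params <- function(df_material = 1.5, df_fuel = 0.67) {
  if (df_material < 0 || df_fuel < 0)
    stop("displacement factors must be nonnegative")
  structure(list(df_material = df_material, df_fuel = df_fuel),
            class = "substitution_params")
}

#' Decarbonization multiplier on the displacement factors
#'
#' As the substituted economy decarbonizes, displacement factors decline
#' exponentially: the multiplier is 1 up to 2020 and
#' `decarb_2050 ^ ((year - 2020) / 30)` afterwards, i.e. it reaches exactly
#' the pace's retained fraction in 2050 and continues to decay at the same
#' exponential rate beyond.
#'
#' @param year calendar year (vectorized).
#' @param decarb_2050 fraction of today's DF remaining in 2050, in (0, 1].
#' @return multiplier in (0, 1].
#' @export
#' @examples
#' decarb_multiplier(2050, 0.25)  # 0.25; 1.5 tC/tC becomes 0.375 tC/tC
decarb_multiplier <- function(year, decarb_2050) {
  if (decarb_2050 <= 0 || decarb_2050 > 1)
    stop("decarb_2050 must lie in (0, 1]")
  ifelse(year <= 2020, 1, decarb_2050^((year - 2020) / 30))
}

#' Material substitution credit for new products
#'
#' Avoided emissions booked in the creation year of products entering the
#' short-, medium- or long-lived pools:
#' `df_material * multiplier(year) * inflow`.
#'
#' @param inflow product-pool inflow carbon, kgC/m2 (sum over classes).
#' @param year booking year.
#' @param params a [substitution_params()] object.
#' @param decarb_2050 decarbonization pace.
#' @return avoided emissions, kgC/m2.
#' @export
material_credit <- function(inflow, year, params = substitution_params(),
                            decarb_2050 = 0.5) {
  if (any(inflow < 0)) stop("product inflow must be nonnegative")
  params$df_material * decarb_multiplier(year, decarb_2050) * inflow
}

#' Fuel substitution credit for burned wood
#'
#' Avoided emissions `df_fuel * multiplier(year) * burned` for firewood,
#' burned branches, the fuel-wood share of removed stems, and end-of-life
#' energy recovery of decayed products. The burned carbon itself is emitted
#' in full in the same year.
#'
#' @param burned carbon burned, kgC/m2.
#' @param year booking year.
#' @param params a [substitution_params()] object.
#' @param decarb_2050 decarbonization pace.
#' @return avoided emissions, kgC/m2.
#' @export
fuel_credit <- function(burned, year, params = substitution_params(),
                        decarb_2050 = 0.5) {
  if (any(burned < 0)) stop("burned carbon must be nonnegative")
  params$df_fuel * decarb_multiplier(year, decarb_2050) * burned
}
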