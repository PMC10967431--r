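#' Methane model parameters
#'
#' Arrhenius parameters for methanogenesis on stored volatile solids and
#' the enteric emission rate.  The slowly degradable VS fraction
#' contributes at 1% of the rate of the degradable fraction.
#'
#' @param VS_d_frac degradable share of excreted VS, kg/kg (default 0.83).
#' @param lnA log Arrhenius pre-factor, ln(g CH4 / kg VS / h)
#'   (default 31.3).
#' @param Ea apparent activation energy, kJ/mol (default 81.0).
#' @param R gas constant, kJ/mol/K (default 0.0083145).
#' @param enteric_rate enteric methane, kg CH4 per pig per year
#'   (default 1.5).
#' @return Object of class `methane_params`.
#' @export
methane_params <- function(VS_d_frac = 0.83, lnA = 31.3, Ea = 81.0,
                           R = 0.0083145, enteric_rate = 1.5) {
  stopifnot(VS_d_frac >= 0, VS_d_frac <= 1, Ea > 0, R > 0,
            enteric_rate >= 0)
  structure(list(VS_d_frac = VS_d_frac, lnA = lnA, Ea = Ea, R = R,
                 enteric_rate = enteric_rate),
            class = "methane_params")
}

#' Specific methane production rate
#'
#' Temperature response of methanogenesis on a unit of volatile solids:
#' \deqn{F_T = (VS_d + 0.01\,VS_{nd}) \exp(\ln A - E_a / (R T))}
#' in g CH4 per kg VS per hour, with \eqn{VS_{nd} = 1 - VS_d}.
#'
#' @param params a [methane_params()].
#' @param T_K temperature, K.
#' @return g CH4 / kg VS / h; vectorised over `T_K`.
#' @export
#' @examples
#' specific_ch4_rate(methane_params(), 293.15)  # about 0.12
specific_ch4_rate <- function(params, T_K) {
  stopifnot(inherits(params, "methane_params"), all(T_K > 0))
  weight <- params$VS_d_frac + 0.01 * (1 - params$VS_d_frac)
  weight * exp(params$lnA - params$Ea / (params$R * T_K))
}

#' Daily methane emission from a manure channel
#'
#' The daily pit emission is proportional to the stored volatile solids
#' (linear volume-emission assumption): the Arrhenius rate at the manure
#' temperature is applied to the degradable pool at full weight and to
#' the non-degradable pool at 1% weight, for 24 hours.  Optionally the
#' degradable pool is depleted by the carbon emitted as CH4 (12/16 of
#' the CH4 mass).
#'
#' @param state a [pit_state()].
#' @param params a [methane_params()].
#' @param manure_T_K manure temperature, K.
#' @param deplete_pool subtract emitted CH4 carbon from the degradable
#'   pool (default `TRUE`).
#' @return List with `ch4_kg` (kg CH4 for the day) and `state` (pool
#'   bookkeeping applied).
#' @export
pit_ch4_day <- function(state, params, manure_T_K, deplete_pool = TRUE) {
  stopifnot(inherits(state, "pit_state"),
            inherits(params, "methane_params"), manure_T_K > 0)
  arr <- exp(params$lnA - params$Ea / (params$R * manure_T_K))
  effective_VS <- state$VS_d + 0.01 * state$VS_nd
  ch4_g <- arr * effective_VS * 24   # g CH4 over one day
  ch4_kg <- ch4_g / 1000
  if (deplete_pool && ch4_kg > 0) {
    c_loss <- ch4_kg * 12 / 16
    VS_d_new <- max(0, state$VS_d - c_loss)
    state <- pit_state(state$geom, state$volume, VS_d_new, state$VS_nd,
                       state$TAN_mass)
  }
  list(ch4_kg = ch4_kg, state = state)
}

#' Daily enteric methane
#'
#' Hindgut fermentation, independent of manure storage.
#'
#' @param headcount number of pigs present.
#' @param params a [methane_params()].
#' @return kg CH4 per day for the room.
#' @export
enteric_ch4_day <- function(headcount, params = methane_params()) {
  stopifnot(headcount >= 0)
  headcount * params$enteric_rate / 365
}
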