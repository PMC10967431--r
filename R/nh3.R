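#' Mass-transfer coefficient for ammonia volatilization
#'
#' Convective mass transfer from a liquid surface into the room air,
#' scaled from a reference point by a boundary-layer power law in air
#' velocity and a linear temperature response:
#' \deqn{k = k_{ref} (v / v_{ref})^{0.8} (T / T_{ref})^{p}}
#'
#' @param v air velocity over the surface, m/s.
#' @param T_K surface temperature, K.
#' @param k_ref reference coefficient at `v_ref`, `T_ref` (default
#'   2.0e-3 m/s).
#' @param v_ref reference velocity, m/s (default 0.15).
#' @param T_ref reference temperature, K (default 293.15).
#' @param v_exp velocity exponent (default 0.8).
#' @param T_exp temperature exponent (default 1).
#' @return k in m/s.
#' @export
mass_transfer_coefficient <- function(v, T_K, k_ref = 2.0e-3,
                                      v_ref = 0.15, T_ref = 293.15,
                                      v_exp = 0.8, T_exp = 1) {
  stopifnot(all(v >= 0), all(T_K > 0))
  k_ref * (v / v_ref)^v_exp * (T_K / T_ref)^T_exp
}

#' Fraction of TAN present as unionized ammonia
#'
#' NH4+/NH3 dissociation equilibrium:
#' \deqn{f = 1 / (1 + 10^{pK_a(T) - pH})}
#' with the temperature-dependent dissociation constant
#' \eqn{pK_a(T) = 0.09018 + 2729.92 / T}.
#'
#' @param pH solution pH at the emitting surface.
#' @param T_K temperature, K.
#' @param pka_a,pka_b constants of the pKa relation.
#' @return Dimensionless fraction in (0, 1).
#' @export
fraction_unionized <- function(pH, T_K, pka_a = 0.09018, pka_b = 2729.92) {
  stopifnot(all(T_K > 0))
  pKa <- pka_a + pka_b / T_K
  1 / (1 + 10^(pKa - pH))
}

#' Dimensionless Henry constant for ammonia
#'
#' Liquid-to-gas concentration ratio at the interface:
#' \deqn{H = 1431 \cdot 1.053^{(293 - T)}}
#' decreasing with temperature (warmer surfaces partition more ammonia
#' into the gas phase).
#'
#' @param T_K temperature, K.
#' @param H_ref value at 293 K (default 1431).
#' @param H_base exponential base (default 1.053).
#' @return Dimensionless Henry constant (liquid/gas).
#' @export
henry_dimensionless <- function(T_K, H_ref = 1431, H_base = 1.053) {
  stopifnot(all(T_K > 0))
  H_ref * H_base^(293 - T_K)
}

#' Ammonia surface source
#'
#' One emitting surface (pit manure surface or floor urine puddles) with
#' the state variables entering the flux equation.
#'
#' @param area emitting area, m^2.
#' @param TAN_conc total ammoniacal N concentration, mol/m^3.
#' @param surface_pH pH at the emitting surface.
#' @param surface_T surface temperature, K.
#' @param air_velocity m/s.
#' @param kind one of `"pit"`, `"solid_floor"`, `"slatted_concrete"`,
#'   `"slatted_metal"`.
#' @return Object of class `surface_source`.
#' @export
surface_source <- function(area, TAN_conc, surface_pH, surface_T,
                           air_velocity = 0.15,
                           kind = c("pit", "solid_floor",
                                    "slatted_concrete", "slatted_metal")) {
  kind <- match.arg(kind)
  stopifnot(area >= 0, TAN_conc >= 0, surface_pH > 0, surface_pH < 14,
            surface_T > 0, air_velocity >= 0)
  structure(list(area = area, TAN_conc = TAN_conc, surface_pH = surface_pH,
                 surface_T = surface_T, air_velocity = air_velocity,
                 kind = kind),
            class = "surface_source")
}

#' Ammonia flux from one emitting surface
#'
#' \deqn{E = k \, A \, f \, [TAN] / H}
#' with the mass-transfer coefficient \eqn{k}, emitting area \eqn{A},
#' unionized fraction \eqn{f}, TAN concentration in mol/m^3 and the
#' dimensionless Henry constant \eqn{H}.
#'
#' @param source a [surface_source()].
#' @param k_ref reference mass-transfer coefficient, m/s (see
#'   [mass_transfer_coefficient()]).
#' @return Emission in mol NH3 per second.
#' @export
#' @examples
#' s <- surface_source(34.5, 300, 7.5, 292.7)
#' nh3_flux(s)
nh3_flux <- function(source, k_ref = 2.0e-3) {
  stopifnot(inherits(source, "surface_source"))
  k <- mass_transfer_coefficient(source$air_velocity, source$surface_T,
                                 k_ref = k_ref)
  f <- fraction_unionized(source$surface_pH, source$surface_T)
  H <- henry_dimensionless(source$surface_T)
  k * source$area * f * source$TAN_conc / H
}

#' Convert a molar NH3 flux to an annual per-pig-place emission
#'
#' @param flux_mol_s mol NH3/s for the whole room.
#' @param animal_places number of pig places.
#' @param vacancy vacancy factor between production cycles (default 0.03).
#' @param molar_mass kg per mol NH3 (default 0.017).
#' @return kg NH3 per year per pig place.
#' @export
annualize_nh3_flux <- function(flux_mol_s, animal_places, vacancy = 0.03,
                               molar_mass = 0.017) {
  stopifnot(animal_places > 0)
  flux_mol_s * molar_mass * 3.1536e7 / animal_places * (1 - vacancy)
}

#' Floor fouling configuration
#'
#' Shares of each floor element covered by urine puddles.  Fouled
#' concrete slats are assumed to emit like the fouled solid floor per m^2;
#' emission from soiled pigs and pen partitions is folded into the
#' solid-floor term.
#'
#' @param fouled_frac_solid fraction of the solid floor fouled
#'   (default 0.10).
#' @param fouled_frac_slatted_front fraction of the front concrete
#'   slatted floor fouled (default 0.05).
#' @param fouled_frac_slatted_back fraction of the back metal slatted
#'   floor fouled (default 0.05).
#' @return Object of class `floor_fouling`.
#' @export
floor_fouling <- function(fouled_frac_solid = 0.10,
                          fouled_frac_slatted_front = 0.05,
                          fouled_frac_slatted_back = 0.05) {
  fr <- c(fouled_frac_solid, fouled_frac_slatted_front,
          fouled_frac_slatted_back)
  if (any(fr < 0 | fr > 1)) stop("fouled fractions must lie in [0, 1]")
  structure(list(fouled_frac_solid = fouled_frac_solid,
                 fouled_frac_slatted_front = fouled_frac_slatted_front,
                 fouled_frac_slatted_back = fouled_frac_slatted_back),
            class = "floor_fouling")
}

#' Room-level ammonia emission for one day
#'
#' Builds the pit and floor surface sources from the current pit states,
#' floor areas and climate, evaluates [nh3_flux()] per source and returns
#' the itemized and total fluxes.  Surface pH is derived from the
#' measured bulk pH through a configurable linear map (default: identity
#' plus 0.5 pH units, the surface being CO2-depleted relative to the
#' bulk).
#'
#' @param pit_sources list of [surface_source()] objects for the manure
#'   channels (build with [surface_source()] at the current emitting area
#'   and TAN concentration).
#' @param floor_areas named list: `solid`, `slatted_front`,
#'   `slatted_back` areas in m^2.
#' @param fouling a [floor_fouling()].
#' @param puddle_TAN TAN concentration of floor urine puddles, mol/m^3.
#' @param puddle_pH surface pH of the puddles (already surface-mapped).
#' @param climate a [indoor_climate()] row.
#' @return List with `pit`, `floor`, `total` (mol/s) and `by_source`
#'   (named vector).
#' @export
room_nh3 <- function(pit_sources, floor_areas, fouling, puddle_TAN,
                     puddle_pH, climate) {
  stopifnot(inherits(fouling, "floor_fouling"))
  T_room <- climate$room_T + 273.15
  v <- climate$air_velocity_surface
  pit <- sum(vapply(pit_sources, nh3_flux, numeric(1)))
  mk <- function(area, frac) {
    if (area * frac <= 0 || puddle_TAN <= 0) return(0)
    nh3_flux(surface_source(area * frac, puddle_TAN, puddle_pH, T_room,
                            v, kind = "solid_floor"))
  }
  fl_solid <- mk(floor_areas$solid, fouling$fouled_frac_solid)
  fl_front <- mk(floor_areas$slatted_front, fouling$fouled_frac_slatted_front)
  fl_back  <- mk(floor_areas$slatted_back, fouling$fouled_frac_slatted_back)
  floor <- fl_solid + fl_front + fl_back
  list(pit = pit, floor = floor, total = pit + floor,
       by_source = c(pit = pit, floor_solid = fl_solid,
                     floor_slatted_front = fl_front,
                     floor_slatted_back = fl_back))
}

#' Surface pH from bulk pH
#'
#' Linear surface-pH map applied to the measured bulk slurry (or urine)
#' pH.  The default adds 0.5 pH units: the manure surface loses CO2 to
#' the air and is less acidic than the bulk.
#'
#' @param bulk_pH measured bulk pH.
#' @param offset additive offset (default 0.5).
#' @param slope multiplicative slope (default 1).
#' @return Surface pH.
#' @export
surface_pH <- function(bulk_pH, offset = 0.5, slope = 1) {
  slope * bulk_pH + offset
}
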