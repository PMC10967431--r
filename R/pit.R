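#' Manure-pit geometry
#'
#' A pit channel is modelled as a trapezoidal prism: a rectangular top
#' plan (`length` x `top_width`), vertical end walls, and 0, 1 or 2 long
#' walls sloping inward at `wall_slope_deg` from the horizontal
#' (90 degrees = straight).  The bottom width is
#' `top_width - n_sloped_walls * depth / tan(slope)` and must stay
#' positive.
#'
#' @param length channel length, m.
#' @param top_width channel width at the slat level, m.
#' @param depth channel depth, m.
#' @param wall_slope_deg wall slope from horizontal, degrees in (0, 90].
#' @param n_sloped_walls 0, 1 or 2 sloped long walls.
#' @return Object of class `pit_geometry` with the derived `bottom_width`
#'   and `capacity` (m^3).
#' @export
#' @examples
#' pit_geometry(11.28, 3.06, 1.20, 90, 0)       # deep pit, straight walls
#' pit_geometry(15.54, 1.18, 0.50, 45, 2)       # shallow sloped channel
pit_geometry <- function(length, top_width, depth, wall_slope_deg = 90,
                         n_sloped_walls = 0) {
  stopifnot(length > 0, top_width > 0, depth > 0,
            wall_slope_deg > 0, wall_slope_deg <= 90,
            n_sloped_walls %in% 0:2)
  inset <- if (wall_slope_deg == 90) 0 else depth / tan(wall_slope_deg * pi / 180)
  bottom_width <- top_width - n_sloped_walls * inset
  if (bottom_width <= 0) {
    stop("wall slope and depth leave no bottom width (",
         format(bottom_width), " m)")
  }
  g <- structure(list(length = length, top_width = top_width, depth = depth,
                      wall_slope_deg = wall_slope_deg,
                      n_sloped_walls = n_sloped_walls,
                      bottom_width = bottom_width),
                 class = "pit_geometry")
  g$capacity <- pit_volume(g, depth)
  g
}

#' Stored volume at a given manure height
#'
#' Forward trapezoidal-prism formula
#' \eqn{V(h) = L (w_b h + n h^2 / (2 \tan\theta))}.
#'
#' @param geom a [pit_geometry()].
#' @param height manure height, m, in `[0, depth]`; vectorised.
#' @return Volume, m^3.
#' @export
pit_volume <- function(geom, height) {
  stopifnot(all(height >= 0), all(height <= geom$depth + 1e-9))
  inv_tan <- if (geom$wall_slope_deg == 90) 0 else
    1 / tan(geom$wall_slope_deg * pi / 180)
  geom$length * (geom$bottom_width * height +
                 geom$n_sloped_walls * inv_tan * height^2 / 2)
}

#' Manure height from stored volume
#'
#' Inverts [pit_volume()].  Straight walls divide by the plan area; sloped
#' walls solve the quadratic
#' \eqn{(L n / (2\tan\theta)) h^2 + L w_b h - V = 0} for the positive
#' root.
#'
#' @param geom a [pit_geometry()].
#' @param volume m^3, in `[0, capacity]`.
#' @return Height, m.
#' @export
height_from_volume <- function(geom, volume) {
  stopifnot(volume >= 0)
  if (volume > geom$capacity * (1 + 1e-9)) {
    stop("pit overflow: volume ", format(volume), " m^3 exceeds capacity ",
         format(geom$capacity), " m^3")
  }
  volume <- min(volume, geom$capacity)
  if (geom$wall_slope_deg == 90 || geom$n_sloped_walls == 0) {
    return(volume / (geom$length * geom$top_width))
  }
  inv_tan <- 1 / tan(geom$wall_slope_deg * pi / 180)
  a <- geom$length * geom$n_sloped_walls * inv_tan / 2
  b <- geom$length * geom$bottom_width
  (-b + sqrt(b^2 + 4 * a * volume)) / (2 * a)
}

#' Emitting surface area at a given manure height
#'
#' Straight walls: the plan area, independent of height.  Sloped walls:
#' the liquid surface widens with the fill,
#' \eqn{A(h) = L (w_b + n h / \tan\theta)}.  An empty pit exposes the
#' wetted bottom by default (`empty_emits = TRUE`); set `FALSE` to treat
#' an empty pit as non-emitting.
#'
#' @param geom a [pit_geometry()].
#' @param height manure height, m.
#' @param empty_emits does an empty pit still expose a wetted bottom?
#' @return Area, m^2.
#' @export
emitting_area <- function(geom, height, empty_emits = TRUE) {
  stopifnot(height >= 0, height <= geom$depth + 1e-9)
  if (height == 0 && !empty_emits) return(0)
  if (geom$wall_slope_deg == 90 || geom$n_sloped_walls == 0) {
    return(geom$length * geom$top_width)
  }
  if (height == 0) return(geom$length * geom$bottom_width)
  inv_tan <- 1 / tan(geom$wall_slope_deg * pi / 180)
  geom$length * (geom$bottom_width + geom$n_sloped_walls * inv_tan * height)
}

#' Removal schedule
#'
#' @param interval_days days between removals (45 for long storage, 1 for
#'   daily flushing).
#' @param residual_height manure height left after a removal, m.
#' @param dilution_water L/d of water added to the channel (short-storage
#'   front water channel).
#' @param empty_on_overflow also empty when an inflow would exceed the
#'   channel capacity (default `TRUE`).
#' @return Object of class `removal_schedule`.
#' @export
removal_schedule <- function(interval_days, residual_height = 0,
                             dilution_water = 0, empty_on_overflow = TRUE) {
  stopifnot(interval_days >= 1, residual_height >= 0, dilution_water >= 0)
  structure(list(interval_days = as.integer(interval_days),
                 residual_height = residual_height,
                 dilution_water = dilution_water,
                 empty_on_overflow = empty_on_overflow),
            class = "removal_schedule")
}

#' Pit state
#'
#' The evolving contents of one channel: volume, degradable and
#' non-degradable volatile-solids pools, and total ammoniacal N mass.
#' Height and emitting area are derived from the geometry.
#'
#' @param geom a [pit_geometry()].
#' @param volume stored volume, m^3.
#' @param VS_d,VS_nd degradable / non-degradable volatile solids, kg.
#' @param TAN_mass total ammoniacal nitrogen, kg N.
#' @return Object of class `pit_state`.
#' @export
pit_state <- function(geom, volume = 0, VS_d = 0, VS_nd = 0, TAN_mass = 0) {
  stopifnot(volume >= 0, VS_d >= 0, VS_nd >= 0, TAN_mass >= 0)
  structure(list(geom = geom, volume = volume, VS_d = VS_d, VS_nd = VS_nd,
                 TAN_mass = TAN_mass,
                 height = height_from_volume(geom, volume)),
            class = "pit_state")
}

#' Add a day's slurry to a channel
#'
#' Well-mixed loading: volume, VS pools and TAN accumulate additively.
#' If the inflow would overflow the channel and the schedule allows it,
#' the channel is emptied to the residual height first (the overflow flag
#' is reported so the event can be logged).
#'
#' @param state a [pit_state()].
#' @param volume_m3 slurry volume added, m^3.
#' @param VS_d,VS_nd,TAN_mass added masses, kg.
#' @param sched optional [removal_schedule()] used for overflow handling.
#' @return List `state` (new [pit_state()]), `overflow` (logical),
#'   `removed` (removal record if an overflow emptying occurred).
#' @export
pit_add <- function(state, volume_m3, VS_d = 0, VS_nd = 0, TAN_mass = 0,
                    sched = NULL) {
  stopifnot(inherits(state, "pit_state"), volume_m3 >= 0)
  removed <- NULL
  overflow <- FALSE
  if (state$volume + volume_m3 > state$geom$capacity) {
    if (is.null(sched) || !sched$empty_on_overflow) {
      stop("pit overflow: inflow ", format(volume_m3),
           " m^3 exceeds remaining capacity")
    }
    r <- empty_pit(state, sched$residual_height)
    state <- r$state
    removed <- r$removed
    overflow <- TRUE
  }
  state <- pit_state(state$geom,
                     volume = state$volume + volume_m3,
                     VS_d = state$VS_d + VS_d,
                     VS_nd = state$VS_nd + VS_nd,
                     TAN_mass = state$TAN_mass + TAN_mass)
  list(state = state, overflow = overflow, removed = removed)
}

# Empty a channel down to residual_height; contents leave proportionally
# to the volume removed (well-mixed).
empty_pit <- function(state, residual_height) {
  v_res <- pit_volume(state$geom, min(residual_height, state$height))
  if (state$volume <= 0) {
    return(list(state = state,
                removed = list(volume = 0, VS_d = 0, VS_nd = 0,
                               TAN_mass = 0)))
  }
  frac_kept <- v_res / state$volume
  removed <- list(volume = state$volume - v_res,
                  VS_d = state$VS_d * (1 - frac_kept),
                  VS_nd = state$VS_nd * (1 - frac_kept),
                  TAN_mass = state$TAN_mass * (1 - frac_kept))
  new <- pit_state(state$geom, volume = v_res,
                   VS_d = state$VS_d * frac_kept,
                   VS_nd = state$VS_nd * frac_kept,
                   TAN_mass = state$TAN_mass * frac_kept)
  list(state = new, removed = removed)
}

#' Apply the removal schedule at the end of a day
#'
#' On removal days (`day` a multiple of the interval) the channel is
#' emptied to the residual height; volume, volatile solids and TAN leave
#' proportionally to the removed volume (well-mixed pit).  Off-days leave
#' the state unchanged.
#'
#' @param state a [pit_state()].
#' @param sched a [removal_schedule()].
#' @param day 1-based day index within the growing period.
#' @return List with `state` and `removed` (volume m^3, VS_d, VS_nd,
#'   TAN_mass kg; all zero on off-days).
#' @export
apply_removal <- function(state, sched, day) {
  stopifnot(inherits(state, "pit_state"),
            inherits(sched, "removal_schedule"), day >= 1)
  if (day %% sched$interval_days != 0) {
    return(list(state = state,
                removed = list(volume = 0, VS_d = 0, VS_nd = 0,
                               TAN_mass = 0)))
  }
  empty_pit(state, sched$residual_height)
}

#' Indoor climate for one day
#'
#' Mechanically ventilated fattening rooms are kept at or above a
#' temperature set point; above it the room tracks the outside
#' temperature with a constant ventilation offset.  Manure temperature
#' follows the room temperature through a linear map, and the air
#' velocity over emitting surfaces is taken as constant.
#'
#' @param outside_T outside temperature, degrees C.
#' @param outside_RH outside relative humidity, %.
#' @param T_set_min minimum room temperature, degrees C (default 20).
#' @param dT_vent room-minus-outside offset above the set point,
#'   degrees C (default 3).
#' @param manure_a,manure_b intercept and slope of the manure-temperature
#'   map `manure_T = a + b * room_T` (defaults 0, 0.88).
#' @param rh_factor room RH as a fraction of outside RH (default 0.85),
#'   clamped to `[30, 90]` %.
#' @param air_velocity air velocity over emitting surfaces, m/s
#'   (default 0.15).
#' @return A one-row data frame (class `climate_day`) with `outside_T`,
#'   `outside_RH`, `room_T`, `room_RH`, `manure_T`,
#'   `air_velocity_surface`.
#' @export
#' @examples
#' indoor_climate(25, 80)  # room 28 C
#' indoor_climate(5, 80)   # set-point floor, room 20 C
indoor_climate <- function(outside_T, outside_RH,
                           T_set_min = 20, dT_vent = 3,
                           manure_a = 0, manure_b = 0.88,
                           rh_factor = 0.85, air_velocity = 0.15) {
  stopifnot(is.finite(outside_T), is.finite(outside_RH))
  room_T <- max(T_set_min, outside_T + dT_vent)
  room_RH <- min(90, max(30, rh_factor * outside_RH))
  out <- data.frame(outside_T = outside_T, outside_RH = outside_RH,
                    room_T = room_T, room_RH = room_RH,
                    manure_T = manure_a + manure_b * room_T,
                    air_velocity_surface = air_velocity)
  class(out) <- c("climate_day", class(out))
  out
}
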