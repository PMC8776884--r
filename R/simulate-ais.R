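# Synthetic AIS tracks with gear-specific behaviour.

KNOT_KMH <- 1.852

# Default behavioural speeds (knots) by gear: the modal towing/setting speed
# and the steaming speed between port and the grounds. OTHER fishes at a
# speed outside every named gear band so that no classification rule fires.
GEAR_BEHAVIOUR <- list(
  OTB   = list(fishing = 3.2, steaming = 9.5),
  PTM   = list(fishing = 3.5, steaming = 9.5),
  TBB   = list(fishing = 5.5, steaming = 9.5),
  PS    = list(fishing = 0.3, steaming = 9.5),
  OTHER = list(fishing = 8.5, steaming = 11.5)
)

#' Specification of a synthetic vessel
#'
#' @param vessel_id Unique opaque identifier.
#' @param gear Gear label; drives the simulated speed regime.
#' @param home_port `c(lon, lat)` of the vessel's port.
#' @param fishing_speed_mode Modal fishing speed in knots (default: a
#'   gear-typical value).
#' @param steaming_speed Transit speed in knots; must exceed the fishing
#'   mode.
#' @param pair_partner For `PTM` only: the `vessel_id` of the paired vessel
#'   (pair trawlers tow one net between two hulls). Must be `NULL` for all
#'   other gears.
#' @return An object of class `"vessel_spec"`.
#' @export
vessel_spec <- function(vessel_id, gear, home_port,
                        fishing_speed_mode = NULL, steaming_speed = NULL,
                        pair_partner = NULL) {
  check_gear(gear)
  stopifnot(is.character(vessel_id), length(vessel_id) == 1L,
            length(home_port) == 2L)
  fishing_speed_mode <- fishing_speed_mode %||% GEAR_BEHAVIOUR[[gear]]$fishing
  steaming_speed <- steaming_speed %||% GEAR_BEHAVIOUR[[gear]]$steaming
  if (fishing_speed_mode >= steaming_speed) {
    stop("fishing_speed_mode must be below steaming_speed", call. = FALSE)
  }
  if (gear == "PTM" && is.null(pair_partner)) {
    stop("PTM vessels must name a pair_partner", call. = FALSE)
  }
  if (gear != "PTM" && !is.null(pair_partner)) {
    stop("only PTM vessels may have a pair_partner", call. = FALSE)
  }
  structure(list(vessel_id = vessel_id, gear = gear,
                 home_port = as.numeric(home_port),
                 fishing_speed_mode = fishing_speed_mode,
                 steaming_speed = steaming_speed,
                 pair_partner = pair_partner),
            class = "vessel_spec")
}

#' Build a mixed synthetic fleet
#'
#' Creates `n_vessels` vessel specifications covering all five gear classes
#' (pair trawlers in even numbers), with home ports placed along the western
#' edge of the bounding box.
#'
#' @param n_vessels Total number of vessels (>= 10 recommended so every
#'   gear is represented).
#' @param bbox `c(lon_min, lat_min, lon_max, lat_max)` of the working area.
#' @param seed RNG seed for port placement.
#' @return Named list of [vessel_spec()]; names are the vessel ids. The true
#'   gear of each vessel is attached as attribute `gears` (a named vector),
#'   serving as the licence-registry ground truth in simulation studies.
#' @export
synthetic_fleet <- function(n_vessels = 20L,
                            bbox = c(13, 42.5, 16, 45), seed = 1L) {
  n_vessels <- as.integer(n_vessels)
  stopifnot(n_vessels >= 5L)
  n_ptm_pairs <- max(1L, n_vessels %/% 7L)
  rest <- n_vessels - 2L * n_ptm_pairs
  base <- c("OTB", "TBB", "PS", "OTHER")
  gears <- rep(base, length.out = rest)
  with_seed(seed, {
    specs <- list()
    k <- 0L
    mk_port <- function() {
      c(bbox[1] + stats::runif(1, 0.05, 0.3) * (bbox[3] - bbox[1]),
        stats::runif(1, bbox[2] + 0.2, bbox[4] - 0.2))
    }
    for (g in gears) {
      k <- k + 1L
      id <- sprintf("V%03d", k)
      specs[[id]] <- vessel_spec(id, g, mk_port())
    }
    for (p in seq_len(n_ptm_pairs)) {
      ida <- sprintf("V%03d", k + 1L)
      idb <- sprintf("V%03d", k + 2L)
      port <- mk_port()
      specs[[ida]] <- vessel_spec(ida, "PTM", port, pair_partner = idb)
      specs[[idb]] <- vessel_spec(idb, "PTM", port, pair_partner = ida)
      k <- k + 2L
    }
    attr(specs, "gears") <- vapply(specs, function(s) s$gear, character(1))
    specs
  })
}

# Advance (lon, lat) by dist_km at bearing theta (radians, 0 = north).
advance_position <- function(lon, lat, dist_km, theta) {
  dlat <- dist_km * cos(theta) / 110.574
  dlon <- dist_km * sin(theta) / (111.320 * cos(lat * pi / 180))
  c(lon + dlon, lat + dlat)
}

# One simulated day for a vessel: a sequence of (speed, heading, phase)
# states at ping cadence. Phases: "port", "steam", "fish".
simulate_day_plan <- function(spec, dt_h) {
  n_of <- function(hours) max(1L, round(hours / dt_h))
  leg <- function(phase, hours, speed_fun, heading) {
    n <- n_of(hours)
    data.frame(phase = phase, sog = speed_fun(n),
               heading = rep(heading, n))
  }
  out_heading <- stats::runif(1, 0.25 * pi, 0.75 * pi)  # roughly eastward
  dwell_h <- min(10, max(0.5, stats::rexp(1, 1 / 1.0)))
  steam_h <- stats::runif(1, 0.75, 1.5)
  fish_total <- stats::runif(1, 6, 9)

  legs <- list(
    leg("port", dwell_h, function(n) stats::runif(n, 0, 0.15), 0)
  )
  legs <- c(legs, list(
    leg("steam", steam_h,
        function(n) pmax(0.5, stats::rnorm(n, spec$steaming_speed, 0.3)),
        out_heading)
  ))
  remaining <- fish_total
  heading <- out_heading
  while (remaining > 0) {
    h <- min(remaining, stats::runif(1, 2, 3.5))
    remaining <- remaining - h
    heading <- heading + stats::runif(1, -pi / 3, pi / 3)
    if (spec$gear == "PS") {
      # purse seining: drifting sets near zero speed with short repositioning
      # runs inside the band
      n <- max(1L, round(h / dt_h))
      cycle <- rep(c(rep(TRUE, 8), rep(FALSE, 4)), length.out = n)
      sog <- ifelse(cycle, stats::runif(n, 0.02, 0.3),
                    stats::runif(n, 0.6, 1.4))
      legs <- c(legs, list(data.frame(phase = "fish", sog = sog,
                                      heading = rep(heading, n))))
    } else {
      m <- spec$fishing_speed_mode
      legs <- c(legs, list(
        leg("fish", h,
            function(n) pmin(m + 0.7, pmax(m - 0.7,
                                           stats::rnorm(n, m, 0.3))),
            heading)
      ))
    }
  }
  legs <- c(legs, list(
    leg("steam", steam_h,
        function(n) pmax(0.5, stats::rnorm(n, spec$steaming_speed, 0.3)),
        out_heading + pi),
    leg("port", 0.4, function(n) stats::runif(n, 0, 0.15), 0)
  ))
  plan <- do.call(rbind, legs)
  # small heading jitter while fishing
  jit <- plan$phase == "fish"
  plan$heading[jit] <- plan$heading[jit] +
    stats::runif(sum(jit), -pi / 18, pi / 18)
  plan
}

#' Simulate AIS ping tables for a fleet
#'
#' Each vessel performs one trip per simulated day: a short port dwell,
#' a steaming leg, several fishing legs at gear-specific speeds, and a
#' return leg, reporting a position every `ping_interval_minutes`. Vessels
#' are silent between trips, so consecutive days separate into distinct
#' trips under the default 4-hour gap rule. Positions are integrated from
#' the reported speed and heading, so displacement-derived speed matches
#' the reported speed-over-ground. Pair trawlers (`PTM`) tow within 150 m
#' of their partner at identical times.
#'
#' @param vessels List of [vessel_spec()] (e.g. from [synthetic_fleet()]).
#' @param n_days Number of simulated days (>= 1).
#' @param ping_interval_minutes Reporting cadence; default 5 minutes.
#' @param seed Integer RNG seed; identical inputs and seed give an
#'   identical ping table.
#' @param start First day (UTC midnight), as `Date` or string.
#' @return A `data.frame` with columns `vessel_id`, `timestamp` (POSIXct
#'   UTC), `lat`, `lon`, `sog_knots`, `cog_degrees`, sorted by
#'   (vessel_id, timestamp).
#' @export
simulate_ais_tracks <- function(vessels, n_days, ping_interval_minutes = 5,
                                seed = 1L, start = "2020-03-01") {
  if (inherits(vessels, "vessel_spec")) vessels <- list(vessels)
  stopifnot(n_days >= 1L)
  if (ping_interval_minutes <= 0) {
    stop("ping_interval_minutes must be positive", call. = FALSE)
  }
  ids <- vapply(vessels, function(v) v$vessel_id, character(1))
  if (anyDuplicated(ids)) stop("vessel ids must be unique", call. = FALSE)
  names(vessels) <- ids
  for (v in vessels) {
    if (v$gear == "PTM" && !(v$pair_partner %in% ids)) {
      stop("pair partner ", v$pair_partner, " of ", v$vessel_id,
           " is absent from the vessel list", call. = FALSE)
    }
  }
  dt_h <- ping_interval_minutes / 60
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")

  with_seed(seed, {
    done <- character(0)
    tracks <- list()
    for (id in ids) {
      v <- vessels[[id]]
      if (id %in% done) next
      partner <- NULL
      if (v$gear == "PTM") partner <- vessels[[v$pair_partner]]
      days <- lapply(seq_len(n_days), function(d) {
        plan <- simulate_day_plan(v, dt_h)
        n <- nrow(plan)
        lon <- numeric(n); lat <- numeric(n)
        lon[1] <- v$home_port[1]; lat[1] <- v$home_port[2]
        for (i in seq_len(n - 1L)) {
          pos <- advance_position(lon[i], lat[i],
                                  plan$sog[i] * KNOT_KMH * dt_h,
                                  plan$heading[i])
          lon[i + 1L] <- pos[1]; lat[i + 1L] <- pos[2]
        }
        ts <- t0 + ((d - 1L) * 86400) + (seq_len(n) - 1L) * dt_h * 3600
        data.frame(timestamp = ts, lat = lat, lon = lon,
                   sog_knots = plan$sog,
                   cog_degrees = (plan$heading * 180 / pi) %% 360,
                   phase = plan$phase, stringsAsFactors = FALSE)
      })
      day_df <- do.call(rbind, days)
      tracks[[id]] <- cbind(vessel_id = id, day_df)
      done <- c(done, id)
      if (!is.null(partner)) {
        # partner mirrors the lead hull at a constant ~150 m offset, so the
        # two displacement series (and hence derived speeds) are identical
        off <- day_df
        for (i in seq_len(nrow(off))) {
          pos <- advance_position(off$lon[i], off$lat[i], 0.15, pi / 4)
          off$lon[i] <- pos[1]; off$lat[i] <- pos[2]
        }
        tracks[[partner$vessel_id]] <- cbind(vessel_id = partner$vessel_id,
                                             off)
        done <- c(done, partner$vessel_id)
      }
    }
    out <- do.call(rbind, tracks)
    out$phase <- NULL
    out <- out[order(out$vessel_id, out$timestamp), ]
    rownames(out) <- NULL
    out
  })
}

#' Write a ping table to CSV
#'
#' Timestamps are written as ISO-8601 UTC so the file round-trips through
#' [read_pings()].
#'
#' @param pings Ping table `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pings <- function(pings, path) {
  out <- pings
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
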