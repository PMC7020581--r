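## Seeded simulator of central-place-forager GPS tracks with ground-truth
## behaviour labels, patch identities and injected quality defects.
##
## The movement model is a mode-switching correlated random walk:
## directed outbound travel to a chosen offshore patch (fast, low
## turning), area-restricted search inside the patch (slow, high
## turning, confined to the patch radius by construction), directed
## return, and a haul-out at the colony between trips (GPS suspended, so
## haul-outs appear as gaps bracketed by two colony fixes). Foraging
## time per trip is scheduled as a fixed fraction of at-sea time.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the analysis is designed for:
#' 15-min fixes across a June to early-December window, repeated trips
#' from an island colony to shallow offshore banks within ~150 km, and
#' a fall shift of effort toward fewer, nearer patches.
#'
#' @param seed Master seed.
#' @param colony `c(lon, lat)` of the colony.
#' @param start,end Study window (dates, UTC).
#' @param fix_interval_min GPS fix interval, minutes (default 15).
#' @param patches Data frame with `id`, `lon`, `lat`, `radius_km`,
#'   `weight`, `summer`, `fall` (logical availability), `bank_depth_m`;
#'   `NULL` defers to the per-sex defaults built by
#'   [simulate_population()] or [default_patches()].
#' @param travel_speed_mean,travel_speed_sd Travel-mode speed, km/h.
#' @param forage_speed_mean,forage_speed_sd ARS-mode speed, km/h.
#' @param travel_turn_sd,forage_turn_sd Heading noise (degrees) per step
#'   in each mode.
#' @param travel_bias Goal attraction of the biased correlated travel
#'   walk, between 0 and 1: each step's heading is a mixture of the
#'   previous heading and the bearing to the goal (default 0.25; 1
#'   reduces to straight-line taxis).
#' @param forage_frac Target fraction of at-sea time spent foraging
#'   (default 0.6).
#' @param ars_attraction_frac Scale of the centre-attraction of the ARS
#'   walk during the ranging phase of a visit, as a fraction of the
#'   patch radius (default 0.5).
#' @param bout_cycle_h,hotspot_bout_h Bout structure of a visit: out of
#'   every `bout_cycle_h` hours (default 20) the animal station-keeps at
#'   the bank's best spot for `hotspot_bout_h` hours (default 6) and
#'   ranges over the wider bank in between.
#' @param hotspot_scale_frac Attraction scale during the hotspot bouts,
#'   as a fraction of the patch radius (default 0.1).
#' @param revisit_damping Multiplier on the weight of the bank exploited
#'   on the previous trip (default 0.1), a prey-renewal effect that
#'   makes the animal rotate among its preferred banks.
#' @param haulout_mean_h,haulout_sd_h Haul-out duration distribution
#'   (gamma, hours).
#' @param low_sat_frac,high_residual_frac,teleport_frac Defect rates for
#'   [inject_defects()] (defaults 0.012, 0.015, 0.05; together ~7.7\%).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       colony = c(-59.9158, 43.95),
                       start = "2014-06-01", end = "2014-12-04",
                       fix_interval_min = 15,
                       patches = NULL,
                       travel_speed_mean = 4, travel_speed_sd = 1,
                       forage_speed_mean = 0.6, forage_speed_sd = 0.4,
                       travel_turn_sd = 10, forage_turn_sd = 120,
                       travel_bias = 0.25,
                       forage_frac = 0.6,
                       ars_attraction_frac = 0.5,
                       bout_cycle_h = 20, hotspot_bout_h = 6,
                       hotspot_scale_frac = 0.1,
                       revisit_damping = 0.1,
                       haulout_mean_h = 12, haulout_sd_h = 6,
                       low_sat_frac = 0.012, high_residual_frac = 0.015,
                       teleport_frac = 0.05) {
  stopifnot(fix_interval_min > 0, travel_speed_mean > 0,
            forage_speed_mean > 0, forage_frac > 0, forage_frac < 1,
            low_sat_frac >= 0, low_sat_frac <= 1,
            high_residual_frac >= 0, high_residual_frac <= 1,
            teleport_frac >= 0, teleport_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Default offshore patch set
#'
#' Patches (shallow banks) at the given distances from the colony along
#' spread bearings; the nearest `n_fall` stay available in fall,
#' emulating the seasonal contraction of effort.
#'
#' @param colony `c(lon, lat)`.
#' @param dist_km Patch distances from the colony, km.
#' @param radius_km Patch radii (recycled).
#' @param n_fall How many of the nearest patches remain in fall.
#' @param bearings_deg Bearings from the colony (defaults spread evenly).
#' @return Patch data frame for [sim_config()].
#' @export
default_patches <- function(colony, dist_km, radius_km = 8, n_fall = 2,
                            bearings_deg = NULL) {
  np <- length(dist_km)
  if (np == 0) {
    return(data.frame(id = integer(0), lon = numeric(0), lat = numeric(0),
                      radius_km = numeric(0), weight = numeric(0),
                      summer = logical(0), fall = logical(0),
                      bank_depth_m = numeric(0)))
  }
  if (is.null(bearings_deg)) bearings_deg <- seq(30, 150, length.out = np)
  radius_km <- rep_len(radius_km, np)
  b <- bearings_deg * pi / 180
  x <- dist_km * 1000 * sin(b)
  y <- dist_km * 1000 * cos(b)
  ll <- aeqd_inverse(x, y, colony)
  near <- rank(dist_km, ties.method = "first") <= n_fall
  data.frame(id = seq_len(np), lon = ll$lon, lat = ll$lat,
             radius_km = radius_km, weight = 1,
             summer = TRUE, fall = near,
             bank_depth_m = seq(50, 75, length.out = np))
}

#' Simulate one animal's track
#'
#' @param config A [sim_config()] (its `patches` must be set, e.g. via
#'   [default_patches()]).
#' @param animal_id Animal identifier.
#' @param sex `"male"` or `"female"`.
#' @param seed Seed for this track (default the config master seed).
#' @param patch_pref Optional per-animal patch preference weights
#'   (multiplied into the patch weights).
#' @return A `forager_track` whose fixes carry ground-truth columns
#'   `mode` (`travel`/`forage`/`haulout`), `patch` (id or `NA`) and
#'   `defect` (`"none"` until [inject_defects()]).
#' @export
simulate_track <- function(config, animal_id = "sim1", sex = "female",
                           seed = config$seed, patch_pref = NULL) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$patches)) cfg$patches <- default_patches(
    cfg$colony, dist_km = c(40, 70, 110), radius_km = 8)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  t0 <- as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC")
  t_end <- as.POSIXct(paste(cfg$end, "23:59:59"), tz = "UTC")
  if (as.numeric(t_end - t0, units = "mins") < cfg$fix_interval_min) {
    stop("study window shorter than one fix interval", call. = FALSE)
  }
  dt_h <- cfg$fix_interval_min / 60
  pat <- cfg$patches
  pxy <- aeqd_forward(pat$lon, pat$lat, cfg$colony)
  pref <- if (is.null(patch_pref)) rep(1, nrow(pat)) else patch_pref
  ## mean forage dwell per trip: set so the expected at-sea time split
  ## matches forage_frac given the animal's mean round-trip commute
  usable0 <- which(pat$weight * pref > 0)
  dwell_mean_h <- if (length(usable0)) {
    d_mean <- mean(sqrt(pxy$x[usable0]^2 + pxy$y[usable0]^2)) / 1000
    (2 * d_mean / cfg$travel_speed_mean) *
      cfg$forage_frac / (1 - cfg$forage_frac)
  } else 0

  ## grow fix records in chunks
  recs <- list()
  emit <- function(t, x, y, mode, patch) {
    recs[[length(recs) + 1]] <<- c(as.numeric(t), x, y, mode, patch)
  }
  MODE <- c(travel = 1, forage = 2, haulout = 3)
  t <- t0
  last_pid <- NA_integer_
  repeat {
    ## haul-out: GPS dry, two bracketing colony fixes
    dur_h <- stats::rgamma(1, shape = (cfg$haulout_mean_h / cfg$haulout_sd_h)^2,
                           rate = cfg$haulout_mean_h / cfg$haulout_sd_h^2)
    dur_h <- max(dur_h, 1)
    emit(t, 0, 0, MODE["haulout"], NA)
    t_dep <- t + dur_h * 3600
    if (t_dep > t_end) break
    emit(t_dep, 0, 0, MODE["haulout"], NA)
    t <- t_dep + dt_h * 3600
    ## choose a patch available this season
    sea <- as.character(assign_season(t))
    usable <- which(pat$weight * pref > 0)
    avail <- intersect(usable,
                       if (sea == "fall") which(pat$fall) else
                         which(pat$summer))
    if (length(avail) == 0) avail <- usable
    pid <- if (length(avail) == 0) NA_integer_ else {
      ## prey renewal: the bank just exploited is down-weighted, so the
      ## animal rotates among its preferred banks rather than streaking
      w_choice <- pat$weight[avail] * pref[avail]
      if (!is.na(last_pid) && last_pid %in% avail && length(avail) > 1) {
        w_choice[avail == last_pid] <- w_choice[avail == last_pid] *
          cfg$revisit_damping
      }
      avail[sample.int(length(avail), 1, prob = w_choice)]
    }
    last_pid <- pid
    ## outbound travel
    x <- 0; y <- 0
    target <- if (is.na(pid)) {
      ## no patches: out-and-back excursion to a random offshore point
      ang <- stats::runif(1, 0, 2 * pi)
      c(50e3 * sin(ang), 50e3 * cos(ang))
    } else c(pxy$x[pid], pxy$y[pid])
    r_m <- if (is.na(pid)) 2000 else pat$radius_km[pid] * 1000
    out_steps <- 0L
    head <- atan2(target[1] - x, target[2] - y)
    repeat {
      if (t > t_end) break
      d2t <- sqrt((target[1] - x)^2 + (target[2] - y)^2)
      if (d2t <= r_m * 0.5) break
      ## biased correlated walk: persistent heading drawn toward the
      ## goal, so successive trips take distinct meandering routes
      bc <- atan2(target[1] - x, target[2] - y)
      b <- cfg$travel_bias
      head <- atan2((1 - b) * sin(head) + b * sin(bc),
                    (1 - b) * cos(head) + b * cos(bc)) +
        stats::rnorm(1, 0, cfg$travel_turn_sd * pi / 180)
      sp <- stats::rgamma(1, shape = (cfg$travel_speed_mean /
                                        cfg$travel_speed_sd)^2,
                          rate = cfg$travel_speed_mean /
                            cfg$travel_speed_sd^2)
      step <- min(sp * 1000 * dt_h, d2t)
      x <- x + step * sin(head); y <- y + step * cos(head)
      emit(t, x, y, MODE["travel"], NA)
      t <- t + dt_h * 3600
      out_steps <- out_steps + 1L
    }
    if (t > t_end) break
    ## area-restricted search inside the patch
    if (!is.na(pid)) {
      forage_h <- max(stats::rgamma(1, shape = 25,
                                    rate = 25 / dwell_mean_h), 2)
      n_forage <- round(forage_h / dt_h)
      head <- stats::runif(1, 0, 2 * pi)
      for (i in seq_len(n_forage)) {
        if (t > t_end) break
        head <- head + stats::rnorm(1, 0, cfg$forage_turn_sd * pi / 180)
        ## centre-attracted ARS: prey density peaks at the patch centre,
        ## so the walk mean-reverts toward it with strength growing as
        ## the animal strays outward. Within a visit the animal works
        ## the bank's best spot in diel bouts (station-keeping at the
        ## hotspot for hotspot_bout_h out of every bout_cycle_h) and
        ## ranges over the wider bank in between.
        scale_frac <- if ((i * dt_h) %% cfg$bout_cycle_h <
                            cfg$hotspot_bout_h) {
          cfg$hotspot_scale_frac
        } else {
          cfg$ars_attraction_frac
        }
        pull <- min(1, ((sqrt((x - target[1])^2 + (y - target[2])^2)) /
                          (scale_frac * r_m))^2)
        bc <- atan2(target[1] - x, target[2] - y)
        head <- atan2((1 - pull) * sin(head) + pull * sin(bc),
                      (1 - pull) * cos(head) + pull * cos(bc))
        sp <- stats::rgamma(1, shape = (cfg$forage_speed_mean /
                                          cfg$forage_speed_sd)^2,
                            rate = cfg$forage_speed_mean /
                              cfg$forage_speed_sd^2)
        x2 <- x + sp * 1000 * dt_h * sin(head)
        y2 <- y + sp * 1000 * dt_h * cos(head)
        dd <- sqrt((x2 - target[1])^2 + (y2 - target[2])^2)
        if (dd > r_m) { # reflect back inside the patch
          x2 <- target[1] + (x2 - target[1]) * r_m / dd
          y2 <- target[2] + (y2 - target[2]) * r_m / dd
          head <- atan2(target[1] - x2, target[2] - y2) +
            stats::runif(1, -pi / 4, pi / 4)
        }
        x <- x2; y <- y2
        emit(t, x, y, MODE["forage"], pid)
        t <- t + dt_h * 3600
      }
    }
    if (t > t_end) break
    ## inbound travel
    head <- atan2(-x, -y)
    repeat {
      if (t > t_end) break
      d2c <- sqrt(x^2 + y^2)
      if (d2c <= 1500) break
      bc <- atan2(-x, -y)
      b <- cfg$travel_bias
      head <- atan2((1 - b) * sin(head) + b * sin(bc),
                    (1 - b) * cos(head) + b * cos(bc)) +
        stats::rnorm(1, 0, cfg$travel_turn_sd * pi / 180)
      sp <- stats::rgamma(1, shape = (cfg$travel_speed_mean /
                                        cfg$travel_speed_sd)^2,
                          rate = cfg$travel_speed_mean /
                            cfg$travel_speed_sd^2)
      step <- min(sp * 1000 * dt_h, d2c)
      x <- x + step * sin(head); y <- y + step * cos(head)
      emit(t, x, y, MODE["travel"], NA)
      t <- t + dt_h * 3600
    }
    x <- 0; y <- 0
    if (t > t_end) break
  }
  m <- do.call(rbind, recs)
  ll <- aeqd_inverse(m[, 2], m[, 3], cfg$colony)
  fixes <- data.frame(
    timestamp = as.POSIXct(m[, 1], origin = "1970-01-01", tz = "UTC"),
    lon = ll$lon, lat = ll$lat,
    n_sats = sample(7:11, nrow(m), replace = TRUE),
    residual = round(stats::runif(nrow(m), 0, 20), 2),
    mode = c("travel", "forage", "haulout")[m[, 4]],
    patch = m[, 5],
    defect = "none")
  trk <- track(fixes, animal_id = animal_id, sex = sex)
  trk$colony <- cfg$colony
  trk$patches <- pat
  trk
}

#' Inject GPS quality defects into a simulated track
#'
#' Randomly selected fixes (disjoint sets, never the first fix) receive
#' a low satellite count, a high residual error, or a teleport (an
#' 8-20 km positional displacement implying an impossible speed at
#' 15-min sampling). Ground truth is recorded in the `defect` column.
#'
#' @param trk A simulated `forager_track`.
#' @param config The [sim_config()] holding the defect rates.
#' @param seed Seed (default config master seed + 1).
#' @return The track with defects applied and flagged.
#' @export
inject_defects <- function(trk, config, seed = config$seed + 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  f <- trk$fixes
  n <- nrow(f)
  if (n < 3) return(trk)
  pool <- 2:n
  n_tp <- round(config$teleport_frac * n)
  n_ls <- round(config$low_sat_frac * n)
  n_hr <- round(config$high_residual_frac * n)
  pick <- sample(pool, min(n_tp + n_ls + n_hr, length(pool)))
  tp <- pick[seq_len(min(n_tp, length(pick)))]
  rest <- setdiff(pick, tp)
  ls <- rest[seq_len(min(n_ls, length(rest)))]
  hr <- setdiff(rest, ls)
  if (length(ls)) {
    f$n_sats[ls] <- sample(3:4, length(ls), replace = TRUE)
    f$defect[ls] <- "low_sat"
  }
  if (length(hr)) {
    f$residual[hr] <- round(stats::runif(length(hr), 31, 100), 2)
    f$defect[hr] <- "high_residual"
  }
  if (length(tp)) {
    colony <- if (!is.null(trk$colony)) trk$colony else c(mean(f$lon),
                                                          mean(f$lat))
    xy <- aeqd_forward(f$lon[tp], f$lat[tp], colony)
    ang <- stats::runif(length(tp), 0, 2 * pi)
    dist <- stats::runif(length(tp), 8000, 20000)
    ll <- aeqd_inverse(xy$x + dist * sin(ang), xy$y + dist * cos(ang),
                       colony)
    f$lon[tp] <- ll$lon
    f$lat[tp] <- ll$lat
    f$defect[tp] <- "teleport"
  }
  trk$fixes <- f
  trk
}

#' Simulate a population of tracks
#'
#' Males draw their patches from a farther, larger bank pool (within
#' ~150 km) and females from a nearer one; in fall both sexes contract
#' onto the nearest available patches. Each animal specialises on
#' `patches_per_animal` equally-preferred banks from its sex's pool
#' (individual site fidelity), revisiting them in balanced rotation.
#' Per-animal seeds and patch preferences derive from the master seed,
#' so the population is reproducible. Deployment masses and recapture
#' masses (via sex-specific relative gain rates) are drawn for the
#' mass-gain analyses.
#'
#' @param config A [sim_config()]; its `patches` field is ignored in
#'   favour of the per-sex defaults unless `use_config_patches = TRUE`.
#' @param n_males,n_females Animal counts.
#' @param defects Apply [inject_defects()] to each track (default FALSE).
#' @param use_config_patches Use `config$patches` for both sexes.
#' @param patches_per_animal Banks each animal specialises on
#'   (default 2).
#' @return List with `tracks` (list of `forager_track`) and `metadata`
#'   (data frame: `animal_id`, `sex`, dates, masses, `pregnant`,
#'   `postpartum_day`).
#' @export
simulate_population <- function(config, n_males = 2, n_females = 4,
                                defects = FALSE,
                                use_config_patches = FALSE,
                                patches_per_animal = 2) {
  stopifnot(n_males + n_females >= 1)
  male_pat <- default_patches(config$colony,
                              dist_km = c(60, 95, 130, 150),
                              radius_km = c(10, 10, 12, 12), n_fall = 2)
  female_pat <- default_patches(config$colony,
                                dist_km = c(30, 55, 80),
                                radius_km = c(7, 8, 8), n_fall = 2,
                                bearings_deg = c(60, 100, 140))
  sexes <- c(rep("male", n_males), rep("female", n_females))
  tracks <- list()
  meta <- list()
  days <- as.numeric(as.Date(config$end) - as.Date(config$start))
  for (i in seq_along(sexes)) {
    seed_i <- (config$seed + 1000L * i) %% .Machine$integer.max
    cfg_i <- config
    if (!use_config_patches || is.null(config$patches)) {
      cfg_i$patches <- if (sexes[i] == "male") male_pat else female_pat
    }
    set.seed(seed_i)
    np <- nrow(cfg_i$patches)
    mine <- sample.int(np, min(patches_per_animal, np))
    pref <- as.numeric(seq_len(np) %in% mine)
    id <- sprintf("%s%02d", ifelse(sexes[i] == "male", "M", "F"), i)
    trk <- simulate_track(cfg_i, animal_id = id, sex = sexes[i],
                          seed = seed_i + 1, patch_pref = pref)
    if (defects) trk <- inject_defects(trk, cfg_i, seed = seed_i + 2)
    tracks[[id]] <- trk
    set.seed(seed_i + 3)
    m0 <- if (sexes[i] == "male") stats::rnorm(1, 209, 36.6) else
      stats::rnorm(1, 164, 24.9)
    rate <- if (sexes[i] == "male") stats::rnorm(1, 0.30, 0.10) else
      stats::rnorm(1, 0.22, 0.10)
    pregnant <- sexes[i] == "female" && stats::runif(1) < 0.5
    meta[[i]] <- data.frame(
      animal_id = id, sex = sexes[i],
      deploy_date = config$start, recapture_date = config$end,
      deploy_mass_kg = round(m0, 1),
      recapture_mass_kg = round(m0 * (1 + rate / 100 * days), 1),
      pregnant = pregnant,
      postpartum_day = ifelse(pregnant, sample(3:6, 1), NA))
  }
  list(tracks = tracks, metadata = do.call(rbind, meta))
}

#' Synthetic bathymetry around the colony
#'
#' Depth increases smoothly with distance from the colony and is pulled
#' toward the configured bank depth (50-75 m) near each patch centre,
#' so patches sit on shallow offshore banks.
#'
#' @param config A [sim_config()] with patches set.
#' @param cellsize Grid node spacing, degrees (default 1/60, one
#'   minute).
#' @param margin_deg Extent margin beyond the patch bounding box.
#' @return A [bathymetry_grid()].
#' @export
simulate_bathymetry <- function(config, cellsize = 1 / 60,
                                margin_deg = 0.5) {
  pat <- config$patches
  if (is.null(pat)) pat <- default_patches(config$colony,
                                           dist_km = c(40, 70, 110))
  lons <- c(config$colony[1], pat$lon)
  lats <- c(config$colony[2], pat$lat)
  lon0 <- min(lons) - margin_deg; lon1 <- max(lons) + margin_deg
  lat0 <- min(lats) - margin_deg; lat1 <- max(lats) + margin_deg
  glon <- seq(lon0, lon1, by = cellsize)
  glat <- seq(lat0, lat1, by = cellsize)
  xy <- expand.grid(lon = glon, lat = glat)
  d_col <- distance_to_colony(xy$lon, xy$lat, config$colony)
  depth <- pmin(30 + 1.1 * d_col, 250)
  for (j in seq_len(nrow(pat))) {
    d_p <- distance_to_colony(xy$lon, xy$lat, c(pat$lon[j], pat$lat[j]))
    wgt <- exp(-(d_p / pat$radius_km[j])^2)
    depth <- depth * (1 - wgt) + pat$bank_depth_m[j] * wgt
  }
  m <- matrix(depth, nrow = length(glat), ncol = length(glon),
              byrow = TRUE)
  bathymetry_grid(lon0 = glon[1], lat0 = glat[1], cellsize = cellsize,
                  depth = m)
}

#' Write a simulated population in the fix/metadata/truth CSV dialects
#'
#' @param pop Output of [simulate_population()].
#' @param dir Output directory (created if needed).
#' @param bathy Optional [bathymetry_grid()] to write as `bathy.asc`.
#' @return Named vector of paths, invisibly.
#' @export
write_sim <- function(pop, dir, bathy = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fix_rows <- lapply(pop$tracks, function(trk) {
    f <- trk$fixes
    data.frame(animal_id = trk$animal_id,
               timestamp_iso8601_utc = format(f$timestamp,
                                              "%Y-%m-%dT%H:%M:%S"),
               lon = f$lon, lat = f$lat, n_sats = f$n_sats,
               residual = f$residual)
  })
  truth_rows <- lapply(pop$tracks, function(trk) {
    f <- trk$fixes
    data.frame(animal_id = trk$animal_id,
               timestamp_iso8601_utc = format(f$timestamp,
                                              "%Y-%m-%dT%H:%M:%S"),
               mode = f$mode, patch = f$patch, defect = f$defect)
  })
  paths <- c(fixes = file.path(dir, "fixes.csv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(do.call(rbind, fix_rows), paths["fixes"],
                   row.names = FALSE)
  utils::write.csv(pop$metadata, paths["metadata"], row.names = FALSE)
  utils::write.csv(do.call(rbind, truth_rows), paths["truth"],
                   row.names = FALSE)
  if (!is.null(bathy)) {
    paths <- c(paths, bathy = file.path(dir, "bathy.asc"))
    write_ascii_grid(bathy, paths["bathy"])
  }
  invisible(paths)
}
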