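## Time-scaled distance, neighbour selection, hull construction and
## isopleth (home range / core area) building.
##
## The time-scaled distance (TSD) between two fixes adds the time
## separation, scaled by s * v_max, as a third Euclidean axis:
##   TSD = sqrt(dx^2 + dy^2 + (s * v_max * dt)^2),  dt in hours.
## With s = 0 it reduces to planar distance; as s grows, temporally
## distant fixes stop being neighbours even when spatially close, which
## separates repeated visits to the same patch into distinct hulls.

#' T-LoCoH analysis configuration
#'
#' @param s Time-scaling parameter (unitless, >= 0).
#' @param v_max Maximum theoretical velocity in m/h; `NULL` derives it
#'   from the track as the 99.9th percentile of observed speeds, capped at
#'   10 km/h (the filter bound).
#' @param method Neighbour selection: `"a"` (adaptive cumulative-distance,
#'   default, recommended for speed-heterogeneous tracks) or `"k"`
#'   (fixed count).
#' @param k Neighbour count for the k-method (and the starting point for
#'   deriving `a`); default 15.
#' @param a Cumulative TSD limit in metres for the a-method; `NULL`
#'   derives `a_k` from `k` via [a_for_k()].
#' @param ivg_h Inter-visit gap in hours separating return visits
#'   (default 12).
#' @param levels Isopleth levels (fractions in (0, 1]).
#' @param min_fixes Minimum fixes per season for seasonal isopleths
#'   (default 100).
#' @return List of class `tlocoh_config`.
#' @export
tlocoh_config <- function(s = 0.05, v_max = NULL, method = c("a", "k"),
                          k = 15, a = NULL, ivg_h = 12,
                          levels = c(0.30, 0.95), min_fixes = 100) {
  method <- match.arg(method)
  stopifnot(s >= 0, k >= 2, is.null(a) || a >= 0, ivg_h > 0,
            all(levels > 0 & levels <= 1))
  structure(list(s = s, v_max = v_max, method = method, k = k, a = a,
                 ivg_h = ivg_h, levels = sort(levels),
                 min_fixes = min_fixes), class = "tlocoh_config")
}

#' Time-scaled distance between fixes
#'
#' @param x1,y1,x2,y2 Projected coordinates in metres (vectorised).
#' @param t1,t2 Timestamps (POSIXct) or numeric hours.
#' @param s Time-scaling parameter (>= 0).
#' @param v_max Maximum theoretical velocity, m/h.
#' @return Distance in metres; `>=` the planar distance, equal to it when
#'   `s = 0` or `t1 == t2`.
#' @export
tsd <- function(x1, y1, t1, x2, y2, t2, s, v_max) {
  dt_h <- if (inherits(t1, "POSIXct") || inherits(t2, "POSIXct")) {
    abs(as.numeric(difftime(t2, t1, units = "hours")))
  } else {
    abs(t2 - t1)
  }
  sqrt((x2 - x1)^2 + (y2 - y1)^2 + (s * v_max * dt_h)^2)
}

## TSD from one parent to all fixes of a prepared coordinate set.
tsd_to_parent <- function(x, y, th, parent, s, v_max) {
  sqrt((x - x[parent])^2 + (y - y[parent])^2 +
         (s * v_max * (th - th[parent]))^2)
}

#' Derive v_max from a track
#'
#' 99.9th percentile of the observed step speeds, capped at `cap` km/h.
#'
#' @param trk Projected `forager_track`.
#' @param cap Cap in km/h (default 10, the speed-filter bound).
#' @return v_max in metres per hour.
#' @export
vmax_from_track <- function(trk, cap = 10) {
  st <- compute_speeds(trk)
  if (nrow(st) == 0) return(cap * 1000)
  min(stats::quantile(st$speed_kmh, 0.999, names = FALSE), cap) * 1000
}

#' Fixed-k neighbour selection
#'
#' The `k` fixes with smallest TSD to the parent; the parent (TSD 0)
#' counts as its own nearest neighbour. Ties broken by fix index.
#'
#' @param trk Projected track or fix data frame.
#' @param parent Parent fix index.
#' @param k Neighbour count (including the parent).
#' @param s,v_max TSD parameters.
#' @return Sorted integer vector of fix indices.
#' @export
select_neighbors_k <- function(trk, parent, k, s, v_max) {
  f <- if (inherits(trk, "forager_track")) trk$fixes else trk
  n <- nrow(f)
  if (k > n) stop("k (", k, ") exceeds number of fixes (", n, ")",
                  call. = FALSE)
  th <- as.numeric(f$timestamp) / 3600
  d <- tsd_to_parent(f$x, f$y, th, parent, s, v_max)
  sort(order(d, seq_len(n))[seq_len(k)])
}

#' Adaptive-a neighbour selection
#'
#' Fixes are sorted by ascending TSD to the parent and included one by
#' one while the running sum of their TSD values stays `<= a`. The parent
#' itself (TSD 0) is always included.
#'
#' @param trk Projected track or fix data frame.
#' @param parent Parent fix index.
#' @param a Cumulative TSD limit, metres (>= 0).
#' @param s,v_max TSD parameters.
#' @return Sorted integer vector of fix indices.
#' @export
select_neighbors_a <- function(trk, parent, a, s, v_max) {
  stopifnot(a >= 0)
  f <- if (inherits(trk, "forager_track")) trk$fixes else trk
  n <- nrow(f)
  th <- as.numeric(f$timestamp) / 3600
  d <- tsd_to_parent(f$x, f$y, th, parent, s, v_max)
  o <- order(d, seq_len(n))
  keep <- cumsum(d[o]) <= a
  keep[1] <- TRUE # parent (d = 0) always in
  sort(o[keep])
}

#' Cumulative-distance limit realised at k neighbours
#'
#' For each parent, the cumulative TSD of its `k` nearest neighbours;
#' the summary (default median over parents) is the conventional starting
#' value `a_k` for the adaptive method.
#'
#' @param trk Projected track.
#' @param k Neighbour count (default 15).
#' @param s,v_max TSD parameters.
#' @param summary Summary function over parents (default median).
#' @return `a_k` in metres.
#' @export
a_for_k <- function(trk, k = 15, s, v_max, summary = stats::median) {
  f <- trk$fixes
  n <- nrow(f)
  stopifnot(k <= n)
  th <- as.numeric(f$timestamp) / 3600
  acc <- numeric(n)
  for (p in seq_len(n)) {
    d <- tsd_to_parent(f$x, f$y, th, p, s, v_max)
    acc[p] <- sum(sort.int(d, partial = k)[seq_len(k)])
  }
  summary(acc)
}

#' Build one convex hull from member fixes
#'
#' @param x,y Member coordinates (metres).
#' @return List with `x`, `y` (polygon vertices, CCW), `area_km2`,
#'   `degenerate`. Degenerate hulls (fewer than 3 distinct non-collinear
#'   members) carry zero area and are excluded from isopleth accounting.
#' @export
build_hull <- function(x, y) {
  h <- convex_hull(x, y)
  list(x = h$x, y = h$y, area_km2 = h$area / 1e6, degenerate = h$degenerate)
}

#' Build the full hullset of a track
#'
#' Generates one hull per parent fix from its selected neighbours, then
#' computes per-hull enclosed fixes, point density, visit count (nsv) and
#' mean locations per visit (mnlv).
#'
#' @param trk Projected `forager_track`.
#' @param config A [tlocoh_config()]; `v_max`/`a` derived if `NULL`.
#' @return Object of class `locoh_hullset`: `fixes`, `config`, `polys`
#'   (list of hull polygons), `enclosed` (list of enclosed fix indices)
#'   and `info` (data frame: `parent`, `parent_time`, `n_members`,
#'   `area_km2`, `degenerate`, `n_enclosed`, `density`, `nsv`, `mnlv`).
#' @export
build_hullset <- function(trk, config = tlocoh_config()) {
  stopifnot(inherits(trk, "forager_track"))
  f <- trk$fixes
  n <- nrow(f)
  if (n < 3) stop("need at least 3 fixes to build hulls", call. = FALSE)
  cfg <- config
  if (is.null(cfg$v_max)) cfg$v_max <- vmax_from_track(trk)
  if (cfg$method == "a" && is.null(cfg$a)) {
    cfg$a <- a_for_k(trk, k = min(cfg$k, n), s = cfg$s, v_max = cfg$v_max)
  }
  th <- as.numeric(f$timestamp) / 3600
  polys <- vector("list", n)
  members <- vector("list", n)
  info <- data.frame(parent = seq_len(n), parent_time = f$timestamp,
                     n_members = 0L, area_km2 = 0, degenerate = TRUE,
                     n_enclosed = 0L, density = NA_real_, nsv = NA_integer_,
                     mnlv = NA_real_)
  for (p in seq_len(n)) {
    d <- tsd_to_parent(f$x, f$y, th, p, cfg$s, cfg$v_max)
    o <- order(d, seq_len(n))
    nb <- if (cfg$method == "k") {
      o[seq_len(min(cfg$k, n))]
    } else {
      cs <- cumsum(d[o])
      sel <- cs <= cfg$a
      sel[1] <- TRUE
      o[sel]
    }
    members[[p]] <- sort(nb)
    h <- build_hull(f$x[nb], f$y[nb])
    polys[[p]] <- h
    info$n_members[p] <- length(nb)
    info$area_km2[p] <- h$area_km2
    info$degenerate[p] <- h$degenerate
  }
  enclosed <- enclosed_points_all(polys, f)
  info$n_enclosed <- vapply(enclosed, length, integer(1))
  info$density <- ifelse(info$degenerate | info$area_km2 <= 0, NA_real_,
                         info$n_enclosed / info$area_km2)
  vis <- lapply(enclosed, function(ix) visit_runs(f$timestamp[ix],
                                                  ivg_h = cfg$ivg_h))
  info$nsv <- vapply(vis, function(v) v$nsv, integer(1))
  info$mnlv <- ifelse(info$nsv > 0, info$n_enclosed / info$nsv, NA_real_)
  structure(list(fixes = f, config = cfg, polys = polys, members = members,
                 enclosed = enclosed, info = info, animal_id = trk$animal_id,
                 sex = trk$sex),
            class = "locoh_hullset")
}

#' @export
print.locoh_hullset <- function(x, ...) {
  cat("<locoh_hullset> ", nrow(x$info), " hulls (",
      sum(!x$info$degenerate), " non-degenerate), method ",
      x$config$method, ", s = ", x$config$s, sep = "")
  if (x$config$method == "a") cat(", a = ", round(x$config$a), " m", sep = "")
  else cat(", k = ", x$config$k, sep = "")
  cat("\n  median hull area: ",
      signif(stats::median(x$info$area_km2[!x$info$degenerate]), 3),
      " km2; median nsv: ",
      stats::median(x$info$nsv[!x$info$degenerate], na.rm = TRUE),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.locoh_hullset <- function(object, ...) {
  print(object)
  print(summary(object$info[!object$info$degenerate,
                            c("area_km2", "n_enclosed", "density", "nsv",
                              "mnlv")]))
  invisible(object)
}

#' Fraction of hulls that are time-selected
#'
#' A hull is time-selected if its neighbour set under the given `s`
#' differs from its neighbour set under `s = 0`. The recommended `s` is
#' the smallest candidate whose fraction falls in `[0.40, 0.80]`.
#'
#' @param trk Projected track.
#' @param s_candidates Numeric vector of candidate `s` values.
#' @param config A [tlocoh_config()] supplying method, k/a, v_max.
#' @return Data frame of class `s_diagnostics` with `s` and
#'   `frac_time_selected`, and attribute `"recommended_s"` (`NA` if no
#'   candidate lands in the band).
#' @export
time_selected_fraction <- function(trk, s_candidates,
                                   config = tlocoh_config()) {
  stopifnot(all(s_candidates >= 0))
  f <- trk$fixes
  n <- nrow(f)
  cfg <- config
  if (is.null(cfg$v_max)) cfg$v_max <- vmax_from_track(trk)
  th <- as.numeric(f$timestamp) / 3600
  nb_for <- function(s_val, a_val) {
    lapply(seq_len(n), function(p) {
      d <- tsd_to_parent(f$x, f$y, th, p, s_val, cfg$v_max)
      o <- order(d, seq_len(n))
      if (cfg$method == "k") {
        sort(o[seq_len(min(cfg$k, n))])
      } else {
        cs <- cumsum(d[o])
        sel <- cs <= a_val
        sel[1] <- TRUE
        sort(o[sel])
      }
    })
  }
  ## the a limit is held at its s-specific derivation so candidates are
  ## comparable; for the k method nothing else varies
  frac <- vapply(s_candidates, function(s_val) {
    a_val <- if (cfg$method == "a") {
      if (is.null(cfg$a)) a_for_k(trk, min(cfg$k, n), s_val, cfg$v_max)
      else cfg$a
    } else NA_real_
    base <- nb_for(0, a_val)
    cur <- nb_for(s_val, a_val)
    mean(!mapply(identical, base, cur))
  }, numeric(1))
  out <- data.frame(s = s_candidates, frac_time_selected = frac)
  in_band <- out$s[out$frac_time_selected >= 0.40 &
                     out$frac_time_selected <= 0.80]
  attr(out, "recommended_s") <- if (length(in_band)) min(in_band) else NA_real_
  class(out) <- c("s_diagnostics", "data.frame")
  out
}

#' Build isopleths from a hullset
#'
#' Hulls are sorted descending by the chosen metric (point density for
#' home ranges, visit frequency for core areas; ties broken by smaller
#' area, then earlier parent timestamp) and their enclosed fixes unioned
#' cumulatively until each requested fraction of the track's retained
#' fixes is covered (fixes counted uniquely across the union). Degenerate
#' hulls are excluded.
#'
#' @param hs A `locoh_hullset`.
#' @param sort_metric `"point_density"` or `"visit_frequency"`.
#' @param levels Fractions in (0, 1]; default from the hullset config.
#' @return Object of class `locoh_isopleths`: `info` data frame (`level`,
#'   `n_hulls`, `area_km2`, `perimeter_km`, `edge_area_ratio`,
#'   `achieved`), `paths` (union rings per level, projected metres),
#'   `hull_idx` (hull indices per level), plus the sort metric.
#' @export
build_isopleths <- function(hs, sort_metric = c("point_density",
                                                "visit_frequency"),
                            levels = NULL) {
  stopifnot(inherits(hs, "locoh_hullset"))
  sort_metric <- match.arg(sort_metric)
  if (is.null(levels)) levels <- hs$config$levels
  levels <- sort(levels)
  info <- hs$info
  ok <- which(!info$degenerate)
  if (length(ok) == 0) stop("no non-degenerate hulls", call. = FALSE)
  metric <- switch(sort_metric,
                   point_density = info$density,
                   visit_frequency = as.numeric(info$nsv))
  o <- ok[order(-metric[ok], info$area_km2[ok],
                as.numeric(info$parent_time[ok]))]
  n_fix <- nrow(hs$fixes)
  covered <- logical(n_fix)
  cum_frac <- numeric(length(o))
  for (i in seq_along(o)) {
    covered[hs$enclosed[[o[i]]]] <- TRUE
    cum_frac[i] <- sum(covered) / n_fix
  }
  out_info <- data.frame(level = levels, n_hulls = NA_integer_,
                         area_km2 = NA_real_, perimeter_km = NA_real_,
                         edge_area_ratio = NA_real_, achieved = NA_real_)
  paths <- vector("list", length(levels))
  hull_idx <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    reach <- which(cum_frac >= levels[li])
    m <- if (length(reach)) min(reach) else length(o)
    sel <- o[seq_len(m)]
    u <- polygon_union(hs$polys[sel])
    out_info$n_hulls[li] <- m
    out_info$area_km2[li] <- u$area / 1e6
    out_info$perimeter_km[li] <- u$perimeter / 1000
    out_info$edge_area_ratio[li] <- if (u$area > 0) {
      (u$perimeter / 1000) / (u$area / 1e6)
    } else NA_real_
    out_info$achieved[li] <- cum_frac[m]
    paths[[li]] <- u$paths
    hull_idx[[li]] <- sel
  }
  structure(list(info = out_info, paths = paths, hull_idx = hull_idx,
                 sort_metric = sort_metric, animal_id = hs$animal_id,
                 sex = hs$sex),
            class = "locoh_isopleths")
}

#' @export
print.locoh_isopleths <- function(x, ...) {
  cat("<locoh_isopleths> sorted by ", x$sort_metric, "\n", sep = "")
  print(transform(x$info, area_km2 = signif(area_km2, 4),
                  perimeter_km = signif(perimeter_km, 4),
                  edge_area_ratio = signif(edge_area_ratio, 3),
                  achieved = round(achieved, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.locoh_isopleths <- function(x, add = FALSE, col = NULL, ...) {
  if (is.null(col)) col <- grDevices::hcl.colors(nrow(x$info), "Blues",
                                                 rev = TRUE, alpha = 0.5)
  allx <- unlist(lapply(x$paths, function(ps) lapply(ps, `[[`, "x")))
  ally <- unlist(lapply(x$paths, function(ps) lapply(ps, `[[`, "y")))
  if (!add) {
    graphics::plot(allx / 1000, ally / 1000, type = "n", asp = 1,
                   xlab = "x (km)", ylab = "y (km)", ...)
  }
  for (li in rev(seq_along(x$paths))) {
    for (p in x$paths[[li]]) {
      graphics::polygon(p$x / 1000, p$y / 1000, col = col[li],
                        border = "grey30")
    }
  }
  invisible(x)
}

#' Isopleth-area diagnostics over k or a candidates
#'
#' For each candidate neighbourhood size, builds the hullset and the
#' density-sorted isopleth at `level`, recording total area and
#' edge:area ratio. Large jumps between consecutive candidates flag a
#' risk of over-merging (type II error); the recommendation is the first
#' candidate whose area changes by less than 10\% from its predecessor
#' (`NA` when no candidate stabilises or fewer than 2 candidates).
#'
#' @param trk Projected track.
#' @param candidates Numeric vector of k or a values (>= 2 of them for a
#'   recommendation).
#' @param type `"k"` or `"a"`.
#' @param config [tlocoh_config()] supplying s, v_max, ivg.
#' @param level Isopleth level (default 0.95).
#' @return Data frame of class `param_diagnostics`: `candidate`,
#'   `area_km2`, `edge_area_ratio`; attribute `"recommended"`.
#' @export
isopleth_diagnostics <- function(trk, candidates, type = c("k", "a"),
                                 config = tlocoh_config(), level = 0.95) {
  type <- match.arg(type)
  candidates <- sort(candidates)
  cfg <- config
  if (is.null(cfg$v_max)) cfg$v_max <- vmax_from_track(trk)
  res <- data.frame(candidate = candidates, area_km2 = NA_real_,
                    edge_area_ratio = NA_real_)
  for (i in seq_along(candidates)) {
    ci <- cfg
    if (type == "k") {
      ci$method <- "k"; ci$k <- candidates[i]
    } else {
      ci$method <- "a"; ci$a <- candidates[i]
    }
    hs <- build_hullset(trk, ci)
    iso <- build_isopleths(hs, "point_density", levels = level)
    res$area_km2[i] <- iso$info$area_km2[1]
    res$edge_area_ratio[i] <- iso$info$edge_area_ratio[1]
  }
  rec <- NA_real_
  if (nrow(res) >= 2) {
    rel <- abs(diff(res$area_km2)) / pmax(res$area_km2[-nrow(res)], 1e-12)
    stable <- which(rel < 0.10)
    if (length(stable)) rec <- res$candidate[min(stable) + 1]
  }
  attr(res, "recommended") <- rec
  class(res) <- c("param_diagnostics", "data.frame")
  res
}

#' Seasonal 95% home range
#'
#' Density-sorted isopleth at level 0.95, computed separately for the
#' summer and fall season windows of the track.
#'
#' @param trk Projected (and filtered) `forager_track`.
#' @param config A [tlocoh_config()].
#' @return Named list (`summer`, `fall`); each element either a one-level
#'   `locoh_isopleths` or a list with `insufficient = TRUE` and the fix
#'   count when the season has fewer than `config$min_fixes` fixes.
#' @export
home_range_95 <- function(trk, config = tlocoh_config()) {
  seasonal_isopleth(trk, config, sort_metric = "point_density",
                    level = 0.95)
}

#' Seasonal 30% core area
#'
#' Visit-frequency (nsv) sorted isopleth at level 0.30; the conservative
#' core of repeatedly revisited habitat.
#'
#' @inheritParams home_range_95
#' @return As [home_range_95()].
#' @export
core_area_30 <- function(trk, config = tlocoh_config()) {
  seasonal_isopleth(trk, config, sort_metric = "visit_frequency",
                    level = 0.30)
}

seasonal_isopleth <- function(trk, config, sort_metric, level) {
  sea <- assign_season(trk$fixes$timestamp)
  out <- list()
  for (s_name in c("summer", "fall")) {
    idx <- which(sea == s_name)
    if (length(idx) < config$min_fixes) {
      out[[s_name]] <- list(insufficient = TRUE, n_fixes = length(idx))
      next
    }
    sub <- trk
    sub$fixes <- trk$fixes[idx, , drop = FALSE]
    rownames(sub$fixes) <- NULL
    hs <- build_hullset(sub, config)
    out[[s_name]] <- build_isopleths(hs, sort_metric, levels = level)
  }
  out
}

## ---- exports --------------------------------------------------------------

#' Export isopleth polygons as GeoJSON
#'
#' Rings are unprojected back to lon/lat using the projection centre.
#'
#' @param iso A `locoh_isopleths`.
#' @param center Projection centre `c(lon, lat)` used for the track.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isopleths_geojson <- function(iso, center, path) {
  feats <- list()
  for (li in seq_along(iso$paths)) {
    rings <- lapply(iso$paths[[li]], function(p) {
      ll <- unproject(p$x, p$y, center)
      coords <- cbind(ll$lon, ll$lat)
      rbind(coords, coords[1, , drop = FALSE]) # close ring
    })
    feats[[li]] <- list(
      type = "Feature",
      properties = list(level = iso$info$level[li],
                        area_km2 = iso$info$area_km2[li],
                        sort_metric = iso$sort_metric),
      geometry = list(type = "MultiPolygon",
                      coordinates = lapply(rings, list)))
  }
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Export the per-hull table as CSV
#'
#' @param hs A `locoh_hullset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hull_table <- function(hs, path) {
  utils::write.csv(hs$info, path, row.names = FALSE)
  invisible(path)
}
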