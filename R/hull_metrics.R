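## Per-hull revisitation/duration metrics, the six-category behavioural
## classification, the near-colony exclusion and time budgets.
##
## Metric vocabulary (population conventions):
##   nsv      number of separate visits to a hull; a new visit begins
##            after the animal has been outside the hull for more than
##            the inter-visit gap (12 h). Values > 1 are return visits,
##            a proxy for site fidelity.
##   mnlv     mean number of enclosed locations per visit, a proxy for
##            residency.
##   *_km2    the same quantities divided by hull area.
##   p(ARS)   mean posterior probability of the slow HMM state over the
##            hull's enclosed fixes; a proxy for apparent foraging.

#' Enclosed fixes of one hull
#'
#' All fixes whose projected position lies inside or on the hull polygon
#' (boundary-inclusive, so hull members are always enclosed).
#'
#' @param poly Hull polygon `list(x=, y=)`.
#' @param fixes Fix data frame with `x`, `y`.
#' @return Integer vector of fix indices, time-ordered.
#' @export
enclosed_points <- function(poly, fixes) {
  if (length(poly$x) < 3) return(integer(0))
  cand <- which(fixes$x >= min(poly$x) & fixes$x <= max(poly$x) &
                  fixes$y >= min(poly$y) & fixes$y <= max(poly$y))
  cand[points_in_polygon(fixes$x[cand], fixes$y[cand], poly)]
}

## Enclosed fixes for every hull of a hullset (bbox prefilter per hull).
enclosed_points_all <- function(polys, fixes) {
  lapply(polys, function(p) {
    if (isTRUE(p$degenerate) || length(p$x) < 3) integer(0)
    else enclosed_points(p, fixes)
  })
}

## Visit segmentation of an ordered timestamp vector.
visit_runs <- function(timestamps, ivg_h = 12) {
  n <- length(timestamps)
  if (n == 0) return(list(nsv = 0L, sizes = integer(0)))
  gaps <- as.numeric(diff(timestamps), units = "secs") / 3600
  new_visit <- c(TRUE, gaps > ivg_h) # strictly more than ivg starts a visit
  id <- cumsum(new_visit)
  list(nsv = max(id), sizes = as.integer(table(id)))
}

#' Number of separate visits (nsv)
#'
#' Consecutive enclosed fixes separated by more than `ivg_h` hours start
#' a new visit; a gap of exactly `ivg_h` does not.
#'
#' @param timestamps Sorted POSIXct of a hull's enclosed fixes.
#' @param ivg_h Inter-visit gap, hours (default 12).
#' @return Integer visit count (0 for an empty set).
#' @export
count_visits <- function(timestamps, ivg_h = 12) {
  visit_runs(timestamps, ivg_h)$nsv
}

#' Mean number of locations per visit (mnlv)
#'
#' @inheritParams count_visits
#' @return Total enclosed fixes divided by nsv; `NA` for an empty set.
#' @export
mean_locations_per_visit <- function(timestamps, ivg_h = 12) {
  v <- visit_runs(timestamps, ivg_h)
  if (v$nsv == 0) return(NA_real_)
  length(timestamps) / v$nsv
}

#' Normalise a hull metric by hull area
#'
#' @param value Metric value(s).
#' @param area_km2 Hull area(s), km^2.
#' @return `value / area_km2`; `NA` where the area is zero or missing
#'   (degenerate hulls, excluded from classification).
#' @export
normalize_by_area <- function(value, area_km2) {
  ifelse(is.na(area_km2) | area_km2 <= 0, NA_real_, value / area_km2)
}

#' Hull eccentricity
#'
#' Eccentricity `sqrt(1 - (b/a)^2)` of the minimum-area enclosing
#' ellipse of the hull vertices (semi-axes `a >= b`). 0 is circle-like
#' (intensive, exploitative use); values near 1 are line-like
#' (extensive, ballistic travel). Degenerate (collinear) hulls return 1.
#'
#' @param poly Hull polygon `list(x=, y=)` (>= 2 distinct points).
#' @param tol Khachiyan iteration tolerance (default 1e-7).
#' @return Eccentricity in [0, 1].
#' @export
hull_eccentricity <- function(poly, tol = 1e-7) {
  pts <- unique(cbind(poly$x, poly$y))
  if (nrow(pts) < 2) return(NA_real_)
  el <- min_enclosing_ellipse(pts[, 1], pts[, 2], tol = tol)
  ax <- el$axes
  if (length(ax) < 2 || ax[1] <= 0 || !is.finite(ax[2]) || ax[2] <= 0) {
    return(1)
  }
  sqrt(max(0, 1 - (ax[2] / ax[1])^2))
}

#' Mean p(ARS) over a hull's enclosed fixes
#'
#' @param enclosed_idx Enclosed fix indices.
#' @param p_ars Per-fix p(ARS) vector aligned with the fix table.
#' @return Arithmetic mean over enclosed fixes with defined p(ARS);
#'   `NA` if none.
#' @export
hull_mean_pars <- function(enclosed_idx, p_ars) {
  v <- p_ars[enclosed_idx]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Full per-hull metric table
#'
#' Computes the hull-metric table (area, nsv, nsv/km^2, mnlv,
#' mnlv/km^2, eccentricity, mean p(ARS), parent distance to colony and
#' parent depth) for a hullset.
#'
#' @param hs A `locoh_hullset` (from [build_hullset()]).
#' @param colony Optional `c(lon, lat)`; parent colony distances require
#'   either this or a `dist_colony_km` fix column.
#' @param p_ars Optional per-fix p(ARS) vector (defaults to the `p_ars`
#'   fix column when present).
#' @param eccentricity Compute the enclosing-ellipse eccentricity per
#'   hull (default TRUE; the iteration is the most expensive metric, so
#'   large batch analyses that do not need shape can skip it).
#' @return Data frame, one row per hull.
#' @export
hull_metrics <- function(hs, colony = NULL, p_ars = NULL,
                         eccentricity = TRUE) {
  stopifnot(inherits(hs, "locoh_hullset"))
  f <- hs$fixes
  info <- hs$info
  if (is.null(p_ars) && "p_ars" %in% names(f)) p_ars <- f$p_ars
  dist_col <- if ("dist_colony_km" %in% names(f)) {
    f$dist_colony_km
  } else if (!is.null(colony)) {
    distance_to_colony(f$lon, f$lat, colony)
  } else {
    rep(NA_real_, nrow(f))
  }
  m <- data.frame(hull = info$parent, animal_id = hs$animal_id,
                  parent_time = info$parent_time,
                  area_km2 = info$area_km2, degenerate = info$degenerate,
                  n_enclosed = info$n_enclosed, nsv = info$nsv,
                  mnlv = info$mnlv)
  m$nsv_km2 <- normalize_by_area(m$nsv, ifelse(m$degenerate, NA, m$area_km2))
  m$mnlv_km2 <- normalize_by_area(m$mnlv, ifelse(m$degenerate, NA,
                                                 m$area_km2))
  m$eccentricity <- if (eccentricity) {
    vapply(seq_along(hs$polys), function(i) {
      if (info$degenerate[i]) 1 else hull_eccentricity(hs$polys[[i]])
    }, numeric(1))
  } else {
    NA_real_
  }
  m$mean_pars <- if (is.null(p_ars)) NA_real_ else {
    vapply(hs$enclosed, hull_mean_pars, numeric(1), p_ars = p_ars)
  }
  m$dist_colony_km <- dist_col[info$parent]
  m$depth_m <- if ("depth_m" %in% names(f)) f$depth_m[info$parent] else NA_real_
  m$season <- assign_season(info$parent_time)
  m
}

#' Exclude hulls near the colony
#'
#' Hulls whose parent fix lies within `radius_km` of the colony are
#' dropped from classification and time budgets (near-colony milling
#' would otherwise dominate the revisitation quantiles). Home ranges and
#' core areas are unaffected by this exclusion.
#'
#' @param metrics Hull-metric table from [hull_metrics()] (needs
#'   `dist_colony_km`).
#' @param radius_km Exclusion radius, km (default 15).
#' @return The retained rows.
#' @export
exclude_near_colony <- function(metrics, radius_km = 15) {
  stopifnot("dist_colony_km" %in% names(metrics))
  metrics[is.na(metrics$dist_colony_km) |
            metrics$dist_colony_km > radius_km, , drop = FALSE]
}

#' Six-category behavioural classification
#'
#' Population-level scheme over all retained hulls (pooled across
#' animals). The first and third quartiles of `nsv_km2` split hulls into
#' infrequent (< q1), frequent and very frequent (> q3) visitation
#' bands; each band is split again at its own median of `mnlv_km2`
#' (ties to the lower-duration category), giving categories 1-2, 3-4 and
#' 5-6. Category 6 is the band with the most return visits and the
#' longest stays, the strongest signature of repeated foraging.
#'
#' @param metrics Pooled hull-metric table (rows with `NA` normalized
#'   metrics are dropped).
#' @return Object of class `hull_classification`: the input rows with a
#'   `category` column, plus `q1`, `q3` and the per-band `duration_medians`.
#' @export
classify_categories <- function(metrics) {
  m <- metrics[!is.na(metrics$nsv_km2) & !is.na(metrics$mnlv_km2), ,
               drop = FALSE]
  if (nrow(m) < 4) stop("need at least 4 hulls with defined metrics",
                        call. = FALSE)
  q <- stats::quantile(m$nsv_km2, c(0.25, 0.75), names = FALSE)
  if (q[1] == q[2]) stop("degenerate thresholds: nsv_km2 quartiles equal",
                         call. = FALSE)
  band <- ifelse(m$nsv_km2 < q[1], 1L, ifelse(m$nsv_km2 > q[2], 3L, 2L))
  med <- vapply(1:3, function(b) {
    v <- m$mnlv_km2[band == b]
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1))
  cat6 <- 2L * (band - 1L) + ifelse(m$mnlv_km2 <= med[band], 1L, 2L)
  m$band <- factor(c("infrequent", "frequent", "very_frequent")[band],
                   levels = c("infrequent", "frequent", "very_frequent"))
  m$category <- cat6
  structure(list(hulls = m, q1 = q[1], q3 = q[2], duration_medians = med),
            class = "hull_classification")
}

#' @export
print.hull_classification <- function(x, ...) {
  cat("<hull_classification> ", nrow(x$hulls), " hulls\n", sep = "")
  cat(sprintf("  nsv/km2 quartiles: q1 = %.3g, q3 = %.3g\n", x$q1, x$q3))
  cat(sprintf("  band medians of mnlv/km2: %.3g / %.3g / %.3g\n",
              x$duration_medians[1], x$duration_medians[2],
              x$duration_medians[3]))
  print(table(category = x$hulls$category))
  invisible(x)
}

#' Time budgets over the six behaviour categories
#'
#' Each classified hull's parent fix represents one sampling interval;
#' the per-animal, per-season time budget is the proportion of those
#' parent fixes carrying each category. Medians and raw mad across
#' animals are reported per category and per visitation band.
#'
#' @param cls A `hull_classification`.
#' @return Object of class `time_budget`: `by_animal` (animal x season x
#'   category proportions, summing to 1 within animal x season) and
#'   `summary` (per season x category median and mad across animals).
#' @export
time_budget <- function(cls) {
  stopifnot(inherits(cls, "hull_classification"))
  h <- cls$hulls
  h <- h[h$season %in% c("summer", "fall"), , drop = FALSE]
  combos <- unique(h[, c("animal_id", "season")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- h$animal_id == combos$animal_id[i] & h$season == combos$season[i]
    tab <- tabulate(h$category[sel], nbins = 6)
    prop <- tab / sum(tab)
    rows[[i]] <- data.frame(animal_id = combos$animal_id[i],
                            season = combos$season[i],
                            category = 1:6, proportion = prop)
  }
  by_animal <- do.call(rbind, rows)
  agg <- list()
  for (s_name in intersect(c("summer", "fall"), unique(by_animal$season))) {
    for (k in 1:6) {
      v <- by_animal$proportion[by_animal$season == s_name &
                                  by_animal$category == k]
      mm <- median_mad(v)
      agg[[length(agg) + 1]] <- data.frame(season = s_name, category = k,
                                           median = mm[1], mad = mm[2],
                                           n_animals = length(v))
    }
  }
  band_of <- c(1, 1, 2, 2, 3, 3)
  band_rows <- list()
  for (s_name in intersect(c("summer", "fall"), unique(by_animal$season))) {
    for (b in 1:3) {
      props <- vapply(unique(by_animal$animal_id), function(id) {
        sel <- by_animal$animal_id == id & by_animal$season == s_name &
          band_of[by_animal$category] == b
        if (!any(sel)) NA_real_ else sum(by_animal$proportion[sel])
      }, numeric(1))
      props <- props[!is.na(props)]
      if (!length(props)) next
      mm <- median_mad(props)
      band_rows[[length(band_rows) + 1]] <-
        data.frame(season = s_name,
                   band = c("infrequent", "frequent", "very_frequent")[b],
                   median = mm[1], mad = mm[2], n_animals = length(props))
    }
  }
  structure(list(by_animal = by_animal,
                 summary = do.call(rbind, agg),
                 band_summary = do.call(rbind, band_rows)),
            class = "time_budget")
}

#' @export
print.time_budget <- function(x, ...) {
  cat("<time_budget> per-category medians (mad) across animals\n")
  print(transform(x$summary, median = round(median, 3),
                  mad = round(mad, 3)), row.names = FALSE)
  invisible(x)
}

#' Export classified fixes as GeoJSON points
#'
#' Parent fixes of classified hulls, coloured by visitation band
#' (categories 1-2 dark orange, 3-4 green, 5-6 blue).
#'
#' @param cls A `hull_classification`.
#' @param fixes Fix table with `lon`, `lat` (indexed by `hull` parent id).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classified_geojson <- function(cls, fixes, path) {
  h <- cls$hulls
  band_col <- c("#cc6600", "#cc6600", "#1a9641", "#1a9641",
                "#2b5bce", "#2b5bce")
  feats <- lapply(seq_len(nrow(h)), function(i) {
    p <- h$hull[i]
    list(type = "Feature",
         properties = list(animal_id = h$animal_id[i],
                           category = h$category[i],
                           band = as.character(h$band[i]),
                           `marker-color` = band_col[h$category[i]]),
         geometry = list(type = "Point",
                         coordinates = c(fixes$lon[p], fixes$lat[p])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
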