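## Body-mass accounting and the AICc multimodel-inference layer.

#' Estimated mass at parturition
#'
#' Females weighed a few days after giving birth are corrected back to
#' the day of parturition using the average lactation mass-loss rate.
#'
#' @param measured_mass Mass at weighing, kg.
#' @param days_postpartum Days since parturition (>= 0).
#' @param rate Lactation mass-loss rate, kg/day (default 4.1).
#' @return Estimated parturition mass, kg.
#' @export
parturition_mass <- function(measured_mass, days_postpartum, rate = 4.1) {
  if (any(days_postpartum < 0)) stop("days_postpartum must be >= 0",
                                     call. = FALSE)
  measured_mass + rate * days_postpartum
}

#' Relative daily mass-gain rate
#'
#' Mass gain per day as a percentage of initial body mass:
#' `100 * (final - initial) / (initial * days)`.
#'
#' @param initial,final Masses, kg.
#' @param days Days between measurements (> 0).
#' @return Rate in percent of initial mass per day.
#' @export
mass_gain_rate <- function(initial, final, days) {
  if (any(days <= 0)) stop("days must be > 0", call. = FALSE)
  if (any(initial <= 0)) stop("initial mass must be > 0", call. = FALSE)
  100 * (final - initial) / (initial * days)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 LL + 2K + 2K(K+1)/(n - K - 1)`.
#'
#' @param LL Maximised log-likelihood.
#' @param K Parameter count (fixed coefficients plus variance
#'   components).
#' @param n Observation count; must exceed `K + 1`.
#' @return AICc value(s).
#' @export
aicc <- function(LL, K, n) {
  if (any(n <= K + 1)) stop("AICc undefined: n must exceed K + 1",
                            call. = FALSE)
  -2 * LL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Delta-AICc and Akaike weights
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return List with `delta` (differences from the minimum) and `weight`
#'   (`exp(-delta/2)` normalised to sum 1).
#' @export
delta_and_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 1)
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  list(delta = delta, weight = w / sum(w))
}

#' Evidence ratio between two models
#'
#' `ER = w_i / w_j = exp((delta_j - delta_i) / 2)` in AICc units. Given
#' a single `delta`, returns `exp(delta / 2)`, the evidence for the
#' better model over the one `delta` units behind it.
#'
#' @param delta Optional AICc difference between the two models.
#' @param w_i,w_j Optional Akaike weights (both > 0).
#' @return The evidence ratio.
#' @export
evidence_ratio <- function(delta = NULL, w_i = NULL, w_j = NULL) {
  if (!is.null(delta)) return(exp(delta / 2))
  stopifnot(!is.null(w_i), !is.null(w_j))
  if (any(c(w_i, w_j) <= 0)) stop("weights must be positive", call. = FALSE)
  w_i / w_j
}

#' Marginal and conditional R-squared for mixed models
#'
#' Variance-decomposition goodness of fit: the marginal R2 is the
#' fixed-effect variance over the total (fixed + random intercept +
#' residual); the conditional R2 adds the random-intercept variance to
#' the numerator.
#'
#' @param var_fixed Variance of the fixed-effect predictor.
#' @param var_random Random-intercept variance.
#' @param var_resid Residual variance.
#' @return Named numeric `c(marginal =, conditional =)`.
#' @export
r2_glmm <- function(var_fixed, var_random, var_resid) {
  v <- c(var_fixed, var_random, var_resid)
  if (any(v < 0)) stop("variances must be >= 0", call. = FALSE)
  tot <- sum(v)
  if (tot == 0) stop("all variance components are zero", call. = FALSE)
  c(marginal = var_fixed / tot,
    conditional = (var_fixed + var_random) / tot)
}

#' Median and raw median absolute deviation
#'
#' The mad is reported unscaled (no 1.4826 consistency factor): the
#' median of absolute deviations from the median.
#'
#' @param values Numeric vector (>= 1 value).
#' @return Named numeric `c(median =, mad =)`.
#' @export
median_mad <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  m <- stats::median(values)
  c(median = m, mad = stats::median(abs(values - m)))
}

#' Candidate fixed-effect model sets
#'
#' The 13-model set over body mass (`Bm`), season (`Sn`) and sex (`Sx`)
#' used for home-range and core-area selection tables, as named
#' right-hand-side formulas for a given response.
#'
#' @param response Response variable name.
#' @return Named list of formulas.
#' @export
candidate_models_hr <- function(response = "log_area") {
  rhs <- c("~ 1" = "1",
           "Bm" = "Bm",
           "Sn" = "Sn",
           "Sx" = "Sx",
           "Bm + Sn" = "Bm + Sn",
           "Bm + Sx" = "Bm + Sx",
           "Sn + Sx" = "Sn + Sx",
           "Bm + Sn + Sx" = "Bm + Sn + Sx",
           "Sn + Sx + Sn * Sx" = "Sn * Sx",
           "Bm + Sx + Bm * Sx" = "Bm * Sx",
           "Bm + Sn + Sx + Sn * Sx" = "Bm + Sn * Sx",
           "Bm + Sn + Sx + Bm * Sx" = "Sn + Bm * Sx",
           "Bm + Sn + Sx + Sn * Sx + Bm * Sx" = "Sn * Sx + Bm * Sx")
  out <- lapply(rhs, function(r) {
    stats::as.formula(paste(response, "~", r))
  })
  names(out) <- names(rhs)
  out
}

#' Fit a candidate-model set
#'
#' Fits each candidate by maximum likelihood and extracts the quantities
#' the selection layer needs: `LL`, `K` (fixed coefficients + variance
#' components), `n`, and the variance decomposition for [r2_glmm()].
#' With a `random` grouping column the backend is [lme4::lmer()] with
#' `REML = FALSE` (ML likelihoods are required for AICc comparison
#' across fixed-effect structures); without one, [stats::lm()].
#'
#' @param data Data frame with the response and predictor columns.
#' @param models Named list of formulas (e.g. [candidate_models_hr()]).
#' @param random Optional name of the random-intercept grouping column
#'   (e.g. animal id).
#' @return Data frame of class `candidate_fits` with one row per model:
#'   `model`, `K`, `LL`, `n`, `var_fixed`, `var_random`, `var_resid`,
#'   `ok` (FALSE where the fit failed; other models are still returned).
#' @export
fit_candidates <- function(data, models, random = NULL) {
  rows <- lapply(names(models), function(nm) {
    fm <- models[[nm]]
    res <- tryCatch({
      if (is.null(random)) {
        fit <- stats::lm(fm, data = data)
        beta <- stats::coef(fit)
        X <- stats::model.matrix(fit)
        list(LL = as.numeric(stats::logLik(fit)),
             K = length(beta) + 1, # + residual variance
             n = stats::nobs(fit),
             var_fixed = stats::var(as.numeric(X %*% beta)),
             var_random = 0,
             var_resid = sum(stats::residuals(fit)^2) / stats::nobs(fit))
      } else {
        fm2 <- stats::update(fm, paste(". ~ . + (1 |", random, ")"))
        fit <- lme4::lmer(fm2, data = data, REML = FALSE)
        beta <- lme4::fixef(fit)
        X <- stats::model.matrix(fit)
        vc <- lme4::VarCorr(fit)
        list(LL = as.numeric(stats::logLik(fit)),
             K = length(beta) + 2, # + random-intercept and residual var
             n = stats::nobs(fit),
             var_fixed = stats::var(as.numeric(X %*% beta)),
             var_random = as.numeric(vc[[random]][1]),
             var_resid = attr(vc, "sc")^2)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      data.frame(model = nm, K = NA_integer_, LL = NA_real_, n = NA_integer_,
                 var_fixed = NA_real_, var_random = NA_real_,
                 var_resid = NA_real_, ok = FALSE)
    } else {
      data.frame(model = nm, K = res$K, LL = res$LL, n = res$n,
                 var_fixed = res$var_fixed, var_random = res$var_random,
                 var_resid = res$var_resid, ok = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("candidate_fits", "data.frame")
  out
}

#' Build a model-selection table
#'
#' Turns candidate log-likelihoods into AICc, delta-AICc, Akaike weights
#' and ranks, ordered best-first.
#'
#' @param fits A `candidate_fits` data frame, or any data frame with
#'   `model`, `LL`, `K`, `n` columns (failed fits dropped).
#' @return Data frame of class `selection_table` with columns `model`,
#'   `K`, `AICc`, `dAICc`, `w`, `LL`, `rank`; attribute `"er_next"`
#'   holds the evidence ratio of the top model over the runner-up.
#' @export
selection_table <- function(fits) {
  f <- fits
  if ("ok" %in% names(f)) f <- f[f$ok, , drop = FALSE]
  stopifnot(nrow(f) >= 1)
  a <- aicc(f$LL, f$K, f$n)
  dw <- delta_and_weights(a)
  out <- data.frame(model = f$model, K = f$K, AICc = a, dAICc = dw$delta,
                    w = dw$weight, LL = f$LL, n = f$n)
  out <- out[order(out$AICc, out$model), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "er_next") <- if (nrow(out) >= 2) {
    evidence_ratio(delta = out$dAICc[2])
  } else NA_real_
  class(out) <- c("selection_table", "data.frame")
  out
}

#' @export
print.selection_table <- function(x, digits = 2, ...) {
  cat("<selection_table> ", nrow(x), " candidate model(s), n = ",
      x$n[1], "\n", sep = "")
  df <- data.frame(Model = x$model, K = x$K,
                   AICc = round(x$AICc, digits),
                   dAICc = round(x$dAICc, digits),
                   w = round(x$w, digits), LL = round(x$LL, digits))
  print(df, row.names = FALSE)
  if (nrow(x) >= 2) {
    cat(sprintf("  evidence ratio, best vs runner-up: %.2f\n",
                attr(x, "er_next")))
  }
  invisible(x)
}

#' Write a selection table as CSV
#'
#' Columns mirror the reporting convention Model, K, AICc, dAICc, w, LL.
#'
#' @param st A `selection_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(st, path) {
  utils::write.csv(st[, c("model", "K", "AICc", "dAICc", "w", "LL")],
                   path, row.names = FALSE)
  invisible(path)
}
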