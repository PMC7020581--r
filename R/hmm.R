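## Two-state hidden Markov model on travel rate.
##
## The observable is the speed between consecutive projected fixes,
## segmented into bursts wherever the inter-fix gap exceeds a threshold
## (haul-outs suspend the GPS, and speeds across such gaps are
## meaningless). Emissions are gamma by state; state 1 is the slow,
## area-restricted-search state by convention. Fitting is Baum-Welch EM
## with the forward recursion restarted at every burst.

#' Per-fix speeds segmented into bursts
#'
#' @param trk A projected `forager_track` (needs `x`, `y`).
#' @param gap_threshold_h Inter-fix gap (hours) above which a new burst
#'   starts; default 2 (eight missed 15-min fixes).
#' @return Data frame of class `step_series` with columns `fix` (row index
#'   of the fix the step ends at), `speed_kmh`, `burst`. Bursts with fewer
#'   than 2 fixes contribute no steps.
#' @export
compute_speeds <- function(trk, gap_threshold_h = 2) {
  f <- if (inherits(trk, "forager_track")) trk$fixes else trk
  if (nrow(f) < 2) {
    out <- data.frame(fix = integer(0), speed_kmh = numeric(0),
                      burst = integer(0))
    class(out) <- c("step_series", "data.frame")
    return(out)
  }
  stopifnot(all(c("x", "y") %in% names(f)))
  dt_h <- as.numeric(diff(f$timestamp), units = "secs") / 3600
  d_km <- sqrt(diff(f$x)^2 + diff(f$y)^2) / 1000
  new_burst <- c(TRUE, dt_h > gap_threshold_h)
  burst_of_fix <- cumsum(new_burst)
  keep <- dt_h <= gap_threshold_h & dt_h > 0
  out <- data.frame(fix = which(c(FALSE, keep)),
                    speed_kmh = (d_km / dt_h)[keep],
                    burst = burst_of_fix[-1][keep])
  out$burst <- match(out$burst, unique(out$burst))
  class(out) <- c("step_series", "data.frame")
  out
}

#' Fit the two-state speed HMM
#'
#' Baum-Welch EM for a 2-state HMM with gamma emissions on speed.
#' Initialisation is a deterministic 2-means split of the speeds;
#' the transition matrix starts at 0.9 self-persistence. Zero speeds are
#' nudged to half the smallest positive speed (gamma support is open at
#' 0). After fitting, states are reordered so state 1 has the smaller
#' emission mean (slow / area-restricted search).
#'
#' @param series A `step_series` from [compute_speeds()], or a numeric
#'   vector of speeds (treated as one burst).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @param seed Integer seed controlling any stochastic initialisation
#'   (the default initialiser is deterministic; the seed is still set for
#'   reproducibility of downstream use).
#' @return Object of class `speed_hmm`: gamma `shape`, `rate` (length 2,
#'   slow first), transition matrix `tpm`, initial distribution `delta`,
#'   `logLik`, `converged`, `iterations`, and the prepared observation
#'   list.
#' @export
fit_hmm2 <- function(series, tol = 1e-6, max_iter = 500, seed = 1L) {
  if (is.numeric(series)) {
    series <- data.frame(fix = seq_along(series) + 1L, speed_kmh = series,
                         burst = 1L)
  }
  sp <- series$speed_kmh
  if (length(sp) < 50) stop("need at least 50 speed observations",
                            call. = FALSE)
  if (any(sp < 0)) stop("negative speeds", call. = FALSE)
  if (diff(range(sp)) < .Machine$double.eps^0.5) {
    stop("degenerate data: all speeds identical", call. = FALSE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  pos <- sp[sp > 0]
  if (length(pos) == 0) stop("degenerate data: all speeds zero", call. = FALSE)
  sp[sp == 0] <- min(pos) / 2
  obs <- split(sp, series$burst)

  ## deterministic 2-means on the speeds
  ctr <- unname(stats::quantile(sp, c(0.25, 0.75)))
  if (diff(ctr) < 1e-8) ctr <- range(sp)
  km <- stats::kmeans(sp, centers = matrix(ctr, ncol = 1))
  mu <- sort(km$centers[, 1])
  vr <- c(stats::var(sp[km$cluster == which.min(km$centers)]),
          stats::var(sp[km$cluster == which.max(km$centers)]))
  vr[!is.finite(vr) | vr <= 0] <- (mu[!is.finite(vr) | vr <= 0] / 2)^2 + 1e-6
  shape <- mu^2 / vr
  rate <- mu / vr
  tpm <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  delta <- c(0.5, 0.5)

  ll_old <- -Inf
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    e <- hmm_estep(obs, shape, rate, tpm, delta)
    ll <- e$logLik
    ## M-step; the initial distribution is tied to the stationary
    ## distribution of the transition matrix (bursts are segments of
    ## one ongoing process, not independent restarts)
    tpm <- e$xi_sum / rowSums(e$xi_sum)
    delta <- stationary_dist(tpm)
    w <- e$gamma_all
    xall <- e$x_all
    for (s in 1:2) {
      fit <- gamma_wmle(xall, w[, s])
      shape[s] <- fit$shape
      rate[s] <- fit$rate
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  ## slow state first
  if (shape[1] / rate[1] > shape[2] / rate[2]) {
    shape <- rev(shape); rate <- rev(rate)
    tpm <- tpm[2:1, 2:1]; delta <- rev(delta)
  }
  structure(list(shape = shape, rate = rate, tpm = tpm, delta = delta,
                 logLik = ll_old, converged = converged, iterations = it,
                 n_obs = length(sp), obs = obs, series = series),
            class = "speed_hmm")
}

## Stationary distribution of a 2x2 stochastic matrix.
stationary_dist <- function(tpm) {
  p12 <- tpm[1, 2]; p21 <- tpm[2, 1]
  if (p12 + p21 <= 0) return(c(0.5, 0.5))
  c(p21, p12) / (p12 + p21)
}

## E-step over bursts: scaled forward-backward.
hmm_estep <- function(obs, shape, rate, tpm, delta) {
  ll <- 0
  gam_list <- list()
  xi_sum <- matrix(0, 2, 2)
  first_post <- c(0, 0)
  for (b in seq_along(obs)) {
    x <- obs[[b]]
    Tn <- length(x)
    dens <- cbind(stats::dgamma(x, shape[1], rate[1]),
                  stats::dgamma(x, shape[2], rate[2]))
    dens <- pmax(dens, 1e-300)
    alpha <- matrix(0, Tn, 2)
    cvec <- numeric(Tn)
    a <- delta * dens[1, ]
    cvec[1] <- sum(a)
    alpha[1, ] <- a / cvec[1]
    if (Tn > 1) {
      for (t in 2:Tn) {
        a <- (alpha[t - 1, ] %*% tpm) * dens[t, ]
        cvec[t] <- sum(a)
        alpha[t, ] <- a / cvec[t]
      }
    }
    beta <- matrix(0, Tn, 2)
    beta[Tn, ] <- 1
    if (Tn > 1) {
      for (t in (Tn - 1):1) {
        beta[t, ] <- (tpm %*% (dens[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
      }
    }
    gam <- alpha * beta
    gam <- gam / rowSums(gam)
    if (Tn > 1) {
      for (t in 1:(Tn - 1)) {
        xi <- (alpha[t, ] %o% (dens[t + 1, ] * beta[t + 1, ])) * tpm /
          cvec[t + 1]
        xi_sum <- xi_sum + xi
      }
    }
    first_post <- first_post + gam[1, ]
    gam_list[[b]] <- gam
    ll <- ll + sum(log(cvec))
  }
  list(logLik = ll, gamma_all = do.call(rbind, gam_list),
       x_all = unlist(obs, use.names = FALSE), xi_sum = xi_sum,
       first_post = first_post)
}

## Weighted gamma MLE: Newton on the profile equation
## log(shape) - digamma(shape) = log(wmean) - wmeanlog.
gamma_wmle <- function(x, w) {
  W <- sum(w)
  m <- sum(w * x) / W
  ml <- sum(w * log(x)) / W
  s <- log(m) - ml
  if (s <= 0) s <- 1e-8
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s) # Minka's start
  for (i in 1:50) {
    num <- log(a) - digamma(a) - s
    den <- 1 / a - trigamma(a)
    step <- num / den
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-10 * a) { a <- a_new; break }
    a <- a_new
  }
  list(shape = a, rate = a / m)
}

#' @export
print.speed_hmm <- function(x, ...) {
  cat("<speed_hmm> 2-state gamma HMM on travel rate\n")
  mu <- x$shape / x$rate
  cat(sprintf("  state means (km/h): slow %.3f, fast %.3f\n", mu[1], mu[2]))
  cat(sprintf("  persistence: slow %.3f, fast %.3f\n",
              x$tpm[1, 1], x$tpm[2, 2]))
  cat(sprintf("  logLik %.2f after %d iteration(s)%s, n = %d\n", x$logLik,
              x$iterations, if (x$converged) "" else " (NOT converged)",
              x$n_obs))
  invisible(x)
}

#' @export
summary.speed_hmm <- function(object, ...) {
  print(object)
  cat("  gamma shape:", format(object$shape, digits = 4), "\n")
  cat("  gamma rate :", format(object$rate, digits = 4), "\n")
  cat("  transition matrix:\n")
  print(round(object$tpm, 4))
  invisible(object)
}

#' @export
coef.speed_hmm <- function(object, ...) {
  c(shape_slow = object$shape[1], shape_fast = object$shape[2],
    rate_slow = object$rate[1], rate_fast = object$rate[2],
    p_stay_slow = object$tpm[1, 1], p_stay_fast = object$tpm[2, 2])
}

#' @export
logLik.speed_hmm <- function(object, ...) {
  structure(object$logLik, df = 7, nobs = object$n_obs, class = "logLik")
}

#' Posterior probability of area-restricted search
#'
#' Forward-backward smoothed posterior probability of the slow state for
#' every step of the series the model was fitted to (or a new series).
#'
#' @param fit A `speed_hmm`.
#' @param series Optional `step_series`; defaults to the fitted one.
#' @param accept_unconverged Proceed even if the EM did not converge.
#' @return Data frame with `fix`, `speed_kmh`, `burst`, `p_ars`.
#' @export
posterior_pars <- function(fit, series = NULL, accept_unconverged = FALSE) {
  stopifnot(inherits(fit, "speed_hmm"))
  if (!fit$converged && !accept_unconverged) {
    stop("HMM fit did not converge; pass accept_unconverged = TRUE to use it",
         call. = FALSE)
  }
  if (is.null(series)) series <- fit$series
  if (nrow(series) == 0) stop("empty step series", call. = FALSE)
  sp <- series$speed_kmh
  pos <- sp[sp > 0]
  sp[sp == 0] <- if (length(pos)) min(pos) / 2 else 1e-6
  obs <- split(sp, series$burst)
  e <- hmm_estep(obs, fit$shape, fit$rate, fit$tpm, fit$delta)
  out <- series
  out$p_ars <- e$gamma_all[, 1]
  out
}

#' Viterbi decoding of the speed HMM
#'
#' @param fit A `speed_hmm`.
#' @param series Optional `step_series`; defaults to the fitted one.
#' @return Integer vector of states (1 = slow/ARS, 2 = fast/travel).
#' @export
viterbi_states <- function(fit, series = NULL) {
  stopifnot(inherits(fit, "speed_hmm"))
  if (is.null(series)) series <- fit$series
  sp <- series$speed_kmh
  pos <- sp[sp > 0]
  sp[sp == 0] <- if (length(pos)) min(pos) / 2 else 1e-6
  obs <- split(sp, series$burst)
  states <- integer(0)
  for (x in obs) {
    Tn <- length(x)
    ld <- cbind(stats::dgamma(x, fit$shape[1], fit$rate[1], log = TRUE),
                stats::dgamma(x, fit$shape[2], fit$rate[2], log = TRUE))
    lt <- log(fit$tpm)
    v <- matrix(-Inf, Tn, 2)
    bp <- matrix(0L, Tn, 2)
    v[1, ] <- log(fit$delta) + ld[1, ]
    if (Tn > 1) {
      for (t in 2:Tn) {
        for (s in 1:2) {
          cand <- v[t - 1, ] + lt[, s]
          bp[t, s] <- which.max(cand)
          v[t, s] <- cand[bp[t, s]] + ld[t, s]
        }
      }
    }
    st <- integer(Tn)
    st[Tn] <- which.max(v[Tn, ])
    if (Tn > 1) for (t in (Tn - 1):1) st[t] <- bp[t + 1, st[t + 1]]
    states <- c(states, st)
  }
  states
}

#' Simulate a two-state gamma speed series
#'
#' Generates a Markov chain of states and gamma speeds, for validation
#' and power analysis of the speed HMM.
#'
#' @param n Number of steps.
#' @param shape,rate Length-2 gamma parameters (slow first).
#' @param tpm 2x2 transition matrix.
#' @param delta Initial state distribution (default stationary-ish 0.5).
#' @param seed Optional integer seed.
#' @return List with `speed` and true `state`.
#' @export
simulate_speed_hmm <- function(n, shape, rate, tpm,
                               delta = c(0.5, 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  st <- integer(n)
  st[1] <- sample(1:2, 1, prob = delta)
  for (t in seq_len(n - 1)) {
    st[t + 1] <- sample(1:2, 1, prob = tpm[st[t], ])
  }
  list(speed = stats::rgamma(n, shape[st], rate[st]), state = st)
}

#' @export
simulate.speed_hmm <- function(object, nsim = 1, seed = NULL, n = 1000, ...) {
  replicate(nsim,
            simulate_speed_hmm(n, object$shape, object$rate, object$tpm,
                               object$delta, seed = seed),
            simplify = FALSE)
}

#' Attach p(ARS) to a track's fix table
#'
#' Fixes without a step (the first fix of each burst, and fixes dropped
#' from all bursts) carry the nearest following step's posterior within
#' the burst where available, otherwise `NA`.
#'
#' @param trk A `forager_track`.
#' @param pars Output of [posterior_pars()].
#' @return The track with a `p_ars` fix column.
#' @export
attach_pars <- function(trk, pars) {
  f <- trk$fixes
  f$p_ars <- NA_real_
  f$p_ars[pars$fix] <- pars$p_ars
  ## burst-first fixes inherit the first step of their burst
  for (b in unique(pars$burst)) {
    rows <- pars[pars$burst == b, ]
    first_fix <- min(rows$fix) - 1L
    if (first_fix >= 1 && is.na(f$p_ars[first_fix])) {
      f$p_ars[first_fix] <- rows$p_ars[which.min(rows$fix)]
    }
  }
  trk$fixes <- f
  trk
}

#' Export fitted HMM parameters as a structured report
#'
#' @param fit A `speed_hmm`.
#' @param path Output path; format chosen by extension (`.json` or
#'   `.yaml`).
#' @return `path`, invisibly.
#' @export
write_hmm_report <- function(fit, path) {
  rep <- list(states = c("ars_slow", "travel_fast"),
              gamma_shape = fit$shape, gamma_rate = fit$rate,
              state_means_kmh = fit$shape / fit$rate,
              tpm = list(slow = fit$tpm[1, ], fast = fit$tpm[2, ]),
              delta = fit$delta, logLik = fit$logLik,
              converged = fit$converged, iterations = fit$iterations,
              n_obs = fit$n_obs)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(rep, path)
  } else {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
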