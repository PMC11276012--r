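# Interaction persistence: binary indicator series, intermittent
# autocorrelation C(t), correlation-time estimation with censoring,
# replica-level aggregation, and bridging-water identity exchange.

#' Build a binary interaction indicator series from contact tables
#'
#' `h[t] = 1` iff a contact matching the requested mode exists in frame t.
#' The `water_mediated` mode is identity-agnostic: any bridging water
#' counts, so a bridge that survives through exchange of the bridging-water
#' molecule is an uninterrupted interaction.
#'
#' @param analysis a `"contact_analysis"` (one replica, contiguous frames).
#' @param mode `"direct"` (category DIRECT_INTERACTION),
#'   `"water_mediated"` (any water bridge in the frame, regardless of the
#'   frame's category), or `"any_polar"` (category other than
#'   NO_POLAR_CONTACT).
#' @return object of class `"indicator_series"`: list with `replica_id`,
#'   `times_ns`, `h` (0/1 integer vector), `mode`.
#' @export
indicator_series <- function(analysis,
                             mode = c("direct", "water_mediated",
                                      "any_polar")) {
  mode <- match.arg(mode)
  cats <- analysis$categories
  if (is.null(cats) || nrow(cats) == 0)
    stop("empty frame range: no categories in contact analysis")
  h <- switch(mode,
    direct = as.integer(cats$category == "DIRECT_INTERACTION"),
    any_polar = as.integer(cats$category != "NO_POLAR_CONTACT"),
    water_mediated = as.integer(cats$frame %in% analysis$bridges$frame))
  structure(list(replica_id = analysis$replica_id, times_ns = cats$time_ns,
                 h = h, mode = mode), class = "indicator_series")
}

#' Construct an indicator series directly from a 0/1 vector
#'
#' Convenience constructor for synthetic or externally computed
#' indicators.
#'
#' @param h 0/1 vector.
#' @param dt_ns uniform frame spacing, ns.
#' @param replica_id integer label.
#' @param mode label for the interaction mode.
#' @return an `"indicator_series"`.
#' @export
as_indicator_series <- function(h, dt_ns, replica_id = 1L, mode = "direct") {
  h <- as.integer(h)
  if (!all(h %in% c(0L, 1L))) stop("h must be binary")
  structure(list(replica_id = as.integer(replica_id),
                 times_ns = (seq_along(h) - 1) * dt_ns,
                 h = h, mode = mode), class = "indicator_series")
}

#' Intermittent autocorrelation of an interaction indicator
#'
#' History-independent (intermittent) definition:
#' `C(t) = <h(s) h(s+t)>_s / <h(s)^2>_s`, with the average over all valid
#' time origins s. The interaction may break and reform within the lag
#' window; `C(0) = 1` whenever the indicator is not identically zero.
#'
#' @param series an `"indicator_series"` with uniform time spacing.
#' @param max_lag_ns maximum lag; defaults to (and may not exceed) half the
#'   series duration.
#' @return object of class `"correlation_result"`: `lags_ns`, `C`,
#'   `mean_occupancy`, with `tau_ns`/`tau_method`/`censored` unset until
#'   [correlation_time()] is applied.
#' @export
autocorrelation <- function(series, max_lag_ns = NULL) {
  h <- series$h
  n <- length(h)
  if (n < 2) stop("series too short for autocorrelation")
  t <- series$times_ns
  dts <- diff(t)
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-9 * max(dt, 1)))
    stop("indicator series must be uniformly spaced in time")
  if (mean(h) == 0)
    stop("no-event error: indicator is identically zero (mean_occupancy=0)")
  half <- (n - 1) * dt / 2
  if (is.null(max_lag_ns)) max_lag_ns <- half
  if (max_lag_ns > half + 1e-9)
    stop("max_lag_ns exceeds half the series duration")
  kmax <- floor(max_lag_ns / dt + 1e-9)
  denom <- mean(h^2)
  C <- vapply(0:kmax, function(k) {
    mean(h[1:(n - k)] * h[(1 + k):n]) / denom
  }, numeric(1))
  structure(list(lags_ns = (0:kmax) * dt, C = C, tau_ns = NA_real_,
                 tau_method = NA_character_, censored = NA,
                 mean_occupancy = mean(h),
                 replica_id = series$replica_id, mode = series$mode),
            class = "correlation_result")
}

#' Correlation time from a C(t) curve
#'
#' Two estimators of the persistence time tau, both correcting for the
#' long-lag plateau `C_inf`. For indicator curves the plateau is taken as
#' the mean occupancy (its exact long-lag limit); curves without an
#' occupancy fall back to the tail-window mean:
#' \describe{
#'   \item{integral}{`tau = integral of (C(t) - C_inf) / (1 - C_inf) dt`
#'     (trapezoidal), with `C_inf` the mean of the last `tail_frac` of
#'     lags; the integral is truncated at the first lag where C crosses
#'     the plateau, since beyond that point the integrand is mean-zero
#'     sampling noise.}
#'   \item{exponential_fit}{least-squares fit of
#'     `C(t) = C_inf + (1 - C_inf) exp(-t / tau)`.}
#' }
#' When `C` never decays below `1 - plateau_tol` the estimate is censored:
#' `tau_ns` is set to the maximum usable lag and is a lower bound.
#'
#' @param corr a `"correlation_result"` from [autocorrelation()].
#' @param method `"integral"` or `"exponential_fit"`.
#' @param plateau_tol censoring threshold on the decay of C.
#' @param tail_frac fraction of the longest lags used for the plateau
#'   estimate.
#' @return the input with `tau_ns`, `tau_method`, `censored` filled in.
#' @export
correlation_time <- function(corr, method = c("integral", "exponential_fit"),
                             plateau_tol = 0.02, tail_frac = 0.10) {
  method <- match.arg(method)
  if (!inherits(corr, "correlation_result"))
    stop("corr must be a correlation_result")
  C <- corr$C; lags <- corr$lags_ns
  if (length(C) < 2) stop("C(t) too short for correlation time")
  if (abs(C[1] - 1) > 1e-6)
    stop("contract violation: C(0) must equal 1, got ", C[1])
  corr$tau_method <- method
  if (min(C) > 1 - plateau_tol) {
    corr$censored <- TRUE
    corr$tau_ns <- max(lags)
    return(corr)
  }
  corr$censored <- FALSE
  # plateau: for a binary indicator C(t) -> mean occupancy exactly, and the
  # known occupancy is far more stable than the noisy tail of one replica;
  # raw curves without an occupancy fall back to the tail-window mean
  occ <- corr$mean_occupancy
  C_inf <- if (!is.null(occ) && is.finite(occ) && occ < 1) {
    occ
  } else {
    mean(utils::tail(C, max(1L, ceiling(tail_frac * length(C)))))
  }
  if (C_inf >= 1) C_inf <- min(C)  # degenerate; fall back
  if (method == "integral") {
    # truncate at the first plateau crossing: beyond it the integrand is
    # mean-zero noise whose accumulated area would swamp the estimate
    cross <- which(C <= C_inf)
    L <- if (length(cross) > 0 && cross[1] > 1) cross[1] else length(C)
    g <- (C[seq_len(L)] - C_inf) / (1 - C_inf)
    dl <- diff(lags[seq_len(L)])
    corr$tau_ns <- sum(dl * (utils::head(g, -1) + utils::tail(g, -1)) / 2)
  } else {
    df <- data.frame(t = lags, C = C)
    # initial tau: lag nearest the 1/e crossing of the plateau-corrected curve
    gc <- (C - C_inf) / (1 - C_inf)
    below <- which(gc < exp(-1))
    tau0 <- if (length(below) > 0) max(lags[below[1]], lags[2]) else max(lags) / 3
    fit <- minpack.lm::nlsLM(
      C ~ cinf + (1 - cinf) * exp(-t / tau),
      data = df, start = list(cinf = max(0, C_inf), tau = tau0),
      lower = c(0, lags[2] * 1e-3), upper = c(0.9999, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    corr$tau_ns <- stats::coef(fit)[["tau"]]
  }
  corr
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("C(t): %d lags (0..%.3g ns), occupancy %.3f",
              length(x$lags_ns), max(x$lags_ns), x$mean_occupancy))
  if (!is.na(x$tau_ns))
    cat(sprintf(", tau = %.4g ns (%s%s)", x$tau_ns, x$tau_method,
                if (isTRUE(x$censored)) ", censored" else ""))
  cat("\n")
  invisible(x)
}

#' Aggregate a per-replica statistic
#'
#' Mean and standard error of the mean across independent replicas, the
#' statistical unit for all reported uncertainties.
#'
#' @param values numeric vector, one value per replica (n >= 1).
#' @return list of class `"replica_aggregate"`: `values`, `mean`, `sem`
#'   (NA when n = 1), `n`.
#' @export
aggregate_replicas <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("no replica values to aggregate")
  n <- length(values)
  sem <- if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_
  structure(list(values = values, mean = mean(values), sem = sem, n = n),
            class = "replica_aggregate")
}

#' @export
print.replica_aggregate <- function(x, ...) {
  cat(sprintf("mean %.4g +/- %.3g (SEM, n=%d)\n", x$mean,
              ifelse(is.na(x$sem), NaN, x$sem), x$n))
  invisible(x)
}

#' Bridging-water identity exchange summary
#'
#' Counts frames carrying at least one water bridge, identity switches
#' (successive bridge-carrying frames whose bridging-water sets are
#' disjoint), and the number of distinct bridging waters observed. Frames
#' are taken in time order; "successive" means adjacent in the ordered
#' subsequence of bridge-carrying frames.
#'
#' @param bridges per-frame water-bridge table (columns `frame`,
#'   `water_resno`), e.g. `analysis$bridges`.
#' @return list of class `"water_exchange"`: `n_bridge_frames`,
#'   `n_identity_switches`, `distinct_waters`, `switch_fraction`
#'   (switches / (bridge frames - 1), NA when < 2 bridge frames).
#' @export
water_exchange <- function(bridges) {
  if (NROW(bridges) == 0)
    return(structure(list(n_bridge_frames = 0L, n_identity_switches = 0L,
                          distinct_waters = 0L, switch_fraction = NA_real_),
                     class = "water_exchange"))
  sets <- split(bridges$water_resno, bridges$frame)
  ord <- order(as.numeric(names(sets)))
  sets <- sets[ord]
  nb <- length(sets)
  switches <- 0L
  if (nb >= 2) {
    for (i in 2:nb) {
      if (length(intersect(sets[[i - 1]], sets[[i]])) == 0)
        switches <- switches + 1L
    }
  }
  structure(list(
    n_bridge_frames = nb,
    n_identity_switches = switches,
    distinct_waters = length(unique(bridges$water_resno)),
    switch_fraction = if (nb >= 2) switches / (nb - 1) else NA_real_),
    class = "water_exchange")
}
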