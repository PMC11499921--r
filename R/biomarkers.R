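#' Extract APD90 / diastolic-interval pairs from node events
#'
#' For each consecutive beat pair at a node, the diastolic interval is the
#' time from 90% repolarization of one beat to the activation of the next,
#' paired with the APD90 of that next beat. Non-physiologic pairs (DI <= 0)
#' are dropped and counted.
#'
#' @param events Events tibble (`node`, `t_act`, `apd90`) from a tissue or
#'   cell trace (or a `simulation_trace`).
#' @param node Node id to extract (default: all nodes).
#' @param window_ms Optional `c(t0, t1)` restriction on activation times
#'   (e.g. the ramp-pacing span).
#' @param max_beats_after_break If not NULL, keep at most this many beats
#'   after each detected cycle-length break (the "up to 3 beats after a
#'   wave break" reading); default uses all valid beats.
#' @param min_peak_mV Beats whose peak stays below this potential are
#'   partial (non-propagated) responses — stimulus-artifact blips near the
#'   pacing site — and are excluded from restitution pairs.
#' @return Tibble: `node`, `di_ms`, `apd90_ms`, plus attribute `n_dropped`.
#' @export
extract_apd_di <- function(events, node = NULL, window_ms = NULL,
                           max_beats_after_break = NULL, min_peak_mV = -20) {
  if (inherits(events, "simulation_trace")) events <- events$events
  ev <- events
  if (!is.null(node)) ev <- ev[ev$node %in% node, ]
  if (!is.null(window_ms))
    ev <- ev[ev$t_act >= window_ms[1] & ev$t_act <= window_ms[2], ]
  ev <- ev[is.finite(ev$apd90), ]
  if ("v_peak" %in% names(ev)) ev <- ev[!is.finite(ev$v_peak) |
                                          ev$v_peak >= min_peak_mV, ]
  if (nrow(ev) < 2) {
    out <- tibble(node = integer(0), di_ms = numeric(0), apd90_ms = numeric(0))
    attr(out, "n_dropped") <- 0L
    attr(out, "diagnostic") <- "fewer than 2 beats detected"
    return(out)
  }
  per_node <- ev %>% arrange(node, t_act) %>% group_by(node) %>%
    summarise(di_ms = list({
      t90 <- t_act + apd90
      t_act[-1] - t90[-length(t90)]
    }), apd90_ms = list(apd90[-1]), t_next = list(t_act[-1]),
    .groups = "drop")
  out <- tidyr::unnest(per_node, c(di_ms, apd90_ms, t_next))
  if (!is.null(max_beats_after_break) && nrow(out) > 0) {
    out <- out %>% group_by(node) %>%
      mutate(brk = cumsum(c(TRUE, abs(diff(di_ms)) > 20)),
             k = dplyr::row_number()) %>%
      group_by(node, brk) %>% dplyr::slice_head(n = max_beats_after_break) %>%
      ungroup() %>% select(-brk, -k)
  }
  bad <- out$di_ms <= 0
  res <- out[!bad, c("node", "di_ms", "apd90_ms")]
  attr(res, "n_dropped") <- sum(bad)
  res
}

#' Fit the APD restitution curve and its maximal slope
#'
#' Nonlinear least-squares fit of APD90 = y0 + A1 (1 - exp(-DI / tau1))
#' to the observed (DI, APD90) pairs, with the maximal slope Smax
#' evaluated from the analytic derivative (A1 / tau1) exp(-DI / tau1) at
#' the smallest observed DI (the slope is monotone decreasing in DI).
#' Initialization: y0 at the minimum APD, A1 at the APD range, tau1 at the
#' median DI. The search is bounded to the physiologic region y0 >= 0,
#' A1 >= 0 (monotone non-decreasing restitution) and tau1 in [1, 1000] ms,
#' which keeps isolated malformed beats from driving the curve into
#' non-physiologic corners.
#'
#' @param pairs Tibble with `di_ms`, `apd90_ms` (>= 4 rows spanning >= 2
#'   distinct DIs).
#' @return A `restitution_fit`: list with `y0`, `a1`, `tau1`, `smax`,
#'   `di_min`, `n_points`, `rss`, `ok` (FALSE with `reason` when
#'   unfittable).
#' @export
fit_restitution <- function(pairs) {
  unfit <- function(reason) {
    structure(list(y0 = NA_real_, a1 = NA_real_, tau1 = NA_real_,
                   smax = NA_real_, di_min = NA_real_,
                   n_points = nrow(pairs), rss = NA_real_,
                   ok = FALSE, reason = reason),
              class = "restitution_fit")
  }
  if (nrow(pairs) < 4) return(unfit("fewer than 4 pairs"))
  if (length(unique(round(pairs$di_ms, 6))) < 2) return(unfit("degenerate DI span"))
  apd_rng <- diff(range(pairs$apd90_ms))
  if (apd_rng < 1e-9) {
    # flat restitution: zero slope by construction
    return(structure(list(y0 = mean(pairs$apd90_ms), a1 = 0, tau1 = NA_real_,
                          smax = 0, di_min = min(pairs$di_ms),
                          n_points = nrow(pairs), rss = 0, ok = TRUE,
                          reason = NULL),
                     class = "restitution_fit"))
  }
  start <- list(y0 = min(pairs$apd90_ms), a1 = apd_rng,
                tau1 = min(max(median(pairs$di_ms), 1), 1000))
  fit <- tryCatch(
    minpack.lm::nlsLM(apd90_ms ~ y0 + a1 * (1 - exp(-di_ms / tau1)),
                      data = pairs, start = start,
                      lower = c(y0 = 0, a1 = 0, tau1 = 1),
                      upper = c(y0 = Inf, a1 = Inf, tau1 = 1000),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(unfit("fit failed to converge"))
  cf <- coef(fit)
  di_min <- min(pairs$di_ms)
  smax <- (cf[["a1"]] / cf[["tau1"]]) * exp(-di_min / cf[["tau1"]])
  structure(list(y0 = cf[["y0"]], a1 = cf[["a1"]], tau1 = cf[["tau1"]],
                 smax = max(smax, 0), di_min = di_min,
                 n_points = nrow(pairs),
                 rss = sum(stats::resid(fit)^2), ok = TRUE, reason = NULL),
            class = "restitution_fit")
}

#' Analytic restitution slope
#'
#' Derivative of the restitution curve, (A1 / tau1) exp(-DI / tau1).
#'
#' @param a1,tau1 Curve parameters (ms).
#' @param di_ms Diastolic interval (ms).
#' @return Slope (dimensionless).
#' @export
restitution_slope <- function(a1, tau1, di_ms) {
  (a1 / tau1) * exp(-di_ms / tau1)
}

#' @export
tidy.restitution_fit <- function(x, ...) {
  tibble(term = c("y0", "a1", "tau1"),
         estimate = c(x$y0, x$a1, x$tau1))
}

#' @export
glance.restitution_fit <- function(x, ...) {
  tibble(smax = x$smax, di_min_ms = x$di_min, n_points = x$n_points,
         rss = x$rss, ok = x$ok)
}

#' @export
print.restitution_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<restitution_fit> y0 = %.1f ms, A1 = %.1f ms, tau1 = %.1f ms, Smax = %.3f (DI_min = %.0f ms, n = %d)\n",
                x$y0, x$a1, x$tau1, x$smax, x$di_min, x$n_points))
  else cat("<restitution_fit> unfittable:", x$reason, "\n")
  invisible(x)
}

#' Per-node Smax map with regional aggregation
#'
#' Fits the restitution curve at every (requested) node from ramp-pacing
#' events and aggregates the per-node maximal slopes over the six-region
#' scheme.
#'
#' @param trace A `simulation_trace` from ramp pacing (or its events).
#' @param substrate The `substrate_map` (for region labels).
#' @param nodes Node subset (default: all nodes with events).
#' @param window_ms Pairs restricted to this activation-time window
#'   (default: the full trace).
#' @param max_beats_after_break See [extract_apd_di()].
#' @return List (`biomarker_map`): `values` tibble (node, smax, ok),
#'   `regional` (see [regional_summary()]), `n_unfittable`,
#'   `low_confidence` flag.
#' @export
smax_map <- function(trace, substrate, nodes = NULL, window_ms = NULL,
                     max_beats_after_break = NULL) {
  pairs <- extract_apd_di(trace, window_ms = window_ms,
                          max_beats_after_break = max_beats_after_break)
  if (!is.null(nodes)) pairs <- pairs[pairs$node %in% nodes, ]
  fits <- pairs %>% group_by(node) %>%
    summarise(fit = list(fit_restitution(dplyr::pick(dplyr::everything()))),
              .groups = "drop")
  vals <- tibble(node = fits$node,
                 smax = vapply(fits$fit, function(f) f$smax, numeric(1)),
                 ok = vapply(fits$fit, function(f) f$ok, logical(1)))
  n_unfit <- sum(!vals$ok)
  good <- vals[vals$ok, c("node", "smax")]
  names(good)[2] <- "value"
  reg <- regional_summary(good, substrate)
  structure(list(values = vals, regional = reg, n_unfittable = n_unfit,
                 low_confidence = n_unfit > 0.5 * nrow(vals),
                 biomarker = "smax"),
            class = "biomarker_map")
}

#' Dominant frequency of one uniformly sampled signal
#'
#' Mean-removed, Hann-tapered, 4x zero-padded FFT; the dominant frequency
#' is the maximal-magnitude bin inside the physiologic search band.
#'
#' @param x Signal samples.
#' @param fs_hz Sampling frequency (Hz).
#' @param band_hz Search band (Hz), default 1-20.
#' @return One-row tibble: `df_hz`, `power`, `found`.
#' @export
dominant_frequency <- function(x, fs_hz, band_hz = c(1, 20)) {
  n <- length(x)
  if (n < 8) abort("signal too short for spectral analysis")
  x <- x - mean(x)
  if (max(abs(x)) < 1e-9)
    return(tibble(df_hz = NA_real_, power = 0, found = FALSE))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  xp <- c(x * w, rep(0, 3 * n))
  sp <- abs(fft(xp))^2
  freqs <- (seq_along(xp) - 1) * fs_hz / length(xp)
  sel <- which(freqs >= band_hz[1] & freqs <= min(band_hz[2], fs_hz / 2))
  if (length(sel) == 0) abort("search band empty at this sampling rate")
  i <- sel[which.max(sp[sel])]
  tibble(df_hz = freqs[i], power = sp[i], found = TRUE)
}

#' Per-node dominant-frequency map with regional aggregation
#'
#' Computes the dominant frequency of every node's membrane-potential
#' signal over the analysis window (the all-node window recording of the
#' trace) and aggregates regionally.
#'
#' @param trace A `simulation_trace` run with `window_ms` recording (via
#'   `df_window_ms` of [run_protocol()]).
#' @param substrate The `substrate_map`.
#' @param band_hz Search band (Hz).
#' @return A `biomarker_map` list, as [smax_map()].
#' @export
df_map <- function(trace, substrate, band_hz = c(1, 20)) {
  tt <- trace$window_time_ms
  if (length(tt) < 8)
    abort("trace has no spectral window recording; rerun with df_window_ms")
  if (trace$t_stop < max(tt) - 1e-6)
    abort("rhythm terminated before the spectral window; DF not computed")
  fs <- 1000 / (tt[2] - tt[1])
  vm <- trace$window_vm
  res <- apply(vm, 1, function(x) {
    d <- dominant_frequency(x, fs, band_hz)
    c(d$df_hz, d$found)
  })
  vals <- tibble(node = seq_len(nrow(vm)), df_hz = res[1, ],
                 ok = res[2, ] > 0)
  good <- vals[vals$ok & !is.na(vals$df_hz), c("node", "df_hz")]
  names(good)[2] <- "value"
  reg <- regional_summary(good, substrate)
  structure(list(values = vals, regional = reg,
                 n_unfittable = sum(!vals$ok),
                 low_confidence = sum(!vals$ok) > 0.5 * nrow(vals),
                 biomarker = "df",
                 window_ms = range(tt)),
            class = "biomarker_map")
}

#' Regional aggregation of a per-node biomarker
#'
#' Mean per region plus the cohort-style aggregates: global mean, the
#' highest and lowest regional means, and the delta-regional value
#' (highest minus lowest, always >= 0).
#'
#' @param values Tibble with `node`, `value`.
#' @param substrate The `substrate_map` (provides `region` per node).
#' @return List: `per_region` tibble (region, mean, n), `mean`, `highest`,
#'   `lowest`, `delta_regional`.
#' @export
regional_summary <- function(values, substrate) {
  reg <- substrate$region[values$node]
  d <- tibble(region = reg, value = values$value)
  d <- d[!is.na(d$region), ]
  per <- d %>% group_by(region, .drop = FALSE) %>%
    summarise(mean = mean(value), n = dplyr::n(), .groups = "drop")
  per_nonempty <- per[per$n > 0, ]
  list(per_region = per,
       mean = mean(d$value),
       highest = if (nrow(per_nonempty)) max(per_nonempty$mean) else NA_real_,
       lowest = if (nrow(per_nonempty)) min(per_nonempty$mean) else NA_real_,
       delta_regional = if (nrow(per_nonempty))
         max(per_nonempty$mean) - min(per_nonempty$mean) else NA_real_)
}

#' @export
print.biomarker_map <- function(x, ...) {
  cat("<biomarker_map> ", x$biomarker, ": ", nrow(x$values), " nodes (",
      x$n_unfittable, " unfittable)\n", sep = "")
  cat(sprintf("  mean %.3f | highest %.3f | lowest %.3f | delta %.3f\n",
              x$regional$mean, x$regional$highest, x$regional$lowest,
              x$regional$delta_regional))
  invisible(x)
}

#' @export
tidy.biomarker_map <- function(x, ...) x$values

#' @export
glance.biomarker_map <- function(x, ...) {
  tibble(biomarker = x$biomarker, mean = x$regional$mean,
         highest = x$regional$highest, lowest = x$regional$lowest,
         delta_regional = x$regional$delta_regional,
         n_nodes = nrow(x$values), n_unfittable = x$n_unfittable,
         low_confidence = x$low_confidence)
}
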