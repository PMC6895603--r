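#' Uniformly sampled physiological trace
#'
#' Container for a uniformly sampled time series (membrane potential,
#' force, current or calcium) with channel label, units and optional
#' pacing event times.
#'
#' @param time_ms numeric vector of times (ms), strictly increasing and
#'   uniformly spaced.
#' @param value numeric vector of samples.
#' @param channel label, e.g. \code{"ap"}, \code{"force"}, \code{"current"}.
#' @param units unit string, e.g. \code{"mV"}, \code{"mN"}.
#' @param pacing_ms optional numeric vector of stimulus times (ms).
#' @return A data frame of class \code{eht_trace} with columns
#'   \code{time_ms} and \code{value} and metadata attributes.
#' @export
as_trace <- function(time_ms, value, channel = "ap", units = "mV",
                     pacing_ms = numeric()) {
  stopifnot(is.numeric(time_ms), is.numeric(value),
            length(time_ms) == length(value), length(time_ms) >= 2)
  dt <- diff(time_ms)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 0.01 * max(dt))
    stop("trace must be uniformly sampled", call. = FALSE)
  structure(data.frame(time_ms = time_ms, value = value),
            class = c("eht_trace", "data.frame"),
            channel = channel, units = units, pacing_ms = pacing_ms,
            dt_ms = mean(dt))
}

#' @export
print.eht_trace <- function(x, ...) {
  cat("<eht_trace> channel", attr(x, "channel"),
      sprintf("(%s), %d samples at %.4g ms, %.4g-%.4g ms\n",
              attr(x, "units"), nrow(x), attr(x, "dt_ms"),
              x$time_ms[1], x$time_ms[nrow(x)]))
  invisible(x)
}

#' @export
plot.eht_trace <- function(x, ...) {
  graphics::plot(x$time_ms, x$value, type = "l", xlab = "time (ms)",
                 ylab = paste0(attr(x, "channel"), " (",
                               attr(x, "units"), ")"), ...)
  invisible(x)
}

# Linear resampling onto a finer uniform grid (used when the sampling
# interval is too coarse for upstroke analysis).
.resample_trace <- function(trace, dt_new) {
  tt <- seq(trace$time_ms[1], trace$time_ms[nrow(trace)], by = dt_new)
  vv <- stats::approx(trace$time_ms, trace$value, xout = tt)$y
  as_trace(tt, vv, channel = attr(trace, "channel"),
           units = attr(trace, "units"),
           pacing_ms = attr(trace, "pacing_ms"))
}

# Interpolated time of the first crossing of `level` between samples
# i and i+1 scanning indices `idx` in the stated direction.
.cross_time <- function(t, v, idx, level, falling = FALSE) {
  for (i in idx) {
    v0 <- v[i]; v1 <- v[i + 1]
    hit <- if (falling) (v0 >= level && v1 < level)
           else (v0 <= level && v1 > level)
    if (hit) {
      frac <- (level - v0) / (v1 - v0)
      return(t[i] + frac * (t[i + 1] - t[i]))
    }
  }
  NA_real_
}

#' Action-potential features
#'
#' Extracts the standard AP phenotype metrics from a voltage trace:
#' take-off potential (TOP), AP amplitude (APA = peak - TOP), maximum
#' upstroke velocity (Vmax), and AP durations at 50 and 90 percent
#' repolarization (APD50/APD90), measured from take-off until the
#' potential repolarizes to TOP + (1 - x/100) * APA, with sub-sample
#' linear interpolation at threshold crossings. Take-off is the last
#' sample before dV/dt first exceeds 5 percent of Vmax on the upstroke.
#' Monophasic AP (MAP) traces are processed identically (MAPD90 is the
#' APD90 of the MAP trace).
#'
#' @param trace an \code{\link{as_trace}} voltage trace (mV), or a data
#'   frame with columns \code{time_ms}, \code{value}.
#' @param stim_time stimulus time (ms); analysis starts here.
#' @return Object of class \code{ap_features}: list with fields
#'   \code{TOP_mV}, \code{APA_mV}, \code{Vmax_V_per_s}, \code{APD50_ms},
#'   \code{APD90_ms}, \code{peak_mV}, \code{takeoff_ms}, \code{censored}.
#' @examples
#' tr <- gen_ap_trace(ap_config(noise_sd = 0))$trace
#' ap_features(tr)
#' @export
ap_features <- function(trace, stim_time = 0) {
  if (!inherits(trace, "eht_trace"))
    trace <- as_trace(trace$time_ms, trace$value)
  if (attr(trace, "dt_ms") > 0.5)
    trace <- .resample_trace(trace, 0.1)
  t <- trace$time_ms
  v <- trace$value
  sel <- t >= stim_time
  t <- t[sel]; v <- v[sel]
  n <- length(v)
  if (n < 5) stop("trace too short after stim_time", call. = FALSE)

  ipk <- which.max(v)
  peak <- v[ipk]

  # upstroke velocity (central differences up to the peak)
  dt <- t[2] - t[1]
  dvdt <- c(diff(v) / dt, 0)
  up <- seq_len(max(ipk - 1, 1))
  vmax <- max(dvdt[up])
  ivmax <- up[which.max(dvdt[up])]

  # take-off: last sample before dV/dt exceeds 5% of Vmax
  thr <- 0.05 * vmax
  if (!is.finite(vmax) || vmax <= 0)
    stop("no action potential detected (no upstroke)", call. = FALSE)
  icross <- which(dvdt[up] > thr)[1]
  if (is.na(icross))
    stop("no action potential detected (no upstroke)", call. = FALSE)
  # dvdt[i] spans [t_i, t_i+1]: t_i is the last sample before the rise
  itop <- max(icross, 1)
  # noise-robust take-off potential: median of the last diastolic samples
  top <- stats::median(v[max(1, itop - 4):itop])
  t_top <- t[itop]

  if (peak < top + 10)
    stop("no action potential detected (peak < TOP + 10 mV)",
         call. = FALSE)
  apa <- peak - top

  lvl <- function(x) top + (1 - x / 100) * apa
  post <- seq(ipk, n - 1)
  t50 <- .cross_time(t, v, post, lvl(50), falling = TRUE)
  t90 <- .cross_time(t, v, post, lvl(90), falling = TRUE)
  censored <- is.na(t50) || is.na(t90)

  structure(list(TOP_mV = top, APA_mV = apa, Vmax_V_per_s = vmax,
                 APD50_ms = t50 - t_top, APD90_ms = t90 - t_top,
                 peak_mV = peak, takeoff_ms = t_top,
                 censored = censored),
            class = "ap_features")
}

#' @export
print.ap_features <- function(x, ...) {
  cat("<ap_features>\n")
  cat(sprintf("  TOP %.1f mV  APA %.1f mV  Vmax %.0f V/s\n",
              x$TOP_mV, x$APA_mV, x$Vmax_V_per_s))
  cat(sprintf("  APD50 %.1f ms  APD90 %.1f ms%s\n", x$APD50_ms,
              x$APD90_ms, if (x$censored) "  [censored]" else ""))
  invisible(x)
}

# Robust noise SD of a trace (MAD of first differences).
.trace_noise_sd <- function(v) {
  stats::mad(diff(v)) / sqrt(2)
}

#' Contraction-trace features
#'
#' Extracts force amplitude, contraction time T1_80 and relaxation time
#' T2_80 from an engineered-heart-tissue force trace. Amplitude is peak
#' minus baseline (baseline = 10th percentile of the trace). T1_80 is the
#' time from the upstroke crossing of 20 percent of amplitude to the peak;
#' T2_80 the time from the peak to the decay crossing of 20 percent of
#' amplitude, so each span covers 80 percent of peak height. Peaks are
#' detected with minimum prominence 3x the robust noise SD; with several
#' beats, features are averaged over complete beats.
#'
#' @param trace an \code{\link{as_trace}} force trace (mN), or a data
#'   frame with \code{time_ms}, \code{value}.
#' @return Object of class \code{contraction_features}: list with
#'   \code{baseline_mN}, \code{amplitude_mN}, \code{T1_80_ms},
#'   \code{T2_80_ms}, \code{peak_time_ms}, \code{n_beats},
#'   \code{censored}.
#' @examples
#' tr <- gen_force_trace(force_config(noise_sd = 0))$trace
#' contraction_features(tr)
#' @export
contraction_features <- function(trace) {
  if (!inherits(trace, "eht_trace"))
    trace <- as_trace(trace$time_ms, trace$value, channel = "force",
                      units = "mN")
  t <- trace$time_ms
  v <- trace$value
  n <- length(v)
  noise <- .trace_noise_sd(v)
  # light running-mean smoothing (~10 ms) so noise does not bias the
  # threshold crossings; negligible for pulses slower than 50 ms
  if (noise > 0) {
    dt <- attr(trace, "dt_ms")
    k <- max(3L, as.integer(round(10 / dt)))
    if (k %% 2 == 0) k <- k + 1L
    vs <- stats::filter(v, rep(1 / k, k), sides = 2)
    v <- ifelse(is.na(vs), v, as.numeric(vs))
  }
  baseline <- unname(stats::quantile(v, 0.10))
  prom <- max(3 * noise, 1e-12)

  # local maxima with sufficient prominence over the baseline
  is_max <- which(diff(sign(diff(v))) < 0) + 1L
  peaks <- is_max[v[is_max] - baseline >= prom]
  if (!length(peaks)) stop("no contraction peak detected", call. = FALSE)
  # merge noisy sub-peaks: keep the highest peak between 20%-level dips
  amp_all <- max(v[peaks]) - baseline
  keep <- peaks[v[peaks] - baseline >= 0.5 * amp_all]

  # group peaks separated by a return below the 20% level
  lvl20 <- baseline + 0.2 * amp_all
  groups <- list()
  cur <- keep[1]
  if (length(keep) > 1) {
    for (i in 2:length(keep)) {
      seg <- v[keep[i - 1]:keep[i]]
      if (min(seg) < lvl20) {
        groups[[length(groups) + 1L]] <- cur
        cur <- keep[i]
      } else if (v[keep[i]] > v[cur]) cur <- keep[i]
    }
  }
  groups[[length(groups) + 1L]] <- cur
  pk_idx <- unlist(groups)

  one_beat <- function(ip) {
    pk <- v[ip]
    amp <- pk - baseline
    lvl <- baseline + 0.2 * amp
    t_up <- .cross_time(t, v, rev(seq_len(ip - 1)), lvl, falling = FALSE)
    # rev() scans backwards; find the *last* upward crossing before peak
    if (ip < n)
      t_dn <- .cross_time(t, v, seq(ip, n - 1), lvl, falling = TRUE)
    else t_dn <- NA_real_
    c(amp = amp, t1 = t[ip] - t_up, t2 = t_dn - t[ip], tp = t[ip],
      cens = as.numeric(is.na(t_up) || is.na(t_dn)))
  }
  rows <- vapply(pk_idx, one_beat, numeric(5))
  complete <- rows["cens", ] == 0
  if (!any(complete)) complete <- rep(TRUE, ncol(rows))
  m <- rowMeans(rows[, complete, drop = FALSE])

  structure(list(baseline_mN = baseline, amplitude_mN = m[["amp"]],
                 T1_80_ms = m[["t1"]], T2_80_ms = m[["t2"]],
                 peak_time_ms = rows["tp", which(complete)[1]],
                 n_beats = sum(complete),
                 censored = any(rows["cens", ] > 0)),
            class = "contraction_features")
}

#' @export
print.contraction_features <- function(x, ...) {
  cat("<contraction_features>\n")
  cat(sprintf("  amplitude %.4g mN (baseline %.4g)\n", x$amplitude_mN,
              x$baseline_mN))
  cat(sprintf("  T1_80 %.1f ms  T2_80 %.1f ms  (%d beat%s%s)\n",
              x$T1_80_ms, x$T2_80_ms, x$n_beats,
              if (x$n_beats == 1) "" else "s",
              if (x$censored) ", censored beats dropped" else ""))
  invisible(x)
}

#' Signed percent change of a feature
#'
#' \code{100 * (treated - baseline) / baseline}, the convention used to
#' quantify drug effects relative to baseline.
#'
#' @param baseline,treated numbers, or feature objects
#'   (\code{ap_features} / \code{contraction_features}) when \code{field}
#'   names the field to compare.
#' @param field optional field name, e.g. \code{"amplitude_mN"}.
#' @return Signed percent change.
#' @examples
#' percent_change(2.0, 1.42)  # -29
#' @export
percent_change <- function(baseline, treated, field = NULL) {
  if (!is.null(field)) {
    baseline <- baseline[[field]]
    treated <- treated[[field]]
  }
  if (!is.numeric(baseline) || !is.numeric(treated))
    stop("baseline and treated must be numeric (or give `field`)",
         call. = FALSE)
  if (any(baseline == 0)) stop("zero baseline", call. = FALSE)
  100 * (treated - baseline) / baseline
}

#' Heart-rate-corrected QT interval
#'
#' Bazett correction \code{QTcB = QT / RR^(1/2)} and Fridericia
#' correction \code{QTcF = QT / RR^(1/3)}, with QT in ms and RR in s.
#'
#' @param qt QT interval(s), ms.
#' @param rr RR interval(s), s.
#' @param method \code{"bazett"} or \code{"fridericia"}.
#' @return Corrected QT (ms), vectorized.
#' @examples
#' qtc(400, 0.64, "bazett")  # 500
#' @export
qtc <- function(qt, rr, method = c("bazett", "fridericia")) {
  method <- match.arg(method)
  if (any(!is.finite(qt)) || any(!is.finite(rr)) || any(qt <= 0) ||
      any(rr <= 0))
    stop("qt and rr must be positive", call. = FALSE)
  if (method == "bazett") qt / sqrt(rr) else qt / rr^(1 / 3)
}
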