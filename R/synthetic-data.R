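# Seeded generators for every input the analysis pipeline consumes:
# paced EHT force traces, action-potential traces, force-pCa ladders,
# striated images with controlled Z-band registration jitter, and QT/RR
# tables. Each generator returns machine-readable ground truth so every
# analysis stage has a closed-loop round-trip test.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for synthetic EHT force traces
#'
#' The defaults emulate a control EHT paced at 1 Hz: peak force 0.15 mN,
#' contraction time T1_80 of 120 ms, relaxation time T2_80 of 200 ms,
#' sampled at 1 kHz with additive Gaussian noise.
#'
#' @param amplitude_mN peak force above baseline (mN).
#' @param t1_ms programmed contraction time T1_80 (ms).
#' @param t2_ms programmed relaxation time T2_80 (ms).
#' @param pacing_hz pacing frequency (Hz).
#' @param duration_s trace duration (s).
#' @param noise_sd additive Gaussian noise SD (mN).
#' @param baseline_mN resting force (mN).
#' @param dt_ms sampling interval (ms).
#' @param seed integer seed.
#' @return List of class \code{force_config}.
#' @export
force_config <- function(amplitude_mN = 0.15, t1_ms = 120, t2_ms = 200,
                         pacing_hz = 1, duration_s = 10,
                         noise_sd = 0.003, baseline_mN = 0.02,
                         dt_ms = 1, seed = 1) {
  stopifnot(amplitude_mN > 0, t1_ms > 0, t2_ms > 0, pacing_hz > 0,
            duration_s > 0, noise_sd >= 0, dt_ms > 0)
  structure(list(amplitude_mN = amplitude_mN, t1_ms = t1_ms,
                 t2_ms = t2_ms, pacing_hz = pacing_hz,
                 duration_s = duration_s, noise_sd = noise_sd,
                 baseline_mN = baseline_mN, dt_ms = dt_ms, seed = seed),
            class = "force_config")
}

# Log-normal pulse with exactly invertible T1_80/T2_80 (asymmetric) or a
# Gaussian bump (symmetric limit). Returns a function of time (ms since
# beat onset, peak at `delay + tp`).
.pulse_shape <- function(amplitude, t1, t2, delay = 10) {
  stopifnot(t1 > 0, t2 > 0)
  kln5 <- sqrt(2 * log(5))
  if (abs(t2 - t1) < 1e-9) {
    s <- t1 / kln5
    tp <- delay + 3 * s
    list(f = function(t) amplitude * exp(-(t - tp)^2 / (2 * s^2)),
         peak_ms = tp,
         support_ms = tp + s * sqrt(2 * log(100)))
  } else {
    if (t2 < t1)
      stop("log-normal pulse needs t2 >= t1", call. = FALSE)
    k <- log(t2 / t1)
    sigma <- k / kln5
    tp0 <- t1 * t2 / (t2 - t1)
    list(f = function(t) {
      tt <- t - delay
      out <- numeric(length(tt))
      pos <- tt > 0
      out[pos] <- amplitude *
        exp(-(log(tt[pos] / tp0))^2 / (2 * sigma^2))
      out
    },
    peak_ms = delay + tp0,
    support_ms = delay + tp0 * exp(sigma * sqrt(2 * log(100))))
  }
}

#' Generate a paced EHT force trace with known ground truth
#'
#' Beats are identical log-normal-shaped pulses whose shape parameters
#' are chosen so the programmed T1_80 and T2_80 are exact in the
#' noiseless limit, superposed on a constant baseline with additive
#' Gaussian noise.
#'
#' @param cfg a \code{\link{force_config}}.
#' @return List with \code{trace} (an \code{\link{as_trace}} force
#'   trace) and \code{truth} (list: amplitude_mN, T1_80_ms, T2_80_ms,
#'   baseline_mN, peak_times_ms).
#' @export
gen_force_trace <- function(cfg = force_config()) {
  stopifnot(inherits(cfg, "force_config"))
  period <- 1000 / cfg$pacing_hz
  shape <- .pulse_shape(cfg$amplitude_mN, cfg$t1_ms, cfg$t2_ms)
  if (shape$support_ms > period)
    stop("pulse support (", round(shape$support_ms), " ms) exceeds the ",
         "pacing period (", round(period), " ms): beats would overlap",
         call. = FALSE)
  tt <- seq(0, cfg$duration_s * 1000, by = cfg$dt_ms)
  onsets <- seq(0, cfg$duration_s * 1000 - period, by = period)
  v <- rep(cfg$baseline_mN, length(tt))
  for (on in onsets) v <- v + shape$f(tt - on)
  if (cfg$noise_sd > 0)
    v <- v + .with_seed(cfg$seed, stats::rnorm(length(v), 0,
                                               cfg$noise_sd))
  list(trace = as_trace(tt, v, channel = "force", units = "mN",
                        pacing_ms = onsets),
       truth = list(amplitude_mN = cfg$amplitude_mN,
                    T1_80_ms = cfg$t1_ms, T2_80_ms = cfg$t2_ms,
                    baseline_mN = cfg$baseline_mN,
                    peak_times_ms = onsets + shape$peak_ms))
}

#' Configuration for synthetic action-potential traces
#'
#' Defaults reproduce the control EHT phenotype: take-off potential
#' -76.1 mV, amplitude 100.9 mV, APD50 154.9 ms, APD90 242.2 ms at 1-Hz
#' pacing.
#'
#' @param top_mV take-off potential (mV).
#' @param apa_mV action-potential amplitude (mV).
#' @param apd50_ms,apd90_ms programmed AP durations (ms);
#'   \code{apd90_ms > apd50_ms > 0}.
#' @param pacing_hz pacing frequency (Hz).
#' @param n_beats number of beats.
#' @param noise_sd additive Gaussian noise SD (mV).
#' @param dt_ms sampling interval (ms).
#' @param seed integer seed.
#' @return List of class \code{ap_config}.
#' @export
ap_config <- function(top_mV = -76.1, apa_mV = 100.9, apd50_ms = 154.9,
                      apd90_ms = 242.2, pacing_hz = 1, n_beats = 3,
                      noise_sd = 0, dt_ms = 0.5, seed = 1) {
  stopifnot(apa_mV > 0, apd50_ms > 0, apd90_ms > apd50_ms,
            pacing_hz > 0, n_beats >= 1, noise_sd >= 0, dt_ms > 0)
  structure(list(top_mV = top_mV, apa_mV = apa_mV, apd50_ms = apd50_ms,
                 apd90_ms = apd90_ms, pacing_hz = pacing_hz,
                 n_beats = n_beats, noise_sd = noise_sd, dt_ms = dt_ms,
                 seed = seed),
            class = "ap_config")
}

# Solve the normalized-logistic repolarization shape g(t) = r(t)/r(0),
# r(t) = 1/(1+exp((t-c)/s)), such that g(T50) = 0.5 and g(T90) = 0.1
# exactly. One-dimensional root in a = exp(-c/s).
.ap_repol_shape <- function(t50, t90) {
  f <- function(a) {
    s <- t50 / log((1 + 2 * a) / a)
    (t90 - t50) / s - log((9 + 10 * a) / (1 + 2 * a))
  }
  a <- stats::uniroot(f, c(1e-12, 1e6), tol = 1e-14)$root
  s <- t50 / log((1 + 2 * a) / a)
  c0 <- -s * log(a)
  r0 <- 1 / (1 + a)
  function(t) (1 / (1 + exp((t - c0) / s))) / r0
}

#' Generate an action-potential trace with known ground truth
#'
#' Each beat jumps from the take-off potential to the peak within one
#' sample and repolarizes along a normalized logistic whose parameters
#' are solved so the programmed APD50 and APD90 are exact (threshold
#' crossings at TOP + (1 - x/100) * APA).
#'
#' @param cfg an \code{\link{ap_config}}.
#' @return List with \code{trace} (voltage \code{\link{as_trace}}) and
#'   \code{truth} (TOP_mV, APA_mV, APD50_ms, APD90_ms, takeoff_times_ms).
#' @export
gen_ap_trace <- function(cfg = ap_config()) {
  stopifnot(inherits(cfg, "ap_config"))
  period <- 1000 / cfg$pacing_hz
  if (cfg$apd90_ms > 0.9 * period)
    stop("APD90 too long for the pacing period", call. = FALSE)
  g <- .ap_repol_shape(cfg$apd50_ms, cfg$apd90_ms)
  t_on <- 20   # take-off time within each beat (ms)
  tt <- seq(0, cfg$n_beats * period, by = cfg$dt_ms)
  v <- rep(cfg$top_mV, length(tt))
  onsets <- seq(0, (cfg$n_beats - 1) * period, by = period)
  for (on in onsets) {
    rel <- tt - (on + t_on)
    # the take-off sample itself stays at TOP (rel = 0 is the last
    # diastolic sample; durations are anchored there)
    idx <- rel > 0 & rel <= period - t_on - 1
    v[idx] <- cfg$top_mV + cfg$apa_mV * pmax(g(rel[idx]), 0)
  }
  if (cfg$noise_sd > 0)
    v <- v + .with_seed(cfg$seed, stats::rnorm(length(v), 0,
                                               cfg$noise_sd))
  list(trace = as_trace(tt, v, channel = "ap", units = "mV",
                        pacing_ms = onsets),
       truth = list(TOP_mV = cfg$top_mV, APA_mV = cfg$apa_mV,
                    APD50_ms = cfg$apd50_ms, APD90_ms = cfg$apd90_ms,
                    takeoff_times_ms = onsets + t_on))
}

#' Configuration for synthetic force-pCa ladders
#'
#' @param fmax maximal force (mN).
#' @param pca50 myofilament Ca2+ sensitivity (pCa units).
#' @param nh Hill coefficient.
#' @param pca_grid pCa measurement points.
#' @param noise_sd Gaussian noise SD as a fraction of \code{fmax}.
#' @param seed integer seed.
#' @return List of class \code{pca_config}.
#' @export
pca_config <- function(fmax = 1, pca50 = 5.6, nh = 2,
                       pca_grid = seq(6.5, 4.5, by = -0.25),
                       noise_sd = 0.02, seed = 1) {
  stopifnot(fmax > 0, nh > 0, noise_sd >= 0, length(pca_grid) >= 4)
  structure(list(fmax = fmax, pca50 = pca50, nh = nh,
                 pca_grid = pca_grid, noise_sd = noise_sd, seed = seed),
            class = "pca_config")
}

#' Generate a force-pCa dataset with known parameters
#'
#' @param cfg a \code{\link{pca_config}}.
#' @return List with \code{data} (a \code{\link{force_pca_dataset}}) and
#'   \code{truth} (Fmax, pCa50, nH).
#' @export
gen_force_pca <- function(cfg = pca_config()) {
  stopifnot(inherits(cfg, "pca_config"))
  f <- .hill_pca(cfg$pca_grid, cfg$fmax, cfg$pca50, cfg$nh)
  if (cfg$noise_sd > 0)
    f <- f + .with_seed(cfg$seed,
                        stats::rnorm(length(f), 0,
                                     cfg$noise_sd * cfg$fmax))
  f <- pmax(f, 0)
  list(data = force_pca_dataset(cfg$pca_grid, f),
       truth = list(Fmax = cfg$fmax, pCa50 = cfg$pca50, nH = cfg$nh))
}

#' Configuration for synthetic striated images
#'
#' The generator renders parallel myofibrils (bands) crossed by Z-band
#' ridges at a regular sarcomere period; each Z band of each myofibril
#' is displaced longitudinally by independent Gaussian jitter with SD
#' \code{jitter_sd_um / sqrt(2)}, so that the expected SD of paired
#' Z-band offsets between two distinct myofibrils equals
#' \code{jitter_sd_um} -- the generator's ground truth for the disarray
#' index.
#'
#' @param period_um sarcomere period (um).
#' @param jitter_sd_um ground-truth disarray (um; SD of paired offsets).
#' @param orientation_deg myofibril axis direction (degrees).
#' @param size_px image edge (pixels, square).
#' @param pixel_size_um um per pixel.
#' @param myofibril_width_um band width (um).
#' @param ridge_sd_um Gaussian width of each Z-band ridge (um).
#' @param noise_sd additive intensity noise SD (intensity units; signal
#'   amplitude is 0.6 over a 0.3 background).
#' @param seed integer seed.
#' @return List of class \code{image_config}.
#' @export
image_config <- function(period_um = 2, jitter_sd_um = 0,
                         orientation_deg = 0, size_px = 256,
                         pixel_size_um = 0.1, myofibril_width_um = 1.5,
                         ridge_sd_um = 0.3, noise_sd = 0, seed = 1) {
  stopifnot(period_um > 0, jitter_sd_um >= 0, size_px >= 64,
            pixel_size_um > 0, noise_sd >= 0)
  structure(list(period_um = period_um, jitter_sd_um = jitter_sd_um,
                 orientation_deg = orientation_deg, size_px = size_px,
                 pixel_size_um = pixel_size_um,
                 myofibril_width_um = myofibril_width_um,
                 ridge_sd_um = ridge_sd_um, noise_sd = noise_sd,
                 seed = seed),
            class = "image_config")
}

#' Generate a striated sarcomere image with controlled disarray
#'
#' @param cfg an \code{\link{image_config}}.
#' @return List with \code{image} (a \code{\link{sarcomere_image}}),
#'   \code{rois} (default ROI placement aligned with the myofibril
#'   axis), and \code{truth} (jitter_sd_um, period_um).
#' @export
gen_sarcomere_image <- function(cfg = image_config()) {
  stopifnot(inherits(cfg, "image_config"))
  n <- cfg$size_px
  px <- cfg$pixel_size_um
  field <- (n - 1) * px
  th <- cfg$orientation_deg * pi / 180
  # pixel-center coordinates (um)
  xs <- (seq_len(n) - 1) * px
  X <- matrix(rep(xs, each = n), n, n)       # column-wise x
  Y <- matrix(rep(xs, times = n), n, n)      # row-wise y
  # u along the myofibril axis, v across (band index)
  U <- X * cos(th) + Y * sin(th)
  V <- -X * sin(th) + Y * cos(th)

  # orientation-independent lattice indexing so a fixed seed yields the
  # same disarray field at any rotation (equivariance by construction)
  band0 <- floor(-1.5 * field / cfg$myofibril_width_um) - 1
  n_bands <- ceiling(1.5 * field / cfg$myofibril_width_um) - band0 + 2
  z0 <- floor(-1.5 * field / cfg$period_um) - 1
  n_z <- ceiling(1.5 * field / cfg$period_um) - z0 + 2

  jit <- .with_seed(cfg$seed, matrix(
    stats::rnorm(n_bands * n_z, 0, cfg$jitter_sd_um / sqrt(2)),
    n_bands, n_z))

  band <- pmin(pmax(floor(V / cfg$myofibril_width_um) - band0 + 1L, 1L),
               n_bands)
  img <- matrix(0.3, n, n)
  amp <- 0.6
  for (k in seq_len(n_z)) {
    zpos <- (z0 + k - 1) * cfg$period_um
    centers <- zpos + jit[cbind(as.vector(band), k)]
    d <- as.vector(U) - centers
    img <- img + amp * matrix(exp(-d^2 / (2 * cfg$ridge_sd_um^2)), n, n)
  }
  if (cfg$noise_sd > 0)
    img <- img + .with_seed(cfg$seed + 1L,
                            matrix(stats::rnorm(n * n, 0, cfg$noise_sd),
                                   n, n))
  img <- pmax(img, 0)
  image <- sarcomere_image(img, px, orientation_deg = cfg$orientation_deg)
  rois <- default_rois(image, n = 3, seed = cfg$seed)
  list(image = image, rois = rois,
       truth = list(jitter_sd_um = cfg$jitter_sd_um,
                    period_um = cfg$period_um))
}

#' Configuration for synthetic QT/RR tables
#'
#' @param n number of records.
#' @param qt_mean_ms,qt_sd_ms QT distribution (ms).
#' @param rr_range_s RR uniform range (s).
#' @param seed integer seed.
#' @return List of class \code{qtrr_config}.
#' @export
qtrr_config <- function(n = 20, qt_mean_ms = 400, qt_sd_ms = 20,
                        rr_range_s = c(0.6, 1.2), seed = 1) {
  stopifnot(n >= 1, qt_mean_ms > 0, qt_sd_ms >= 0,
            length(rr_range_s) == 2, all(rr_range_s > 0))
  structure(list(n = n, qt_mean_ms = qt_mean_ms, qt_sd_ms = qt_sd_ms,
                 rr_range_s = rr_range_s, seed = seed),
            class = "qtrr_config")
}

#' Generate a QT/RR table with true corrected values
#'
#' @param cfg a \code{\link{qtrr_config}}.
#' @return Data frame with columns \code{QT_ms}, \code{RR_s},
#'   \code{QTcB_ms}, \code{QTcF_ms} (the last two are the ground truth).
#' @export
gen_qt_rr <- function(cfg = qtrr_config()) {
  stopifnot(inherits(cfg, "qtrr_config"))
  .with_seed(cfg$seed, {
    qt <- abs(stats::rnorm(cfg$n, cfg$qt_mean_ms, cfg$qt_sd_ms))
    rr <- stats::runif(cfg$n, cfg$rr_range_s[1], cfg$rr_range_s[2])
    data.frame(QT_ms = qt, RR_s = rr,
               QTcB_ms = qt / sqrt(rr), QTcF_ms = qt / rr^(1 / 3))
  })
}
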