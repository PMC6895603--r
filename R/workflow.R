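# Configuration-driven orchestration of the package's computational
# experiments: the control-vs-1.5x-I_CaL simulation, the diltiazem
# emergent-prediction protocol, and the synthetic-data validation suite.

#' Run a named computational experiment
#'
#' Three experiments are available:
#' \describe{
#'   \item{\code{"hcm_vs_ctrl"}}{Paces the control and 1.5x-g_CaL presets
#'     to steady state at each requested frequency and tabulates APD50,
#'     APD90, force amplitude and T2_80.}
#'   \item{\code{"diltiazem"}}{Calibrates a fractional L-type block so
#'     the control model's force amplitude falls by the configured
#'     fraction (default 11 percent), applies the identical fraction to
#'     the 1.5x-g_CaL preset, and reports percent changes in force and
#'     relaxation for both presets.}
#'   \item{\code{"synthetic_validation"}}{Runs every synthetic-data
#'     generator round trip (force trace, AP trace, force-pCa, striated
#'     image, QT/RR) and reports recovered versus programmed values.}
#' }
#'
#' @param config named list (or path to a JSON/YAML file readable by
#'   \code{\link{read_run_config}}) with fields \code{experiment},
#'   optional \code{seed}, \code{frequencies_hz}, \code{beats},
#'   \code{target_force_change}, \code{out_dir} (write CSV/JSON
#'   artifacts there when set).
#' @return Object of class \code{eht_report}: list with \code{experiment},
#'   \code{tables} (named list of data frames), \code{seed}, and
#'   \code{provenance}.
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- read_run_config(config)
  if (is.null(config$experiment))
    stop("config$experiment is required", call. = FALSE)
  known <- c("hcm_vs_ctrl", "diltiazem", "synthetic_validation")
  if (!config$experiment %in% known)
    stop("unknown experiment '", config$experiment, "' (expected one of ",
         paste(known, collapse = ", "), ")", call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  tables <- switch(config$experiment,
    hcm_vs_ctrl = .exp_hcm_vs_ctrl(config),
    diltiazem = .exp_diltiazem(config),
    synthetic_validation = .exp_synthetic(config, seed))

  report <- structure(
    list(experiment = config$experiment, tables = tables, seed = seed,
         provenance = list(
           package_version = as.character(utils::packageVersion("ehtkit")),
           config = config[setdiff(names(config), "out_dir")])),
    class = "eht_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables))
      utils::write.csv(tables[[nm]],
                       file.path(config$out_dir,
                                 paste0(config$experiment, "_", nm,
                                        ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(
      list(experiment = report$experiment, seed = report$seed,
           tables = tables, provenance = report$provenance),
      file.path(config$out_dir,
                paste0(config$experiment, "_report.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

.exp_hcm_vs_ctrl <- function(config) {
  freqs <- if (is.null(config$frequencies_hz)) c(1, 2, 3)
           else as.numeric(config$frequencies_hz)
  beats <- if (is.null(config$beats)) 300L else as.integer(config$beats)
  proto <- pacing_protocol(beats = beats)
  rows <- list()
  for (preset in c("control", "hcm_1p5x_ical")) {
    p <- cm_parameters(preset)
    tab <- rate_dependence(p, freqs, protocol = proto)
    tab$preset <- preset
    rows[[preset]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(rate_dependence = out)
}

.exp_diltiazem <- function(config) {
  target <- if (is.null(config$target_force_change)) -0.11
            else as.numeric(config$target_force_change)
  beats <- if (is.null(config$beats)) 300L else as.integer(config$beats)
  proto <- pacing_protocol(beats = beats)
  res <- diltiazem_protocol(target_force_change = target,
                            protocol = proto)
  list(diltiazem = res$table,
       block = data.frame(component = "ICaL",
                          fraction = res$block$fraction,
                          target_force_change = target))
}

.exp_synthetic <- function(config, seed) {
  ft <- gen_force_trace(force_config(seed = seed))
  cf <- contraction_features(ft$trace)
  at <- gen_ap_trace(ap_config(seed = seed))
  af <- ap_features(at$trace)
  pc <- gen_force_pca(pca_config(seed = seed))
  hf <- hill_fit(pc$data)
  im <- gen_sarcomere_image(image_config(jitter_sd_um = 0.2,
                                         noise_sd = 0.02, seed = seed))
  dz <- disarray_index(im$image, im$rois)
  qt <- gen_qt_rr(qtrr_config(seed = seed))
  chk <- function(stage, quantity, truth, recovered)
    data.frame(stage = stage, quantity = quantity, truth = truth,
               recovered = recovered)
  tab <- rbind(
    chk("force_trace", "amplitude_mN", ft$truth$amplitude_mN,
        cf$amplitude_mN),
    chk("force_trace", "T1_80_ms", ft$truth$T1_80_ms, cf$T1_80_ms),
    chk("force_trace", "T2_80_ms", ft$truth$T2_80_ms, cf$T2_80_ms),
    chk("ap_trace", "APD50_ms", at$truth$APD50_ms, af$APD50_ms),
    chk("ap_trace", "APD90_ms", at$truth$APD90_ms, af$APD90_ms),
    chk("ap_trace", "TOP_mV", at$truth$TOP_mV, af$TOP_mV),
    chk("force_pca", "pCa50", pc$truth$pCa50, hf$pCa50),
    chk("force_pca", "nH", pc$truth$nH, hf$nH),
    chk("disarray", "jitter_sd_um", im$truth$jitter_sd_um, dz$index_um),
    chk("qt_rr", "QTcB_ms_mean", mean(qt$QTcB_ms),
        mean(qtc(qt$QT_ms, qt$RR_s, "bazett"))))
  list(validation = tab)
}

#' Diltiazem emergent-prediction protocol
#'
#' Calibrates a pure fractional L-type Ca2+ block on the control preset
#' so its steady-state force amplitude falls by \code{target_force_change}
#' (the measured control response to 3 uM diltiazem), then applies the
#' identical fraction to the 1.5x-g_CaL preset. Because the calibration
#' never sees the HCM-like preset, its force, relaxation and APD
#' responses are emergent predictions.
#'
#' @param target_force_change signed fractional force change used for
#'   calibration (default -0.11).
#' @param protocol a \code{\link{pacing_protocol}}.
#' @return List with \code{block} (the calibrated \code{block_spec}) and
#'   \code{table}: one row per preset with baseline and blocked force
#'   amplitude, T2_80 and APD90 plus their percent changes.
#' @export
diltiazem_protocol <- function(target_force_change = -0.11,
                               protocol = pacing_protocol()) {
  ctrl <- cm_parameters("control")
  hcm <- cm_parameters("hcm_1p5x_ical")
  blk <- calibrate_block(ctrl, "force_amplitude", target_force_change,
                         protocol = protocol)
  rows <- lapply(list(control = ctrl, hcm_1p5x_ical = hcm),
                 function(p) {
    base <- pace_to_steady_state(p, protocol)
    trt <- pace_to_steady_state(apply_block(p, blk), protocol,
                                init = base$state)
    cb <- base$features$contraction; ct <- trt$features$contraction
    ab <- base$features$ap; at <- trt$features$ap
    data.frame(
      force_baseline_mN = cb$amplitude_mN,
      force_blocked_mN = ct$amplitude_mN,
      force_change_pct = percent_change(cb$amplitude_mN,
                                        ct$amplitude_mN),
      T2_baseline_ms = cb$T2_80_ms,
      T2_blocked_ms = ct$T2_80_ms,
      T2_change_pct = percent_change(cb$T2_80_ms, ct$T2_80_ms),
      APD90_baseline_ms = ab$APD90_ms,
      APD90_blocked_ms = at$APD90_ms,
      APD90_change_pct = percent_change(ab$APD90_ms, at$APD90_ms))
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(preset = names(rows), tab)
  rownames(tab) <- NULL
  list(block = blk, table = tab)
}

#' @export
print.eht_report <- function(x, ...) {
  cat("<eht_report>", x$experiment, "(seed", x$seed, ")\n")
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    print(x$tables[[nm]], row.names = FALSE, digits = 4)
  }
  invisible(x)
}
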