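#' Sarcomere striation image container
#'
#' A grayscale alpha-actinin-stained image as an intensity matrix with a
#' physical pixel size. Rows index y, columns x; intensities must be
#' finite and nonnegative.
#'
#' @param intensity numeric matrix of intensities.
#' @param pixel_size_um pixel edge length (micrometers per pixel).
#' @param orientation_deg optional stated myofibril orientation (degrees;
#'   0 = striations normal to the x axis).
#' @return Object of class \code{sarcomere_image}.
#' @export
sarcomere_image <- function(intensity, pixel_size_um,
                            orientation_deg = NA_real_) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and nonnegative", call. = FALSE)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel size must be > 0", call. = FALSE)
  structure(list(intensity = intensity, pixel_size_um = pixel_size_um,
                 orientation_deg = orientation_deg),
            class = "sarcomere_image")
}

#' Read a sarcomere image from TIFF or PNG
#'
#' @param path file path (.tif/.tiff/.png).
#' @param pixel_size_um pixel size (micrometers per pixel).
#' @return A \code{\link{sarcomere_image}} (first channel if RGB).
#' @export
read_sarcomere_image <- function(path, pixel_size_um) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  sarcomere_image(img, pixel_size_um)
}

#' @export
print.sarcomere_image <- function(x, ...) {
  cat("<sarcomere_image>", nrow(x$intensity), "x", ncol(x$intensity),
      "px at", x$pixel_size_um, "um/px\n")
  invisible(x)
}

#' Region-of-interest specification for disarray analysis
#'
#' Two parallel measurement lines perpendicular to the striation
#' alignment: each of length about 10 um (spanning roughly 6 sarcomere
#' intervals), separated laterally by 5-10 um.
#'
#' @param center_um ROI center (x, y) in micrometers.
#' @param length_um line length (um).
#' @param separation_um lateral separation between the two lines (um).
#' @param angle_deg direction of the lines in degrees (0 = along +x);
#'   lines should run perpendicular to the striations.
#' @return Object of class \code{roi_spec}.
#' @export
roi_spec <- function(center_um, length_um = 10, separation_um = 6,
                     angle_deg = 0) {
  stopifnot(length(center_um) == 2, length_um > 0, separation_um > 0)
  structure(list(center_um = as.numeric(center_um),
                 length_um = length_um, separation_um = separation_um,
                 angle_deg = angle_deg),
            class = "roi_spec")
}

# Bilinear interpolation of image intensity at (x, y) in um coordinates.
# x runs along columns, y along rows; (0, 0) is the pixel-(1,1) center.
.bilinear <- function(img, x_um, y_um, px) {
  xi <- x_um / px + 1
  yi <- y_um / px + 1
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  nr <- nrow(img); nc <- ncol(img)
  x0 <- pmin(pmax(x0, 1), nc - 1)
  y0 <- pmin(pmax(y0, 1), nr - 1)
  v00 <- img[cbind(y0, x0)]
  v01 <- img[cbind(y0, x0 + 1)]
  v10 <- img[cbind(y0 + 1, x0)]
  v11 <- img[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
}

# Endpoints of the two parallel lines of an ROI.
.roi_lines <- function(roi) {
  th <- roi$angle_deg * pi / 180
  u <- c(cos(th), sin(th))              # along the line
  v <- c(-sin(th), cos(th))             # lateral (line separation)
  h <- roi$length_um / 2
  s <- roi$separation_um / 2
  list(line1 = list(p0 = roi$center_um - h * u + s * v, u = u,
                    len = roi$length_um),
       line2 = list(p0 = roi$center_um - h * u - s * v, u = u,
                    len = roi$length_um))
}

#' Striation intersections along a measurement line
#'
#' Samples the image intensity along one ROI line (bilinear
#' interpolation, 0.05-um steps) and returns the positions of the Z-band
#' intensity maxima along the line, refined to sub-pixel precision by
#' parabolic interpolation around each peak.
#'
#' @param image a \code{\link{sarcomere_image}}.
#' @param line list with \code{p0} (start point, um) and \code{u} (unit
#'   direction) and \code{len} (length, um), as produced internally from
#'   an \code{\link{roi_spec}}; alternatively an \code{roi_spec}, in
#'   which case its first line is used.
#' @param min_prominence peak prominence threshold as a fraction of the
#'   profile's intensity range.
#' @return Numeric vector of intersection positions (um along the line);
#'   an error if fewer than 4 are found.
#' @export
striation_intersections <- function(image, line,
                                    min_prominence = 0.1) {
  stopifnot(inherits(image, "sarcomere_image"))
  if (inherits(line, "roi_spec")) line <- .roi_lines(line)$line1
  step <- 0.05
  s <- seq(0, line$len, by = step)
  xs <- line$p0[1] + s * line$u[1]
  ys <- line$p0[2] + s * line$u[2]
  px <- image$pixel_size_um
  nr <- nrow(image$intensity); nc <- ncol(image$intensity)
  if (any(xs < 0) || any(ys < 0) || any(xs > (nc - 1) * px) ||
      any(ys > (nr - 1) * px))
    stop("line extends outside the image", call. = FALSE)
  prof <- .bilinear(image$intensity, xs, ys, px)
  # light smoothing (0.45-um boxcar) against pixel noise before peak
  # detection; sub-pixel refinement operates on the smoothed profile
  kw <- 9L
  kern <- rep(1 / kw, kw)
  prof <- stats::filter(prof, kern, sides = 2)
  keep_idx <- !is.na(prof)
  prof <- as.numeric(prof[keep_idx])
  s <- s[keep_idx]

  rng <- diff(range(prof))
  if (rng <= 0) stop("flat intensity profile", call. = FALSE)
  thr <- min_prominence * rng
  n <- length(prof)
  peaks <- which(diff(sign(diff(prof))) < 0) + 1L
  # prominence: height above the higher of the two flanking minima
  keep <- vapply(peaks, function(i) {
    lmin <- min(prof[max(1, i - 40):i])
    rmin <- min(prof[i:min(n, i + 40)])
    (prof[i] - max(lmin, rmin)) >= thr
  }, logical(1))
  peaks <- peaks[keep]
  if (length(peaks) < 4)
    stop("fewer than 4 striation intersections detected", call. = FALSE)
  # sub-pixel parabolic refinement
  pos <- vapply(peaks, function(i) {
    if (i <= 1 || i >= n) return(s[i])
    y1 <- prof[i - 1]; y2 <- prof[i]; y3 <- prof[i + 1]
    den <- y1 - 2 * y2 + y3
    d <- if (abs(den) < 1e-12) 0 else 0.5 * (y1 - y3) / den
    s[i] + d * step
  }, numeric(1))
  sort(pos)
}

# Pair k-th intersections of two lines by nearest neighbor within half a
# median spacing; returns matrix of paired positions.
.pair_intersections <- function(a, b) {
  if (length(a) == length(b)) {
    # aligned counts: pair in order
    return(cbind(a, b))
  }
  spacing <- stats::median(diff(a))
  tol <- spacing / 2
  used <- rep(FALSE, length(b))
  pairs <- NULL
  for (x in a) {
    d <- abs(b - x)
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol) {
      pairs <- rbind(pairs, c(x, b[j]))
      used[j] <- TRUE
    }
  }
  pairs
}

#' Myofibrillar disarray index
#'
#' For each ROI, the k-th striation intersections of the two parallel
#' lines are paired and the longitudinal offset of each pair computed;
#' the ROI's disarray is the standard deviation of these offsets
#' (Z-band registration disorder between neighboring myofibrils), and
#' the image's index is the mean of the per-ROI standard deviations, in
#' micrometers. A perfectly registered striation lattice gives an index
#' near zero. The within-line spacing SD is reported as a secondary
#' metric (\code{spacing_sd_um}).
#'
#' @param image a \code{\link{sarcomere_image}}.
#' @param rois list of \code{\link{roi_spec}} objects (default
#'   placement: see \code{\link{default_rois}}).
#' @return Object of class \code{disarray_result}: list with
#'   \code{index_um}, \code{per_roi} (data frame: offset SD, n pairs,
#'   accepted flag and reason), \code{spacing_sd_um},
#'   \code{intersections} (per-ROI list of paired positions).
#' @examples
#' img <- gen_sarcomere_image(image_config(jitter_sd_um = 0))
#' disarray_index(img$image, img$rois)$index_um
#' @export
disarray_index <- function(image, rois) {
  stopifnot(inherits(image, "sarcomere_image"))
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  per <- lapply(seq_along(rois), function(k) {
    roi <- rois[[k]]
    ln <- .roi_lines(roi)
    res <- tryCatch({
      a <- striation_intersections(image, ln$line1)
      b <- striation_intersections(image, ln$line2)
      pairs <- .pair_intersections(a, b)
      if (is.null(pairs) || nrow(pairs) < 4)
        stop("fewer than 4 matched pairs")
      offs <- pairs[, 1] - pairs[, 2]
      list(sd = stats::sd(offs), n = nrow(pairs),
           spacing_sd = stats::sd(c(diff(pairs[, 1]), diff(pairs[, 2]))),
           pairs = pairs, ok = TRUE, reason = "")
    }, error = function(e)
      list(sd = NA_real_, n = 0L, spacing_sd = NA_real_, pairs = NULL,
           ok = FALSE, reason = conditionMessage(e)))
    res
  })
  ok <- vapply(per, `[[`, logical(1), "ok")
  if (!any(ok))
    stop("all ROIs rejected: ",
         paste(unique(vapply(per, `[[`, character(1), "reason")),
               collapse = "; "), call. = FALSE)
  idx <- mean(vapply(per[ok], `[[`, numeric(1), "sd"))
  structure(list(
    index_um = idx,
    spacing_sd_um = mean(vapply(per[ok], `[[`, numeric(1), "spacing_sd")),
    per_roi = data.frame(
      roi = seq_along(rois),
      offset_sd_um = vapply(per, `[[`, numeric(1), "sd"),
      n_pairs = vapply(per, `[[`, integer(1), "n"),
      accepted = ok,
      reason = vapply(per, `[[`, character(1), "reason")),
    intersections = lapply(per, `[[`, "pairs")),
    class = "disarray_result")
}

#' @export
print.disarray_result <- function(x, ...) {
  cat(sprintf("<disarray_result> index %.4f um over %d/%d ROIs (spacing SD %.4f um)\n",
              x$index_um, sum(x$per_roi$accepted), nrow(x$per_roi),
              x$spacing_sd_um))
  invisible(x)
}

#' Default random ROI placement
#'
#' Places \code{n} ROIs (default 3, mirroring the three randomly chosen
#' regions per cell) at seeded-random centers within the image, leaving a
#' margin for the line geometry, with lines perpendicular to the stated
#' striation orientation.
#'
#' @param image a \code{\link{sarcomere_image}}.
#' @param n number of ROIs.
#' @param seed integer seed for reproducible placement.
#' @param length_um,separation_um line geometry (um).
#' @return List of \code{\link{roi_spec}}.
#' @export
default_rois <- function(image, n = 3, seed = 1, length_um = 10,
                         separation_um = 6) {
  stopifnot(inherits(image, "sarcomere_image"))
  angle <- if (is.finite(image$orientation_deg))
    image$orientation_deg else 0
  px <- image$pixel_size_um
  w <- (ncol(image$intensity) - 1) * px
  h <- (nrow(image$intensity) - 1) * px
  margin <- (length_um + separation_um) / 2 + 2 * px
  if (w <= 2 * margin || h <= 2 * margin)
    stop("image too small for ROI geometry", call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n), function(i)
    roi_spec(center_um = c(stats::runif(1, margin, w - margin),
                           stats::runif(1, margin, h - margin)),
             length_um = length_um, separation_um = separation_um,
             angle_deg = angle))
}
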