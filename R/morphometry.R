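# Morphometry of projected fluorescence images.
#
# Implements the quantification rules used on maximum-intensity
# projections: segment bright structures, measure the sub-pixel outline
# perimeter (half of which is the isolation-membrane size), fit ellipse
# axes (the major axis of rings/puncta is the opening size), and record
# ROI intensities.  The manual exclusion of non-IM signals is replaced by
# a deterministic area/circularity filter with recorded settings.
#
# Conventions: pixel indices are 0-based with intensities at pixel
# centres; outlines are sub-pixel iso-contours of the smoothed image at
# the threshold level.

#' Segmentation settings for projected images
#'
#' @param smoothing_sigma Gaussian smoothing sigma in pixels before
#'   thresholding. Default 0.5.
#' @param threshold_method `"otsu"` (histogram-based, default) or
#'   `"fixed"`.
#' @param fixed_threshold Threshold level (counts) for
#'   `threshold_method = "fixed"`.
#' @param min_area Minimum component area, pixels. Default 9.
#' @param circularity_bounds Components whose outline circularity
#'   \eqn{4\pi A/P^2} falls outside this interval are excluded
#'   (the automated replacement of manual signal exclusion).
#' @param dilation_radius_for_roi Radius (pixels) by which component
#'   pixels are dilated to form the intensity ROI.
#' @param peak_snr_margin Components are kept only if their peak smoothed
#'   intensity exceeds the expected maximum of pure background noise,
#'   `median + MAD * (sqrt(2 log N) + peak_snr_margin)` for an N-pixel
#'   image (an extreme-value bound), so noise-only images segment to an
#'   empty labelling. Default margin 2; set to a negative large value to
#'   disable.
#' @param punctum_max_axis Largest major axis (nm) still classified as a
#'   punctum; filled structures above it (and not elongated) are `other`.
#' @param tubule_elongation Axis ratio at and above which a filled
#'   component is classified as a tubule.
#' @param psf_sigma Lateral Gaussian blur sigma of the imaging system, nm
#'   (default 100).  Used only for the sub-resolution punctum size
#'   estimate: a punctum is modelled as a small ring whose
#'   intensity-weighted radial variance per axis is \eqn{\rho^2/2} plus
#'   the blur variance, so its diameter is recovered as
#'   \eqn{2\sqrt{2(\lambda - \sigma^2)}} from the measured second moment
#'   \eqn{\lambda}.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(smoothing_sigma = 0.5,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area = 9,
                                circularity_bounds = c(0, 1),
                                dilation_radius_for_roi = 2,
                                peak_snr_margin = 2,
                                punctum_max_axis = 700,
                                tubule_elongation = 2,
                                psf_sigma = 100) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(smoothing_sigma >= 0, min_area >= 1,
            length(circularity_bounds) == 2L,
            circularity_bounds[1] <= circularity_bounds[2],
            dilation_radius_for_roi >= 0)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("`fixed_threshold` required for threshold_method = \"fixed\"")
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area = as.integer(min_area),
                 circularity_bounds = circularity_bounds,
                 dilation_radius_for_roi = as.integer(dilation_radius_for_roi),
                 peak_snr_margin = peak_snr_margin,
                 punctum_max_axis = punctum_max_axis,
                 tubule_elongation = tubule_elongation,
                 psf_sigma = psf_sigma),
            class = "segmentation_config")
}

.smooth2d <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  norm_rows <- function(K) K / rowSums(K)
  # renormalised at the borders so constant images stay constant
  Kx <- norm_rows(.gaussian_band(nrow(img), sigma_px))
  Ky <- if (ncol(img) == nrow(img)) Kx
        else norm_rows(.gaussian_band(ncol(img), sigma_px))
  Kx %*% img %*% t(Ky)
}

# Otsu threshold: maximises between-class variance over a 256-bin histogram
.otsu_threshold <- function(img, n_bins = 256L) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(img, br, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  br[which.max(sb) + 1L]
}

# 8-connected labelling by iterative minimum-label propagation
.label_components <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  lab[mask] <- seq_len(sum(mask))
  shift <- function(m, di, dj) {
    out <- matrix(0L, d[1], d[2])
    si <- max(1, 1 + di):min(d[1], d[1] + di)
    sj <- max(1, 1 + dj):min(d[2], d[2] + dj)
    out[si, sj] <- m[si - di, sj - dj]
    out
  }
  repeat {
    new <- lab
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      s <- shift(lab, di, dj)
      upd <- mask & s > 0L & (new == 0L | s < new)
      new[upd] <- s[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Segment bright structures on a projection
#'
#' Smooths the projection, thresholds it (Otsu by default), labels
#' 8-connected components and drops components below `min_area`.  An
#' all-background image yields an empty labelling, not an error.
#'
#' @param projection Matrix of intensities (x by y), e.g. from
#'   [max_intensity_projection()].
#' @param config A [segmentation_config()].
#' @return An object of class `im_segmentation`: list with `labels`
#'   (integer matrix), `threshold`, `smoothed`, `config`.
#' @export
segment_projection <- function(projection, config = segmentation_config()) {
  stopifnot(is.matrix(projection), inherits(config, "segmentation_config"))
  sm <- .smooth2d(projection, config$smoothing_sigma)
  thr <- if (config$threshold_method == "otsu") .otsu_threshold(sm)
         else config$fixed_threshold
  mask <- sm > thr
  lab <- if (any(mask)) .label_components(mask) else
    matrix(0L, nrow(projection), ncol(projection))
  if (any(lab > 0L)) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < config$min_area)
    bg <- stats::median(sm)
    s_bg <- stats::mad(sm)
    if (s_bg > 0) {
      cut <- bg + s_bg * (sqrt(2 * log(length(sm))) + config$peak_snr_margin)
      peaks <- tapply(sm[lab > 0L], lab[lab > 0L], max)
      weak <- as.integer(names(peaks)[peaks < cut])
      drop <- union(drop, weak)
    }
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      ids <- sort(unique(lab[lab > 0L]))
      lab[lab > 0L] <- match(lab[lab > 0L], ids)
    }
  }
  structure(list(labels = lab, threshold = thr, smoothed = sm,
                 config = config),
            class = "im_segmentation")
}

# filled-polygon geometry via Green's theorem; xy is an m x 2 matrix.
# Closed contours from a pixel grid carry staircase wiggle that inflates
# perimeters; a short circular moving average of the vertices removes it
# without affecting features larger than a few pixels.
.poly_geometry <- function(xy, smooth_window = 5L) {
  if (nrow(xy) >= 4L * smooth_window) {
    k <- rep(1 / smooth_window, smooth_window)
    xy <- cbind(stats::filter(xy[, 1], k, circular = TRUE),
                stats::filter(xy[, 2], k, circular = TRUE))
  }
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  per <- sum(sqrt((x2 - x)^2 + (y2 - y)^2))
  if (abs(A) < 1e-9)
    return(list(area = 0, perimeter = per, cx = mean(x), cy = mean(y),
                major = 0, minor = 0))
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  Ixx <- sum((x^2 + x * x2 + x2^2) * cr) / 12
  Iyy <- sum((y^2 + y * y2 + y2^2) * cr) / 12
  Ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  # second central moments of the filled region
  mxx <- Ixx / A - cx^2
  myy <- Iyy / A - cy^2
  mxy <- Ixy / A - cx * cy
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)$values
  ev[ev < 0] <- 0
  list(area = abs(A), perimeter = per, cx = cx, cy = cy,
       major = 4 * sqrt(ev[1]), minor = 4 * sqrt(ev[2]))
}

# assign a contour polygon to the label of an adjacent foreground pixel
.contour_label <- function(poly, labels) {
  n <- nrow(poly)
  probe <- unique(pmin(pmax(cbind(
    round(c(poly[, 1], poly[, 1] + 0.5, poly[, 1] - 0.5)),
    round(c(poly[, 2], poly[, 2] + 0.5, poly[, 2] - 0.5))), 0),
    rep(dim(labels) - 1L, each = 3L * n)))
  lv <- labels[probe + 1L]
  lv <- lv[lv > 0L]
  if (!length(lv)) return(0L)
  as.integer(names(sort(table(lv), decreasing = TRUE))[1L])
}

#' Measure segmented structures
#'
#' For every labelled component, extracts its sub-pixel outline(s) at the
#' threshold level, and measures: the outer outline perimeter (half of
#' which is reported as the isolation-membrane size), ellipse axes from
#' second-order moments of the filled outline (for ring-like components
#' with a hole, the axes of the outer and hole outlines are averaged,
#' which removes the blur widening to first order), and the mean and
#' integrated intensity inside the dilated component ROI.  Components are
#' classified `ring` (hole present), `tubule` (elongation at or above
#' `tubule_elongation`), `punctum` (compact, small) or `other`; components
#' outside the area/circularity filter are excluded.
#'
#' @param segmentation An [segment_projection()] result.
#' @param projection The raw projection the segmentation came from.
#' @param voxel_xy Pixel size in nm (defaults to the projection's
#'   `voxel_xy` attribute, else 65).
#' @return A data frame with one row per retained structure: `label`,
#'   `class`, `area_px`, `perimeter_nm`, `im_size_nm` (= perimeter/2),
#'   `major_axis_nm`, `minor_axis_nm`, `has_hole`, `circularity`,
#'   `centroid_x_px`, `centroid_y_px`, `mean_intensity`,
#'   `integrated_intensity`.
#' @export
measure_structures <- function(segmentation, projection,
                               voxel_xy = NULL) {
  stopifnot(inherits(segmentation, "im_segmentation"),
            is.matrix(projection))
  if (is.null(voxel_xy))
    voxel_xy <- attr(projection, "voxel_xy") %||% 65
  cfg <- segmentation$config
  lab <- segmentation$labels
  nlab <- max(lab)
  empty <- data.frame(label = integer(), class = character(),
                      area_px = numeric(), perimeter_nm = numeric(),
                      im_size_nm = numeric(), major_axis_nm = numeric(),
                      minor_axis_nm = numeric(), has_hole = logical(),
                      circularity = numeric(), centroid_x_px = numeric(),
                      centroid_y_px = numeric(), mean_intensity = numeric(),
                      integrated_intensity = numeric())
  if (nlab == 0L) return(empty)

  bg <- stats::median(projection)
  cl <- grDevices::contourLines(x = seq_len(nrow(projection)) - 1,
                                y = seq_len(ncol(projection)) - 1,
                                z = segmentation$smoothed,
                                levels = segmentation$threshold)
  owner <- integer(length(cl))
  geoms <- vector("list", length(cl))
  for (k in seq_along(cl)) {
    poly <- cbind(cl[[k]]$x, cl[[k]]$y)
    geoms[[k]] <- .poly_geometry(poly)
    owner[k] <- if (geoms[[k]]$area >= 1) .contour_label(poly, lab) else 0L
  }

  rows <- lapply(seq_len(nlab), function(l) {
    pix <- which(lab == l, arr.ind = TRUE)
    npx <- nrow(pix)
    ks <- which(owner == l)
    if (length(ks) == 0L) {
      # degenerate / border-touching component: pixel-level fallback
      g <- list(area = npx,
                perimeter = max(4, 2 * (diff(range(pix[, 1])) +
                                          diff(range(pix[, 2])) + 2)),
                cx = mean(pix[, 1]) - 1, cy = mean(pix[, 2]) - 1,
                major = max(1, diff(range(pix[, 1])) + 1),
                minor = max(1, diff(range(pix[, 2])) + 1))
      if (g$minor > g$major) { tmp <- g$major; g$major <- g$minor; g$minor <- tmp }
      outer <- g; hole <- NULL
    } else {
      areas <- vapply(geoms[ks], `[[`, numeric(1), "area")
      outer <- geoms[[ks[which.max(areas)]]]
      holes <- ks[-which.max(areas)]
      holes <- holes[vapply(geoms[holes], `[[`, numeric(1), "area") >= 2]
      hole <- if (length(holes))
        geoms[[holes[which.max(vapply(geoms[holes], `[[`, numeric(1), "area"))]]]
      else NULL
    }
    has_hole <- !is.null(hole)
    major_px <- if (has_hole) (outer$major + hole$major) / 2 else outer$major
    minor_px <- if (has_hole) (outer$minor + hole$minor) / 2 else outer$minor
    if (has_hole) {
      # the bright band of a blurred thin ring peaks inward of the true
      # radius by sigma^2/(2 rho); undo this first-order ridge shift
      sig_eff2 <- (cfg$psf_sigma / voxel_xy)^2 + cfg$smoothing_sigma^2
      major_px <- major_px + 2 * sig_eff2 / major_px
      minor_px <- minor_px + 2 * sig_eff2 / minor_px
    }
    # sub-resolution filled blobs: blur-corrected intensity-moment size
    # (punctum = unresolved small ring; see segmentation_config docs)
    contour_elong <- if (minor_px > 0) major_px / minor_px else Inf
    if (!has_hole && contour_elong < cfg$tubule_elongation &&
        major_px * voxel_xy <= cfg$punctum_max_axis + 6 * cfg$psf_sigma) {
      win <- ceiling(3 * (cfg$psf_sigma / voxel_xy + cfg$smoothing_sigma))
      i0 <- max(1L, min(pix[, 1]) - win); i1 <- min(nrow(lab), max(pix[, 1]) + win)
      j0 <- max(1L, min(pix[, 2]) - win); j1 <- min(ncol(lab), max(pix[, 2]) + win)
      wimg <- pmax(projection[i0:i1, j0:j1, drop = FALSE] - bg, 0)
      tw <- sum(wimg)
      if (tw > 0) {
        xi <- rep(seq(i0, i1) - 1, times = j1 - j0 + 1L)
        yj <- rep(seq(j0, j1) - 1, each = i1 - i0 + 1L)
        wv <- as.vector(wimg) / tw
        mx <- sum(wv * xi); my <- sum(wv * yj)
        vxx <- sum(wv * (xi - mx)^2); vyy <- sum(wv * (yj - my)^2)
        vxy <- sum(wv * (xi - mx) * (yj - my))
        lam <- eigen(matrix(c(vxx, vxy, vxy, vyy), 2), symmetric = TRUE)$values
        # moments are taken on the raw projection: blur variance is the
        # instrument psf plus the pixel-integration term 1/12
        sig2 <- (cfg$psf_sigma / voxel_xy)^2 + 1 / 12
        major_px <- max(2 * sqrt(2 * max(lam[1] - sig2, 0)), 1)
        minor_px <- max(2 * sqrt(2 * max(lam[2] - sig2, 0)), 1)
      }
    }
    circ <- if (outer$perimeter > 0) 4 * pi * outer$area / outer$perimeter^2 else 0
    # area/circularity exclusion filter (automated non-IM signal rejection)
    if (circ < cfg$circularity_bounds[1] || circ > cfg$circularity_bounds[2])
      return(NULL)
    # intensity ROI: component pixels dilated by the configured radius
    roi <- matrix(FALSE, nrow(lab), ncol(lab))
    roi[pix] <- TRUE
    r <- cfg$dilation_radius_for_roi
    if (r > 0) {
      base <- roi
      for (di in -r:r) for (dj in -r:r) {
        if (di * di + dj * dj > r * r) next
        si <- pmin(pmax(pix[, 1] + di, 1L), nrow(lab))
        sj <- pmin(pmax(pix[, 2] + dj, 1L), ncol(lab))
        roi[cbind(si, sj)] <- TRUE
      }
    }
    elong <- if (minor_px > 0) major_px / minor_px else Inf
    cls <- if (elong >= cfg$tubule_elongation) "tubule"
      else if (has_hole) "ring"
      else if (major_px * voxel_xy <= cfg$punctum_max_axis) "punctum"
      else "other"
    # hollow structures: the mid-line of the bright band (mean of outer
    # and hole outlines) estimates the true outline, cancelling the blur
    # widening to first order
    per_px <- if (has_hole) (outer$perimeter + hole$perimeter) / 2
              else outer$perimeter
    per_nm <- per_px * voxel_xy
    data.frame(label = l, class = cls, area_px = npx,
               perimeter_nm = per_nm,
               im_size_nm = per_nm / 2,
               major_axis_nm = major_px * voxel_xy,
               minor_axis_nm = minor_px * voxel_xy,
               has_hole = has_hole, circularity = circ,
               centroid_x_px = outer$cx, centroid_y_px = outer$cy,
               mean_intensity = mean(projection[roi]),
               integrated_intensity = sum(projection[roi]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Five-number summary with the boxplot whisker rule
#'
#' Quartiles use linear interpolation (quantile type 7).  The upper
#' whisker is the largest observation not exceeding the third quartile
#' plus 1.5 times the inter-quartile range; the lower whisker is the
#' smallest observation not below the first quartile minus 1.5 IQR.
#'
#' @param x Numeric vector (length >= 1).
#' @return List with `n`, `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @examples
#' boxplot_stats(1:100)
#' @export
boxplot_stats <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1, all(is.finite(x)))
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = lo, whisker_high = hi,
       outliers = sort(x[x < lo | x > hi]))
}

#' Opening-size summary over ring/punctum measurements
#'
#' The major axis of ring- and punctum-classified structures estimates the
#' isolation-membrane opening size; this summarises its distribution with
#' the same quartile/whisker definitions used in the boxplots.
#'
#' @param measurements A [measure_structures()] data frame.
#' @param classes Structure classes to include.
#' @return A one-row data frame (`n`, `median_nm`, `q1_nm`, `q3_nm`,
#'   `whisker_low_nm`, `whisker_high_nm`); zero-row if nothing qualifies.
#' @export
opening_size_distribution <- function(measurements,
                                      classes = c("ring", "punctum")) {
  x <- measurements$major_axis_nm[measurements$class %in% classes]
  if (!length(x))
    return(data.frame(n = integer(), median_nm = numeric(),
                      q1_nm = numeric(), q3_nm = numeric(),
                      whisker_low_nm = numeric(), whisker_high_nm = numeric()))
  b <- boxplot_stats(x)
  data.frame(n = b$n, median_nm = b$median, q1_nm = b$q1, q3_nm = b$q3,
             whisker_low_nm = b$whisker_low, whisker_high_nm = b$whisker_high)
}
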