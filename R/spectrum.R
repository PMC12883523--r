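#' Construct a spectrum object
#'
#' @param mz Numeric vector of m/z values.
#' @param intensity Numeric vector of intensities (same length, >= 0).
#' @param window Length-2 numeric `(low, high)` m/z window; points outside
#'   `[low, high)` are discarded. Default `c(1000, 8000)`, the acquisition
#'   range typical for native MS of intact phycobiliprotein complexes.
#' @return Object of class `spectrum`: list with `mz` (strictly increasing),
#'   `intensity` and `window`. Duplicate m/z values are merged by intensity
#'   sum.
#' @export
spectrum <- function(mz, intensity, window = c(1000, 8000)) {
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' must have equal length")
  keep <- mz >= window[1L] & mz < window[2L] & is.finite(mz)
  mz <- mz[keep]; intensity <- intensity[keep]
  if (length(mz) < 2L)
    stop("fewer than 2 points inside the m/z window")
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  } else {
    ord <- order(mz)
    mz <- mz[ord]; intensity <- intensity[ord]
  }
  if (any(intensity < 0)) intensity[intensity < 0] <- 0
  structure(list(mz = mz, intensity = intensity, window = as.numeric(window)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, m/z %.1f-%.1f (window %.0f-%.0f), base intensity %.3g\n",
              length(x$mz), min(x$mz), max(x$mz), x$window[1L], x$window[2L],
              max(x$intensity)))
  invisible(x)
}

#' Read a mass spectrum
#'
#' Two formats are supported: whitespace- or comma-delimited two-column
#' `m/z intensity` text, and mzML. Multiple MS1 scans in an mzML file are
#' averaged: every scan is linearly interpolated onto the first scan's m/z
#' grid and the arithmetic mean taken, matching the convention of reporting
#' the average spectrum over the acquisition.
#'
#' @param path Input file.
#' @param format `"xy_text"` or `"mzml"`; `NULL` guesses from the extension.
#' @param window m/z window passed to [spectrum()].
#' @return A `spectrum` object.
#' @export
read_spectrum <- function(path, format = NULL, window = c(1000, 8000)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "xy_text"
  }
  format <- match.arg(format, c("xy_text", "mzml"))
  if (format == "xy_text") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^\\s*#", lines)]
    parts <- strsplit(trimws(lines), "[,[:space:]]+")
    bad <- which(vapply(parts, length, integer(1L)) < 2L)
    if (length(bad)) stop("line ", bad[1L], ": expected two columns")
    mz <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1L), 1L)))
    it <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1L), 2L)))
    if (anyNA(mz) || anyNA(it)) stop("non-numeric values in two-column file")
    spectrum(mz, it, window = window)
  } else {
    scans <- read_mzml_scans(path)
    if (!length(scans)) stop("no MS1 spectra found in ", path)
    if (length(scans) == 1L) {
      spectrum(scans[[1L]]$mz, scans[[1L]]$intensity, window = window)
    } else {
      grid <- scans[[1L]]$mz
      mat <- vapply(scans, function(s)
        stats::approx(s$mz, s$intensity, xout = grid, rule = 2L)$y,
        numeric(length(grid)))
      spectrum(grid, rowMeans(mat), window = window)
    }
  }
}

#' Write a spectrum as two-column text
#'
#' @param spec A `spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_xy <- function(spec, path) {
  utils::write.table(data.frame(mz = spec$mz, intensity = spec$intensity),
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

rolling_median_baseline <- function(y, k = 101L) {
  n <- length(y)
  k <- min(as.integer(k), if (n %% 2L == 1L) n else n - 1L)
  if (k < 3L) return(rep(stats::median(y), n))
  if (k %% 2L == 0L) k <- k - 1L
  stats::runmed(y, k, endrule = "median")
}

#' Robust noise estimate of a spectrum
#'
#' Subtracts a rolling-median baseline and returns `1.4826 *` the median
#' absolute deviation of the residuals: a robust estimate of the standard
#' deviation of the additive noise that is insensitive to peaks occupying a
#' minority of the points. Returns 0 for a constant spectrum.
#'
#' @param spec A `spectrum` with at least 16 points.
#' @param baseline_k Rolling-median window in points (odd; clamped to the
#'   spectrum length). The default 101 spans many peak widths at typical
#'   native-MS grid spacing, so peaks do not inflate the baseline.
#' @return Noise sigma in intensity units.
#' @export
estimate_noise <- function(spec, baseline_k = 101L) {
  if (!inherits(spec, "spectrum")) stop("'spec' must be a spectrum")
  if (length(spec$mz) < 16L) stop("too few points to estimate noise (need >= 16)")
  resid <- spec$intensity - rolling_median_baseline(spec$intensity, baseline_k)
  stats::mad(resid, center = 0, constant = 1.4826)
}

#' Pick peaks above a signal-to-noise threshold
#'
#' Finds local maxima of the baseline-subtracted intensity, keeps those with
#' `S/N = height / noise >= sn_threshold` (the 3:1 cut used for native-MS
#' charge-state assignment), and refines each apex m/z by parabolic
#' interpolation of log-intensity through the apex and its two neighbours
#' (exact for a sampled Gaussian). Relative intensities are expressed against
#' the tallest returned peak, the base peak.
#'
#' When the noise estimate is positive, a peak is a contiguous region of
#' points above half the intensity threshold whose maximum clears the full
#' threshold, with at least `min_peak_points` points in the region above the
#' full threshold. One peak is reported per region, so a noisy profile peak
#' does not fragment into several apices, and isolated single-point
#' exceedances — common in pure Gaussian noise over ~1e5 grid points — are
#' rejected. On a noiseless spectrum every strict local maximum is a peak.
#'
#' @param spec A `spectrum`.
#' @param sn_threshold Minimum signal-to-noise ratio (default 3).
#' @param baseline_k Rolling-median baseline window (see [estimate_noise()]).
#' @param min_peak_points Minimum consecutive points at or above the threshold
#'   (default 2).
#' @param noise Optional externally supplied noise sigma; estimated from the
#'   spectrum when `NULL`.
#' @return data.frame of class `peak_list` with columns `mz`, `intensity`
#'   (apex height above baseline), `sn` and `relative_intensity`, sorted by
#'   m/z. May have zero rows.
#' @export
pick_peaks <- function(spec, sn_threshold = 3.0, baseline_k = 101L,
                       min_peak_points = 2L, noise = NULL) {
  if (!inherits(spec, "spectrum")) stop("'spec' must be a spectrum")
  y <- spec$intensity
  base <- rolling_median_baseline(y, baseline_k)
  h <- y - base
  if (is.null(noise)) {
    noise <- if (length(y) >= 16L)
      stats::mad(h, center = 0, constant = 1.4826) else 0
  }
  n <- length(y)
  empty <- data.frame(mz = numeric(0L), intensity = numeric(0L),
                      sn = numeric(0L), relative_intensity = numeric(0L))
  class(empty) <- c("peak_list", "data.frame")
  if (n < 3L) return(empty)
  if (noise > 0) {
    thr <- sn_threshold * noise
    mask <- h >= 0.5 * thr
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    apex <- integer(0L)
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      if (sum(h[idx] >= thr) < min_peak_points) next
      j <- idx[which.max(h[idx])]
      if (h[j] >= thr) apex <- c(apex, j)
    }
    apex <- apex[apex > 1L & apex < n]
    if (!length(apex)) return(empty)
    sn <- h[apex] / noise
  } else {
    i <- 2:(n - 1L)
    is_max <- h[i] > h[i - 1L] & h[i] >= h[i + 1L] & h[i] > 0
    apex <- i[is_max]
    if (!length(apex)) return(empty)
    sn <- rep(Inf, length(apex))
  }
  mz_ref <- vapply(apex, function(j) {
    y3 <- h[(j - 1L):(j + 1L)]
    x3 <- spec$mz[(j - 1L):(j + 1L)]
    if (all(y3 > 0)) y3 <- log(y3)
    denom <- y3[1L] - 2 * y3[2L] + y3[3L]
    if (denom >= 0) return(x3[2L])
    delta <- 0.5 * (y3[1L] - y3[3L]) / denom
    delta <- max(-0.5, min(0.5, delta))
    # local grid spacing (apex may sit between unequal steps)
    if (delta >= 0) x3[2L] + delta * (x3[3L] - x3[2L])
    else x3[2L] + delta * (x3[2L] - x3[1L])
  }, numeric(1L))
  height <- h[apex]
  out <- data.frame(mz = mz_ref, intensity = height, sn = sn,
                    relative_intensity = height / max(height))
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Write a peak list as TSV
#'
#' @param peaks A `peak_list` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
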