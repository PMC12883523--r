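#' Deconvolution parameters
#'
#' Controls charge-state series detection. Adducting species are protons only
#' (mass 1.00728 Da); the adduct mass is configurable for generality but salt
#' adducts are otherwise ignored, since the 0.1% assignment tolerance absorbs
#' typical native-MS adduction.
#'
#' @param proton_mass Adduct mass in Da (default 1.00728, a proton).
#' @param z_range Integer `(z_min, z_max)` charge search range.
#' @param min_series_length Minimum number of charge states per series
#'   (default 3: "multiple charge states", guarding against accidental
#'   ladders; configurable down to 2).
#' @param consistency_tol Relative tolerance on per-peak neutral masses within
#'   one series (default 5e-4, half the assignment threshold, so series
#'   formation is stricter than assignment).
#' @param extension_tol Relative guard used when growing a ladder: an
#'   extension peak must lie within `extension_tol * M` of the running mean as
#'   well as within `consistency_tol`. This rejects harmonic contamination (a
#'   species at ~2x the mass whose even charge states land exactly on the
#'   extension predictions with a small systematic mass offset) that the
#'   flat consistency tolerance alone would accept, and starves ladders seeded
#'   from an accidental cross-species pair. Default 1e-4.
#' @param allow_shared_peaks If `FALSE` (default) each peak joins at most one
#'   series, claimed greedily by series intensity rank.
#' @return Object of class `deconv_params`.
#' @export
deconv_params <- function(proton_mass = 1.00728, z_range = c(5L, 40L),
                          min_series_length = 3L, consistency_tol = 5e-4,
                          extension_tol = 1e-4,
                          allow_shared_peaks = FALSE) {
  z_range <- as.integer(z_range)
  if (z_range[1L] < 1L) stop("z_min must be >= 1")
  if (min_series_length < 2L) stop("min_series_length must be >= 2")
  if (consistency_tol <= 0) stop("consistency_tol must be > 0")
  structure(list(proton_mass = proton_mass, z_range = z_range,
                 min_series_length = as.integer(min_series_length),
                 consistency_tol = consistency_tol,
                 extension_tol = extension_tol,
                 allow_shared_peaks = isTRUE(allow_shared_peaks)),
            class = "deconv_params")
}

#' m/z of a neutral mass at charge z
#'
#' Standard positive-mode electrospray relation `(M + z * m_H) / z`.
#'
#' @param M Neutral mass in Da (> 0).
#' @param z Positive integer charge.
#' @param proton_mass Adduct mass in Da.
#' @return m/z value.
#' @export
mz_from_mass <- function(M, z, proton_mass = 1.00728) {
  if (any(M <= 0)) stop("'M' must be positive")
  if (any(z < 1)) stop("'z' must be >= 1")
  (M + z * proton_mass) / z
}

#' Neutral mass implied by an m/z value at charge z
#'
#' Algebraic inverse of [mz_from_mass()]: `z * (mz - m_H)`.
#'
#' @param mz m/z value.
#' @param z Positive integer charge.
#' @param proton_mass Adduct mass in Da.
#' @return Neutral mass in Da.
#' @export
mass_from_mz <- function(mz, z, proton_mass = 1.00728) {
  if (any(z < 1)) stop("'z' must be >= 1")
  z * (mz - proton_mass)
}

#' Infer the charge of the higher-m/z peak of an adjacent pair
#'
#' If two peaks are consecutive charge states z and z+1 of one species, then
#' `z = (mz_low - m_H) / (mz_high - mz_low)` where `mz_high` carries charge z.
#' The unrounded value must land within 0.15 of an integer inside the charge
#' search range, otherwise the pair is rejected (returns `NA`), which is how
#' peaks of unrelated species are kept apart.
#'
#' @param mz_high,mz_low m/z of the pair, `mz_high > mz_low`.
#' @param params A [deconv_params()].
#' @return Integer charge of the `mz_high` peak, or `NA_integer_`.
#' @export
infer_charge_from_adjacent <- function(mz_high, mz_low,
                                       params = deconv_params()) {
  if (mz_high <= mz_low) stop("'mz_high' must exceed 'mz_low'")
  z_raw <- (mz_low - params$proton_mass) / (mz_high - mz_low)
  z <- round(z_raw)
  if (abs(z_raw - z) > 0.15) return(NA_integer_)
  if (z < params$z_range[1L] || z > params$z_range[2L]) return(NA_integer_)
  as.integer(z)
}

new_charge_series <- function(peak_idx, charges, peaks, params) {
  mzs <- peaks$mz[peak_idx]
  masses <- mass_from_mz(mzs, charges, params$proton_mass)
  structure(list(
    peak_idx = peak_idx,
    charges = charges,
    peaks = peaks[peak_idx, , drop = FALSE],
    neutral_mass = mean(masses),
    mass_spread = if (length(masses) > 1L) stats::sd(masses) else 0,
    degenerate = length(masses) < 2L,
    summed_intensity = sum(peaks$intensity[peak_idx]),
    relative_intensity = NA_real_),
    class = "charge_series")
}

#' @export
print.charge_series <- function(x, ...) {
  cat(sprintf("<charge_series> M = %.2f Da (spread %.2f), z = %s, %d peaks, summed intensity %.3g\n",
              x$neutral_mass, x$mass_spread,
              paste(range(x$charges), collapse = "-"),
              length(x$charges), x$summed_intensity))
  invisible(x)
}

# grow a ladder outward from a seed (mass M, one peak at charge z)
extend_ladder <- function(seed_idx, seed_z, peaks, params) {
  idx <- seed_idx; charges <- seed_z
  masses <- mass_from_mz(peaks$mz[seed_idx], seed_z, params$proton_mass)
  for (dir in c(1L, -1L)) {
    z <- seed_z[if (dir == 1L) length(seed_z) else 1L]
    misses <- 0L
    repeat {
      z <- z + dir
      if (z < params$z_range[1L] || z > params$z_range[2L]) break
      M <- mean(masses)
      guard <- params$extension_tol * M
      cand_mass <- mass_from_mz(peaks$mz, z, params$proton_mass)
      dev <- abs(cand_mass - M) / M
      ok <- which(dev <= params$consistency_tol &
                  abs(cand_mass - M) <= guard &
                  !(seq_len(nrow(peaks)) %in% idx))
      if (length(ok)) {
        j <- ok[which.min(dev[ok])]
        idx <- c(idx, j); charges <- c(charges, z)
        masses <- c(masses, cand_mass[j])
        misses <- 0L
      } else {
        misses <- misses + 1L
        if (misses >= 2L) break
      }
    }
  }
  ord <- order(charges)
  list(idx = idx[ord], charges = charges[ord])
}

# drop charges separated from the ladder body by gaps > 1 missing state
trim_gaps <- function(idx, charges) {
  if (length(charges) < 2L) return(list(idx = idx, charges = charges))
  d <- diff(charges)
  breaks <- which(d > 2L)
  if (!length(breaks)) return(list(idx = idx, charges = charges))
  # keep the longest contiguous run
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(charges))
  runs <- ends - starts + 1L
  k <- which.max(runs)
  sel <- starts[k]:ends[k]
  list(idx = idx[sel], charges = charges[sel])
}

#' Group peaks into charge-state series
#'
#' Reproduces the manual multi-charge-state mass determination as a greedy
#' search: every peak pair whose spacing is consistent with consecutive
#' charges seeds a ladder; the ladder is extended in both charge directions,
#' accepting peaks whose implied neutral mass stays within `consistency_tol`
#' of the running mean; ladders with at least `min_series_length` members are
#' kept, ranked by summed intensity; unless `allow_shared_peaks`, each peak is
#' claimed by at most one series (ties broken by longer ladder, then lower
#' neutral mass). The result is deterministic given the input peak order.
#'
#' @param peaks A `peak_list` data.frame from [pick_peaks()].
#' @param params A [deconv_params()].
#' @return List of `charge_series`, ranked by summed intensity; each carries
#'   `neutral_mass`, `mass_spread`, `summed_intensity` and
#'   `relative_intensity` (fraction of the most intense series).
#' @export
find_series <- function(peaks, params = deconv_params()) {
  if (nrow(peaks) < params$min_series_length) return(list())
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  n <- nrow(peaks)

  candidates <- list()
  seen <- character(0L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mz_low <- peaks$mz[i]; mz_high <- peaks$mz[j]
    # plausible spacing pre-filter: consecutive charges in z_range
    if ((mz_high - mz_low) > mz_low / params$z_range[1L]) next
    z <- infer_charge_from_adjacent(mz_high, mz_low, params)
    if (is.na(z)) next
    lad <- extend_ladder(c(j, i), c(z, z + 1L), peaks, params)
    lad <- trim_gaps(lad$idx, lad$charges)
    if (length(lad$idx) < params$min_series_length) next
    sig <- paste(lad$idx, lad$charges, sep = ":", collapse = ",")
    if (sig %in% seen) next
    seen <- c(seen, sig)
    candidates[[length(candidates) + 1L]] <- lad
  }
  if (!length(candidates)) return(list())

  series <- lapply(candidates, function(l)
    new_charge_series(l$idx, l$charges, peaks, params))
  ord <- order(-vapply(series, `[[`, numeric(1L), "summed_intensity"),
               -vapply(series, function(s) length(s$charges), integer(1L)),
               vapply(series, `[[`, numeric(1L), "neutral_mass"))
  series <- series[ord]
  candidates <- candidates[ord]

  accepted <- list()
  claimed <- logical(n)
  for (k in seq_along(series)) {
    lad <- candidates[[k]]
    if (!params$allow_shared_peaks) {
      free <- !claimed[lad$idx]
      if (!all(free)) {
        lad <- trim_gaps(lad$idx[free], lad$charges[free])
      }
    }
    if (length(lad$idx) < params$min_series_length) next
    s <- new_charge_series(lad$idx, lad$charges, peaks, params)
    # a trimmed ladder may drift outside the consistency envelope; re-check
    masses <- mass_from_mz(s$peaks$mz, s$charges, params$proton_mass)
    if (any(abs(masses - s$neutral_mass) / s$neutral_mass >
            params$consistency_tol)) next
    if (!params$allow_shared_peaks) claimed[lad$idx] <- TRUE
    accepted[[length(accepted) + 1L]] <- s
  }
  if (!length(accepted)) return(list())
  top <- max(vapply(accepted, `[[`, numeric(1L), "summed_intensity"))
  lapply(accepted, function(s) {
    s$relative_intensity <- s$summed_intensity / top
    s
  })
}

#' Estimate the neutral mass of a charge-state series
#'
#' Per-peak masses `M_i = z_i * (mz_i - m_H)` are combined as an unweighted
#' mean with the sample standard deviation as spread, mirroring manual mass
#' determination from multiple charge states. Intensity weighting is available
#' via `weighted = TRUE`.
#'
#' @param series A `charge_series`.
#' @param params A [deconv_params()].
#' @param weighted Weight per-peak masses by peak intensity (default `FALSE`).
#' @return The series with `neutral_mass` and `mass_spread` updated; a
#'   single-peak series gets spread 0 and `degenerate = TRUE`.
#' @export
estimate_mass <- function(series, params = deconv_params(), weighted = FALSE) {
  masses <- mass_from_mz(series$peaks$mz, series$charges, params$proton_mass)
  series$neutral_mass <- if (weighted)
    stats::weighted.mean(masses, series$peaks$intensity) else mean(masses)
  series$mass_spread <- if (length(masses) > 1L) stats::sd(masses) else 0
  series$degenerate <- length(masses) < 2L
  series
}

#' Tabulate charge-state series
#'
#' @param series_list List of `charge_series`.
#' @return data.frame: series id, neutral mass, spread, charge range, number
#'   of peaks, summed and relative intensity.
#' @export
series_table <- function(series_list) {
  if (!length(series_list))
    return(data.frame(series = integer(0L), neutral_mass = numeric(0L),
                      mass_spread = numeric(0L), charges = character(0L),
                      n_peaks = integer(0L), summed_intensity = numeric(0L),
                      relative_intensity = numeric(0L)))
  data.frame(
    series = seq_along(series_list),
    neutral_mass = vapply(series_list, `[[`, numeric(1L), "neutral_mass"),
    mass_spread = vapply(series_list, `[[`, numeric(1L), "mass_spread"),
    charges = vapply(series_list, function(s)
      paste(s$charges, collapse = ","), character(1L)),
    n_peaks = vapply(series_list, function(s) length(s$charges), integer(1L)),
    summed_intensity = vapply(series_list, `[[`, numeric(1L),
                              "summed_intensity"),
    relative_intensity = vapply(series_list, `[[`, numeric(1L),
                                "relative_intensity"))
}

#' Write a series table as TSV
#'
#' @param series_list List of `charge_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_table <- function(series_list, path) {
  utils::write.table(series_table(series_list), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
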