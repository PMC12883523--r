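#' Default pipeline thresholds
#'
#' Single authoritative home of the three published filter constants:
#' assignment requires a percent mass error strictly below 0.1%; a complex is
#' low-abundant when its relative intensity is strictly below 5% of the base
#' peak; peaks must clear a 3:1 signal-to-noise cut. These defaults are echoed
#' into every pipeline report.
#'
#' @return Named list: `max_pct_error`, `low_abundance_frac`, `sn_threshold`.
#' @export
pipeline_defaults <- function() {
  list(max_pct_error = 0.1, low_abundance_frac = 0.05, sn_threshold = 3.0)
}

#' Match charge-state series to candidate compositions
#'
#' For each experimental series, every candidate composition whose percent
#' mass error `100 * |M_exp - M_theo| / M_theo` is strictly below
#' `max_pct_error` is reported, ranked by absolute error; the closest is
#' flagged primary. Series with no candidate in range are reported unassigned.
#'
#' @param series_list List of `charge_series`.
#' @param candidates List of `complex_composition` (theoretical masses set).
#' @param max_pct_error Percent error threshold (default
#'   `pipeline_defaults()$max_pct_error`).
#' @return data.frame of class `assignment_table`: columns `series`,
#'   `neutral_mass`, `relative_intensity`, `label`, `theoretical_mass`,
#'   `pct_error`, `primary`, `n_in_range`. Unassigned series appear with
#'   `label = NA` and `pct_error` of the nearest candidate.
#' @export
match_compositions <- function(series_list, candidates,
                               max_pct_error = pipeline_defaults()$max_pct_error) {
  theo <- vapply(candidates, `[[`, numeric(1L), "theoretical_mass")
  labels <- vapply(candidates, `[[`, character(1L), "label")
  rows <- list()
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    err <- 100 * abs(s$neutral_mass - theo) / theo
    inr <- which(err < max_pct_error)
    if (length(inr)) {
      inr <- inr[order(err[inr])]
      for (k in seq_along(inr)) {
        j <- inr[k]
        rows[[length(rows) + 1L]] <- data.frame(
          series = i, neutral_mass = s$neutral_mass,
          relative_intensity = s$relative_intensity,
          label = labels[j], theoretical_mass = theo[j],
          pct_error = err[j], primary = (k == 1L),
          n_in_range = length(inr), stringsAsFactors = FALSE)
      }
    } else {
      j <- which.min(err)
      rows[[length(rows) + 1L]] <- data.frame(
        series = i, neutral_mass = s$neutral_mass,
        relative_intensity = s$relative_intensity,
        label = NA_character_,
        theoretical_mass = if (length(j)) theo[j] else NA_real_,
        pct_error = if (length(j)) err[j] else NA_real_,
        primary = FALSE, n_in_range = 0L, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(series = integer(0L), neutral_mass = numeric(0L),
               relative_intensity = numeric(0L), label = character(0L),
               theoretical_mass = numeric(0L), pct_error = numeric(0L),
               primary = logical(0L), n_in_range = integer(0L))
  rownames(out) <- NULL
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Classify the abundance of an assigned complex
#'
#' A complex is `low_abundant` when its series relative intensity is strictly
#' below `low_abundance_frac` of the base peak, otherwise `major`.
#'
#' @param relative_intensity Fraction of base-peak intensity in (0, 1].
#' @param low_abundance_frac Threshold fraction (default 0.05).
#' @return `"low_abundant"` or `"major"` (vectorised).
#' @export
classify_abundance <- function(relative_intensity,
                               low_abundance_frac = pipeline_defaults()$low_abundance_frac) {
  ifelse(relative_intensity < low_abundance_frac, "low_abundant", "major")
}

#' Presence/absence verdicts for queried heterogeneous compositions
#'
#' A query is `detected` when it is the primary (closest in-range) composition
#' of some series that has no competing in-range candidate;
#' `ambiguous_detected` when the query is in range of a series but shares it
#' with other candidates within the error threshold (the data cannot tell the
#' stoichiometries apart); otherwise `not_detected`, with the expected m/z
#' ladder of the queried complex across the observed charge range and the
#' nearest series' percent error attached as evidence. `not_detected` means
#' "no series within threshold"; it does not assert absence below the noise.
#'
#' @param assignments An `assignment_table` from [match_compositions()].
#' @param queries Character vector of composition labels to interrogate; must
#'   be a subset of the candidate labels.
#' @param candidates The enumerated `complex_composition` list.
#' @param params A [deconv_params()] (proton mass for the expected ladders).
#' @param max_pct_error Threshold echoed into the report.
#' @param low_abundance_frac Threshold echoed into the report.
#' @return Object of class `heterogeneity_report`: data.frame `verdicts` with
#'   one row per query (`query`, `verdict`, `series`, `pct_error`,
#'   `abundance_class`, `expected_mz`), plus the thresholds used.
#' @export
heterogeneity_verdict <- function(assignments, queries, candidates,
                                  params = deconv_params(),
                                  max_pct_error = pipeline_defaults()$max_pct_error,
                                  low_abundance_frac = pipeline_defaults()$low_abundance_frac) {
  labels <- vapply(candidates, `[[`, character(1L), "label")
  unknown <- setdiff(queries, labels)
  if (length(unknown))
    stop("query label(s) not among enumerated candidates: ",
         paste(unknown, collapse = ", "))
  theo <- stats::setNames(
    vapply(candidates, `[[`, numeric(1L), "theoretical_mass"), labels)

  # observed charge span for expected-ladder evidence
  z_obs <- c(15L, 25L)
  if (nrow(assignments)) {
    z_lo <- params$z_range[1L]; z_hi <- params$z_range[2L]
    z_obs <- c(z_lo, z_hi)
  }

  rows <- lapply(queries, function(q) {
    hits <- assignments[!is.na(assignments$label) & assignments$label == q, ,
                        drop = FALSE]
    prim <- hits[hits$primary, , drop = FALSE]
    if (nrow(prim) && all(prim$n_in_range == 1L)) {
      data.frame(query = q, verdict = "detected",
                 series = prim$series[1L], pct_error = prim$pct_error[1L],
                 abundance_class = classify_abundance(
                   prim$relative_intensity[1L], low_abundance_frac),
                 expected_mz = NA_character_, stringsAsFactors = FALSE)
    } else if (nrow(hits)) {
      data.frame(query = q, verdict = "ambiguous_detected",
                 series = hits$series[1L], pct_error = hits$pct_error[1L],
                 abundance_class = classify_abundance(
                   hits$relative_intensity[1L], low_abundance_frac),
                 expected_mz = NA_character_, stringsAsFactors = FALSE)
    } else {
      # nearest series by percent error against this query's mass
      M <- theo[[q]]
      best_series <- NA_integer_; best_err <- NA_real_
      if (nrow(assignments)) {
        per_series <- unique(assignments[, c("series", "neutral_mass")])
        errs <- 100 * abs(per_series$neutral_mass - M) / M
        k <- which.min(errs)
        best_series <- per_series$series[k]; best_err <- errs[k]
      }
      zz <- z_obs[1L]:z_obs[2L]
      ladder <- paste(sprintf("%d:%.2f", zz,
                              mz_from_mass(M, zz, params$proton_mass)),
                      collapse = ";")
      data.frame(query = q, verdict = "not_detected",
                 series = best_series, pct_error = best_err,
                 abundance_class = NA_character_,
                 expected_mz = ladder, stringsAsFactors = FALSE)
    }
  })
  verdicts <- do.call(rbind, rows)
  rownames(verdicts) <- NULL
  structure(list(verdicts = verdicts,
                 thresholds = list(max_pct_error = max_pct_error,
                                   low_abundance_frac = low_abundance_frac)),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat("<heterogeneity_report> thresholds: pct_error <",
      x$thresholds$max_pct_error, "%, low-abundance <",
      100 * x$thresholds$low_abundance_frac, "% of base peak\n")
  print(x$verdicts[, c("query", "verdict", "pct_error", "abundance_class")])
  invisible(x)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full native-MS inference pipeline
#'
#' Read spectrum -> estimate noise -> pick peaks -> find charge-state series
#' -> enumerate candidate compositions -> match -> classify abundance ->
#' heterogeneity verdicts, writing TSV reports and a threshold/seed log.
#' Errors are re-raised with the failing stage's name; an empty spectrum or a
#' no-detection verdict is a success, not an error.
#'
#' @param config Named list (or path to a flat `key = value` file):
#'   \describe{
#'     \item{fasta}{subunit FASTA path (header `id|species|role[|family]`)}
#'     \item{ptm_tsv}{optional PTM rule table path}
#'     \item{rules}{optional [assembly_rules()] object or config path}
#'     \item{spectrum}{spectrum path}
#'     \item{spectrum_format}{`"xy_text"` or `"mzml"` (guessed when absent)}
#'     \item{queries}{optional character vector of composition labels}
#'     \item{out_dir}{output directory (created)}
#'     \item{max_pct_error, low_abundance_frac, sn_threshold}{threshold
#'       overrides; defaults from [pipeline_defaults()]}
#'     \item{z_min, z_max, min_series_length}{deconvolution overrides}
#'     \item{seed}{echoed into the log (the pipeline itself is deterministic)}
#'   }
#' @return Invisible list with `peaks`, `series`, `candidates`, `assignments`
#'   and `report` (`NULL` when no queries were given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_flat_config(config)
  defs <- pipeline_defaults()
  cfg <- utils::modifyList(
    c(defs, list(z_min = 5L, z_max = 40L, min_series_length = 3L,
                 spectrum_format = NULL, queries = NULL, ptm_tsv = NULL,
                 rules = NULL, seed = NA)),
    config)
  for (key in c("fasta", "spectrum", "out_dir"))
    if (is.null(cfg[[key]])) stop("[config] missing required key: ", key)

  ptms <- if (!is.null(cfg$ptm_tsv))
    stage("ptm", read_ptm_rules(cfg$ptm_tsv)) else NULL
  registry <- stage("fasta", read_subunit_fasta(cfg$fasta, ptms = ptms))
  rules <- stage("rules", {
    if (is.null(cfg$rules)) assembly_rules()
    else if (inherits(cfg$rules, "assembly_rules")) cfg$rules
    else read_assembly_rules(cfg$rules)
  })
  spec <- stage("spectrum", read_spectrum(cfg$spectrum, cfg$spectrum_format))
  peaks <- stage("peaks", pick_peaks(spec, sn_threshold = cfg$sn_threshold))
  dparams <- deconv_params(z_range = c(cfg$z_min, cfg$z_max),
                           min_series_length = cfg$min_series_length)
  series <- stage("deconv", find_series(peaks, dparams))
  candidates <- stage("enumerate", enumerate_compositions(registry, rules))
  assignments <- stage("assign",
    match_compositions(series, candidates, cfg$max_pct_error))
  report <- if (!is.null(cfg$queries))
    stage("verdict", heterogeneity_verdict(
      assignments, cfg$queries, candidates, dparams,
      cfg$max_pct_error, cfg$low_abundance_frac)) else NULL

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!length(series)) warning("no charge-state series detected; empty reports")
  write_peak_table(peaks, file.path(cfg$out_dir, "peaks.tsv"))
  write_series_table(series, file.path(cfg$out_dir, "series.tsv"))
  write_composition_table(candidates, file.path(cfg$out_dir, "candidates.tsv"))
  adf <- as.data.frame(assignments)
  adf$abundance_class <- ifelse(adf$n_in_range > 0L,
                                classify_abundance(adf$relative_intensity,
                                                   cfg$low_abundance_frac),
                                NA_character_)
  utils::write.table(adf, file.path(cfg$out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report))
    utils::write.table(report$verdicts,
                       file.path(cfg$out_dir, "verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(
    sprintf("max_pct_error\t%g", cfg$max_pct_error),
    sprintf("low_abundance_frac\t%g", cfg$low_abundance_frac),
    sprintf("sn_threshold\t%g", cfg$sn_threshold),
    sprintf("z_range\t%d-%d", cfg$z_min, cfg$z_max),
    sprintf("min_series_length\t%d", cfg$min_series_length),
    sprintf("seed\t%s", cfg$seed)),
    file.path(cfg$out_dir, "log.txt"))
  invisible(list(peaks = peaks, series = series, candidates = candidates,
                 assignments = assignments, report = report))
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    k <- trimws(p[1L])
    v <- trimws(paste(p[-1L], collapse = "="))
    out[[k]] <- if (k %in% c("max_pct_error", "low_abundance_frac",
                             "sn_threshold")) as.numeric(v)
      else if (k %in% c("z_min", "z_max", "min_series_length", "seed"))
        as.integer(v)
      else if (k == "queries") trimws(strsplit(v, ",")[[1L]])
      else v
  }
  out
}
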