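series_at <- function(M, rel = 1.0) {
  # minimal charge_series stand-in for matching tests
  structure(list(neutral_mass = M, relative_intensity = rel,
                 summed_intensity = 100 * rel, charges = 20:22,
                 peaks = data.frame(mz = mz_from_mass(M, 20:22),
                                    intensity = rep(10, 3))),
            class = "charge_series")
}

candidates_at <- function(masses, registry = NULL) {
  lapply(seq_along(masses), function(i) {
    reg <- fixed_mass_registry(masses[i])
    cc <- complex_composition(stats::setNames(1L, names(reg)[1L]), reg)
    cc$label <- paste0("C", i)
    cc
  })
}

test_that("matching honours the strict 0.1% error threshold", {
  cand <- candidates_at(100000)
  exact <- match_compositions(list(series_at(100000)), cand)
  expect_identical(exact$label, "C1")
  expect_identical(exact$pct_error, 0)
  expect_true(exact$primary)

  ok <- match_compositions(list(series_at(100000 * 1.0005)), cand)
  expect_identical(ok$label, "C1")
  expect_equal(ok$pct_error, 0.05, tolerance = 1e-9)

  out <- match_compositions(list(series_at(100000 * 1.002)), cand)
  expect_true(is.na(out$label))
  expect_identical(out$n_in_range, 0L)
  expect_equal(out$pct_error, 0.2, tolerance = 1e-9)  # nearest-candidate evidence

  # boundary: exactly 0.1% is NOT assigned (strict <); 100100 is exactly
  # representable so the percent error is exactly 0.1
  bound <- match_compositions(list(series_at(100100)), cand)
  expect_true(is.na(bound$label))
})

test_that("abundance classification uses strict < 5%", {
  expect_identical(classify_abundance(0.04), "low_abundant")
  expect_identical(classify_abundance(1.0), "major")
  expect_identical(classify_abundance(0.05), "major")
  expect_identical(classify_abundance(c(0.01, 0.5)),
                   c("low_abundant", "major"))
})

test_that("near-coincident candidates are flagged ambiguous, not picked", {
  cand <- candidates_at(c(100000, 100050))   # 0.05% apart
  asn <- match_compositions(list(series_at(100010)), cand)
  expect_identical(nrow(asn), 2L)
  expect_identical(asn$label[asn$primary], "C1")
  expect_identical(unique(asn$n_in_range), 2L)
  rep <- heterogeneity_verdict(asn, c("C1", "C2"), cand)
  expect_setequal(rep$verdicts$verdict, "ambiguous_detected")
})

test_that("verdicts: detected / not_detected with m/z-ladder evidence", {
  cand <- candidates_at(c(100000, 120000))
  asn <- match_compositions(list(series_at(100000)), cand)
  rep <- heterogeneity_verdict(asn, c("C1", "C2"), cand)
  v <- rep$verdicts
  expect_identical(v$verdict[v$query == "C1"], "detected")
  expect_identical(v$verdict[v$query == "C2"], "not_detected")
  # not_detected always carries expected m/z evidence
  expect_match(v$expected_mz[v$query == "C2"], "21:")
  expect_false(is.na(v$pct_error[v$query == "C2"]))
  expect_error(heterogeneity_verdict(asn, "nope", cand), "not among")
})

test_that("shrinking max_pct_error never converts not_detected to detected", {
  b <- scenario_library("fig4e", seed = 2L)
  out <- run_bundle(b)
  verdict_at <- function(thr) {
    asn <- match_compositions(out$series, out$candidates, max_pct_error = thr)
    heterogeneity_verdict(asn, out$report$verdicts$query, out$candidates,
                          max_pct_error = thr)$verdicts$verdict
  }
  thresholds <- c(0.1, 0.05, 0.02, 0.01, 0.001, 1e-5)
  states <- vapply(thresholds, function(t) verdict_at(t)[1L], character(1L))
  detected <- states == "detected"
  # once lost under a tighter threshold, detection never reappears
  expect_true(all(diff(detected) <= 0))
})

test_that("run_pipeline executes end to end from files", {
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "subunits.fasta")
  reg <- make_inventory(seed = 9L, include_linker = TRUE, fasta = fa)
  cand <- enumerate_compositions(reg, assembly_rules())
  labels <- vapply(cand, `[[`, character(1L), "label")
  trimer <- cand[[which(labels == "a3.b3")]]
  withl <- cand[[which(labels == "a3.b3+Lc")]]
  sim <- simulate_spectrum(sim_scenario(list(trimer, withl), c(1, 0.03),
                                        seed = 17L))
  spec_path <- file.path(dir, "spec.xy")
  write_spectrum_xy(sim$spectrum, spec_path)

  ptm_path <- file.path(dir, "ptms.tsv")
  write_ptm_rules(reg, ptm_path)
  out <- run_pipeline(list(fasta = fa, spectrum = spec_path,
                           ptm_tsv = ptm_path,
                           out_dir = file.path(dir, "out"),
                           queries = c("a3.b3", "a3.b3+Lc"), seed = 17L))
  v <- out$report$verdicts
  expect_identical(v$verdict, c("detected", "detected"))
  expect_identical(v$abundance_class, c("major", "low_abundant"))
  expect_true(all(file.exists(file.path(dir, "out",
    c("peaks.tsv", "series.tsv", "candidates.tsv", "assignments.tsv",
      "verdicts.tsv", "log.txt")))))
  # the published thresholds are echoed from the single source of defaults
  log <- readLines(file.path(dir, "out", "log.txt"))
  expect_true(any(grepl("max_pct_error\t0.1", log, fixed = TRUE)))
  expect_true(any(grepl("low_abundance_frac\t0.05", log, fixed = TRUE)))
  expect_true(any(grepl("sn_threshold\t3", log, fixed = TRUE)))
  expect_identical(pipeline_defaults(),
                   list(max_pct_error = 0.1, low_abundance_frac = 0.05,
                        sn_threshold = 3.0))
})

test_that("run_pipeline: empty spectrum warns, bad stage errors are labelled", {
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "subunits.fasta")
  make_inventory(seed = 9L, fasta = fa)
  flat <- file.path(dir, "flat.xy")
  set.seed(1)
  write_spectrum_xy(spectrum(seq(1000, 2000, by = 1),
                             abs(rnorm(1001, 0, 0.1))), flat)
  expect_warning(
    res <- run_pipeline(list(fasta = fa, spectrum = flat,
                             out_dir = file.path(dir, "out2"))),
    "no charge-state series")
  expect_length(res$series, 0L)
  expect_identical(nrow(res$assignments), 0L)

  expect_error(
    run_pipeline(list(fasta = fa, spectrum = flat, ptm_tsv = "missing.tsv",
                      out_dir = file.path(dir, "out3"))),
    "\\[ptm\\]")
  expect_error(run_pipeline(list(spectrum = flat, out_dir = dir)),
               "\\[config\\].*fasta")
})

test_that("the CLI dispatches subcommands", {
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "subunits.fasta")
  make_inventory(seed = 9L, fasta = fa)
  df <- phycoms_cli(c("masses", "--fasta", fa,
                      "--out", file.path(dir, "masses.tsv")))
  expect_identical(df$id, c("a", "b"))
  expect_true(file.exists(file.path(dir, "masses.tsv")))
  comps <- phycoms_cli(c("enumerate", "--fasta", fa,
                         "--out", file.path(dir, "enum.tsv")))
  expect_true(length(comps) >= 2L)
  expect_error(phycoms_cli("frobnicate"), "unknown subcommand")

  sim <- suppressMessages(
    phycoms_cli(c("simulate", "--scenario", "fig1b", "--seed", "3",
                  "--out-prefix", file.path(dir, "sim"))))
  expect_true(file.exists(file.path(dir, "sim.xy")))
  expect_true(file.exists(file.path(dir, "sim.mzML")))
  expect_true(file.exists(file.path(dir, "sim.truth.json")))
  pk <- phycoms_cli(c("peaks", "--spectrum", file.path(dir, "sim.xy"),
                      "--out", file.path(dir, "peaks.tsv")))
  expect_gt(nrow(pk), 5L)
  sl <- phycoms_cli(c("deconv", "--spectrum", file.path(dir, "sim.xy"),
                      "--out", file.path(dir, "series.tsv")))
  expect_length(sl, 2L)
})
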