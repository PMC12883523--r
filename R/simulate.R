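# Synthetic native-MS world: random subunit inventories and simulated
# charge-state envelopes with ground truth, so every pipeline stage can be
# validated without instrument data.

# Robinson & Robinson style average residue frequencies
RESIDUE_FREQ <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, E = 0.063,
  Q = 0.043, G = 0.073, H = 0.022, I = 0.053, L = 0.091, K = 0.059,
  M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.014,
  Y = 0.033, V = 0.066)

random_protein <- function(length) {
  paste(sample(names(RESIDUE_FREQ), length, replace = TRUE,
               prob = RESIDUE_FREQ), collapse = "")
}

role_ptms <- function(role) {
  switch(role,
    alpha = ,
    alpha_variant = list(ptm_rule("PCB", 586.7, 1L)),
    beta = ,
    beta_variant = list(ptm_rule("PCB", 586.7, 2L),
                        ptm_rule("methylation", 14, 1L)),
    linker = list())
}

#' Generate a synthetic subunit inventory
#'
#' Draws random protein sequences with realistic residue frequencies for each
#' (source, family) group: one alpha and one beta subunit per group, plus
#' optional minor variants and a 7.8 kDa-class linker. Subunit lengths are
#' staggered across the inventory so that all resolved masses differ pairwise
#' by at least `min_separation` (relative), keeping enumerated compositions
#' mass-resolvable at the 0.1% assignment threshold. PTM rules mimic
#' phycobiliprotein chemistry: one chromophore on alpha-type subunits, two
#' chromophores plus Asn methylation on beta-type subunits, none on linkers.
#'
#' @param seed Integer seed; the output is a deterministic function of the
#'   arguments.
#' @param n_families Number of pigment families (named F1, F2, ...).
#' @param n_sources Number of source organisms (named S1, S2, ...); every
#'   family is present in every source.
#' @param variants_per_family Named counts, e.g.
#'   `c(alpha_variant = 1, beta_variant = 0)`, added to the first source of
#'   each family.
#' @param length_range Sequence length range over which subunit lengths are
#'   staggered; minimum 50.
#' @param include_linker Add one linker subunit (~70 residues, ~7.8 kDa).
#' @param min_separation Minimum relative pairwise mass separation
#'   (default 0.003).
#' @param fasta Optional path; when given the inventory is also written as
#'   FASTA.
#' @return A `subunit_registry`.
#' @export
make_inventory <- function(seed = 1L, n_families = 1L, n_sources = 1L,
                           variants_per_family = c(alpha_variant = 0L,
                                                   beta_variant = 0L),
                           length_range = c(150L, 185L),
                           include_linker = FALSE,
                           min_separation = 0.003, fasta = NULL) {
  if (length_range[1L] < 50L) stop("sequence lengths must be >= 50")
  vpf <- c(alpha_variant = 0L, beta_variant = 0L)
  vpf[names(variants_per_family)] <- as.integer(variants_per_family)
  set.seed(as.integer(seed))

  # plan (id, species, family, role) rows first so lengths can be staggered
  plan <- list()
  for (f in seq_len(n_families)) for (s in seq_len(n_sources)) {
    fam <- paste0("F", f); src <- paste0("S", s)
    tag <- paste0(if (n_families > 1L) tolower(fam) else "",
                  if (n_sources > 1L) tolower(src) else "")
    plan[[length(plan) + 1L]] <- c(paste0("a", tag), src, fam, "alpha")
    plan[[length(plan) + 1L]] <- c(paste0("b", tag), src, fam, "beta")
    if (s == 1L) {
      for (v in seq_len(vpf[["alpha_variant"]]))
        plan[[length(plan) + 1L]] <-
          c(paste0("aB", if (vpf[["alpha_variant"]] > 1L) v else "", tag),
            src, fam, "alpha_variant")
      for (v in seq_len(vpf[["beta_variant"]]))
        plan[[length(plan) + 1L]] <-
          c(paste0("b18", if (vpf[["beta_variant"]] > 1L) v else "", tag),
            src, fam, "beta_variant")
    }
  }
  np <- length(plan)
  lens <- length_range[1L] +
    round((seq_len(np) - 1L) * diff(range(length_range)) / max(1L, np - 1L))

  for (attempt in seq_len(1000L)) {
    subs <- lapply(seq_len(np), function(i) {
      p <- plan[[i]]
      subunit_spec(id = p[1L], species = p[2L], family = p[3L], role = p[4L],
                   sequence = random_protein(lens[i]),
                   ptms = role_ptms(p[4L]))
    })
    if (include_linker)
      subs <- c(subs, list(subunit_spec(
        id = "Lc", species = plan[[1L]][2L], family = plan[[1L]][3L],
        role = "linker", sequence = random_protein(70L), ptms = list())))
    masses <- vapply(subs, resolve_subunit_mass, numeric(1L))
    d <- outer(masses, masses, function(x, y) abs(x - y) / pmin(x, y))
    if (all(d[upper.tri(d)] >= min_separation)) {
      reg <- subunit_registry(subs)
      if (!is.null(fasta)) write_subunit_fasta(reg, fasta)
      return(reg)
    }
  }
  stop("could not satisfy the mass-separation constraint in 1000 attempts")
}

#' Define a simulation scenario
#'
#' A scenario is a stated world: which complexes are present, at what relative
#' abundances, and under what instrument model. Each species produces a
#' charge-state envelope centred at the empirical native-ESI charge
#' `z = round(0.0778 * sqrt(M))` (configurable), with Gaussian weights across
#' charges, Gaussian peak shapes of FWHM `m/z / resolution`, and additive
#' Gaussian noise.
#'
#' @param compositions List of `complex_composition` objects (the species).
#' @param abundances Relative abundances in (0, 1]; the maximum must be 1.
#' @param charge_center_rule Function mapping neutral mass (Da) to the central
#'   charge.
#' @param charge_envelope_width Gaussian width of the envelope in charge units
#'   (default 1.5).
#' @param resolution Instrument resolving power; FWHM = m/z / resolution
#'   (default 15000).
#' @param noise_sigma Additive noise sigma in intensity units; the base peak
#'   is generated at height 100 (default 0.5).
#' @param mz_grid `(low, high, step)` of the m/z grid (default
#'   `c(1000, 8000, 0.05)`).
#' @param seed Integer seed for the noise.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(compositions, abundances,
                         charge_center_rule = function(M) round(0.0778 * sqrt(M)),
                         charge_envelope_width = 1.5,
                         resolution = 15000,
                         noise_sigma = 0.5,
                         mz_grid = c(1000, 8000, 0.05),
                         seed = 1L) {
  if (inherits(compositions, "complex_composition"))
    compositions <- list(compositions)
  if (length(compositions) != length(abundances))
    stop("one abundance per composition required")
  if (any(abundances <= 0) || any(abundances > 1))
    stop("abundances must lie in (0, 1]")
  if (max(abundances) != 1)
    stop("the most abundant species must have abundance 1")
  if (resolution <= 0) stop("resolution must be positive")
  structure(list(compositions = compositions,
                 abundances = as.numeric(abundances),
                 charge_center_rule = charge_center_rule,
                 charge_envelope_width = charge_envelope_width,
                 resolution = resolution, noise_sigma = noise_sigma,
                 mz_grid = as.numeric(mz_grid), seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate a native mass spectrum with ground truth
#'
#' For each species, charges `z_center - 3 .. z_center + 3` are generated with
#' Gaussian envelope weights; each charge contributes a Gaussian peak at
#' `(M + z * 1.00728) / z` with FWHM `apex / resolution` and apex height
#' `100 * abundance * weight`. Gaussian noise of sigma `noise_sigma` is added
#' on top of a constant offset of `5 * noise_sigma` (a noise floor, removed
#' downstream by the rolling-median baseline), and intensities are floored at
#' zero. The generation is fully seeded and reproducible.
#'
#' @param scenario A [sim_scenario()].
#' @return List with `spectrum` (a [spectrum()] object) and `truth`: one entry
#'   per species giving `label`, `mass`, `charges`, `apex_mz` and `height`.
#'   Species whose envelope falls partly outside the grid are truncated with a
#'   warning.
#' @export
simulate_spectrum <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  g <- scenario$mz_grid
  mz <- seq(g[1L], g[2L], by = g[3L])
  y <- numeric(length(mz))
  truth <- list()
  for (i in seq_along(scenario$compositions)) {
    cc <- scenario$compositions[[i]]
    M <- cc$theoretical_mass
    zc <- scenario$charge_center_rule(M)
    zs <- max(1L, zc - 3L):(zc + 3L)
    apex <- mz_from_mass(M, zs, 1.00728)
    inside <- apex >= g[1L] & apex <= g[2L]
    if (!all(inside)) {
      warning(sprintf("species '%s': %d of %d charge states fall outside the m/z grid and were truncated",
                      cc$label, sum(!inside), length(zs)))
      zs <- zs[inside]; apex <- apex[inside]
    }
    w <- exp(-((zs - zc)^2) / (2 * scenario$charge_envelope_width^2))
    h <- 100 * scenario$abundances[i] * w
    for (k in seq_along(zs)) {
      sigma <- (apex[k] / scenario$resolution) / (2 * sqrt(2 * log(2)))
      lo <- findInterval(apex[k] - 6 * sigma, mz) + 1L
      hi <- findInterval(apex[k] + 6 * sigma, mz)
      if (hi < lo) next
      idx <- lo:hi
      y[idx] <- y[idx] + h[k] * exp(-((mz[idx] - apex[k])^2) / (2 * sigma^2))
    }
    truth[[i]] <- list(label = cc$label, mass = M, charges = zs,
                       apex_mz = apex, height = h)
  }
  if (scenario$noise_sigma > 0) {
    set.seed(scenario$seed)
    y <- y + 5 * scenario$noise_sigma +
      stats::rnorm(length(y), 0, scenario$noise_sigma)
    y[y < 0] <- 0
  }
  list(spectrum = spectrum(mz, y, window = c(g[1L], g[2L] + g[3L])),
       truth = truth)
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element of [simulate_spectrum()]'s result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

scenario_bundle <- function(registry, rules, compositions, abundances,
                            queries, planted, seed, noise_sigma = 0.5) {
  list(registry = registry, rules = rules,
       scenario = sim_scenario(compositions, abundances, seed = seed,
                               noise_sigma = noise_sigma),
       queries = queries, planted = planted)
}

comp_by_label <- function(candidates, label) {
  labels <- vapply(candidates, `[[`, character(1L), "label")
  hit <- which(labels == label)
  if (!length(hit)) stop("no enumerated candidate labelled '", label, "'")
  candidates[[hit]]
}

#' Canned simulation scenarios mirroring the published figures
#'
#' Returns named scenario bundles, each with a subunit registry, assembly
#' rules, a [sim_scenario()], the query labels to interrogate downstream, and
#' the planted species labels (the ground truth):
#' \describe{
#'   \item{fig1b}{one family: trimer at 100% plus trimer + 7.8 kDa linker at
#'     3% (a low-abundant species under the 5% rule).}
#'   \item{fig1c}{alpha-beta pair at 100% plus the beta-variant pair at 10%.}
#'   \item{fig1d}{trimers carrying 0-3 copies of the alpha variant, abundances
#'     1.0/0.6/0.3/0.1.}
#'   \item{fig2}{two pigment families, only the pure trimers planted; the two
#'     mixed-ring queries must come back not_detected.}
#'   \item{fig3}{two co-expressed isoform pairs (sources) with only like-with-
#'     like pairs and trimers planted; crossed-pair queries must come back
#'     not_detected.}
#'   \item{fig4e}{two sources with a cross-source mixed trimer planted at 20%;
#'     its query must come back detected.}
#' }
#' True abundances of the minor species in the figures are not published;
#' the values here are the package's stated world, not reported values.
#'
#' @param name Scenario name; one of the above.
#' @param seed Integer master seed (inventories and noise derive from it).
#' @return A scenario bundle (list).
#' @export
scenario_library <- function(name, seed = 1L) {
  seed <- as.integer(seed)
  known <- c("fig1b", "fig1c", "fig1d", "fig2", "fig3", "fig4e")
  if (!(is.character(name) && length(name) == 1L && name %in% known))
    stop("unknown scenario '", name, "'; available: ",
         paste(known, collapse = ", "))
  switch(name,
    fig1b = {
      reg <- make_inventory(seed = seed, include_linker = TRUE)
      rules <- assembly_rules()
      cand <- enumerate_compositions(reg, rules)
      trimer <- comp_by_label(cand, "a3.b3")
      with_l <- comp_by_label(cand, "a3.b3+Lc")
      scenario_bundle(reg, rules, list(trimer, with_l), c(1.0, 0.03),
                      queries = c("a3.b3", "a3.b3+Lc"),
                      planted = c("a3.b3", "a3.b3+Lc"), seed = seed + 101L)
    },
    fig1c = {
      reg <- make_inventory(seed = seed,
                            variants_per_family = c(beta_variant = 1L))
      rules <- assembly_rules()
      cand <- enumerate_compositions(reg, rules)
      scenario_bundle(reg, rules,
                      list(comp_by_label(cand, "a.b"),
                           comp_by_label(cand, "a.b18")),
                      c(1.0, 0.1),
                      queries = c("a.b", "a.b18"),
                      planted = c("a.b", "a.b18"), seed = seed + 102L)
    },
    fig1d = {
      reg <- make_inventory(seed = seed,
                            variants_per_family = c(alpha_variant = 1L))
      rules <- assembly_rules()
      cand <- enumerate_compositions(reg, rules)
      labs <- c("a3.b3", "a2.aB.b3", "a.aB2.b3", "aB3.b3")
      scenario_bundle(reg, rules, lapply(labs, comp_by_label, candidates = cand),
                      c(1.0, 0.6, 0.3, 0.1),
                      queries = labs, planted = labs, seed = seed + 103L)
    },
    fig2 = {
      reg <- make_inventory(seed = seed, n_families = 2L)
      rules <- assembly_rules()
      cand <- enumerate_compositions(reg, rules)
      pure <- c("af13.bf13", "af23.bf23")
      hybrids <- c("af12.af2.bf12.bf2", "af1.af22.bf1.bf22")
      scenario_bundle(reg, rules, lapply(pure, comp_by_label, candidates = cand),
                      c(1.0, 0.9),
                      queries = hybrids, planted = pure, seed = seed + 104L)
    },
    fig3 = {
      reg <- make_inventory(seed = seed, n_sources = 2L)
      rules <- assembly_rules(allow_cross_pairs = TRUE)
      cand <- enumerate_compositions(reg, rules)
      pure <- c("as1.bs1", "as2.bs2", "as13.bs13", "as23.bs23")
      crossed <- c("as1.bs2", "as2.bs1")
      scenario_bundle(reg, rules, lapply(pure, comp_by_label, candidates = cand),
                      c(1.0, 0.8, 0.9, 0.7),
                      queries = crossed, planted = pure, seed = seed + 105L)
    },
    fig4e = {
      reg <- make_inventory(seed = seed, n_sources = 2L)
      rules <- assembly_rules()
      cand <- enumerate_compositions(reg, rules)
      pure <- c("as13.bs13", "as23.bs23")
      hybrid <- "as12.as2.bs12.bs2"
      scenario_bundle(reg, rules,
                      lapply(c(pure, hybrid), comp_by_label, candidates = cand),
                      c(1.0, 0.8, 0.2),
                      queries = hybrid, planted = c(pure, hybrid),
                      seed = seed + 106L)
    })
}
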