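# Independent oracles, deliberately written with different algorithms than
# the implementation they check.

# mass of a free amino acid from its elemental formula and standard atomic
# weights (independent of the residue-mass table in the package)
ATOMIC_WEIGHT <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

elemental_mass <- function(formula_counts) {
  sum(ATOMIC_WEIGHT[names(formula_counts)] * formula_counts)
}

oracle_glycine_mass <- function() {
  elemental_mass(c(C = 2, H = 5, N = 1, O = 2))          # C2H5NO2
}

oracle_water_mass <- function() elemental_mass(c(H = 2, O = 1))

# brute-force multiset counter: enumerate all ordered n-tuples over k types
# and count distinct multisets
brute_force_multiset_count <- function(k, n) {
  tuples <- do.call(expand.grid, rep(list(seq_len(k)), n))
  keys <- apply(tuples, 1L, function(r) paste(sort(r), collapse = ","))
  length(unique(keys))
}

# brute-force best global alignment score under affine gaps: full recursion
# over all monotone alignments (no DP memoisation). Gap run of length L costs
# gap_open + L * gap_extend, matching the package's scoring convention.
brute_force_align_score <- function(a, b, match, mismatch, gap_open,
                                    gap_extend) {
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= n) {  # gap in b
      cost <- gap_extend + if (prev != "A") gap_open else 0
      best <- max(best, -cost + rec(i + 1L, j, "A"))
    }
    if (j <= m) {  # gap in a
      cost <- gap_extend + if (prev != "B") gap_open else 0
      best <- max(best, -cost + rec(i, j + 1L, "B"))
    }
    best
  }
  rec(1L, 1L, "M")
}

# run a scenario bundle through the whole pipeline in memory
run_bundle <- function(bundle) {
  sim <- simulate_spectrum(bundle$scenario)
  pk <- pick_peaks(sim$spectrum)
  sl <- find_series(pk)
  cand <- enumerate_compositions(bundle$registry, bundle$rules)
  asn <- match_compositions(sl, cand)
  rep <- heterogeneity_verdict(asn, bundle$queries, cand)
  list(sim = sim, peaks = pk, series = sl, candidates = cand,
       assignments = asn, report = rep)
}

# registry of fixed-mass pseudo-subunits, for planting species of exact mass
fixed_mass_registry <- function(masses) {
  subs <- lapply(seq_along(masses), function(i)
    subunit_spec(paste0("X", i), role = if (i %% 2L) "alpha" else "beta",
                 fixed_mass = masses[i]))
  subunit_registry(subs)
}

fixed_mass_composition <- function(mass) {
  reg <- fixed_mass_registry(mass)
  complex_composition(stats::setNames(1L, names(reg)[1L]), reg)
}
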