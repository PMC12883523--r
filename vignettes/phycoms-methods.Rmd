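---
title: "phycoMS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phycoMS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phycoMS decides, from a native electrospray mass spectrum, which
phycobiliprotein complex stoichiometries are present and which hypothesised
heterogeneous complexes are absent. This vignette records the model, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices that were genuinely open.

# The mass model

Subunit masses are **average masses**: the sum of average residue masses
(standard IUPAC atomic-weight tables) plus one water, then adjusted by PTM
rules applied as `count × delta_mass`. Average rather than monoisotopic
masses are the only sensible choice here: the complexes weigh 30–130 kDa and
are measured at resolving power 15,000, where isotope structure is
unresolved, and the canonical PTM constants in this field (phycocyanobilin
+586.7 Da, initiator-Met loss −131.2 Da, Asn methylation +14 Da) are average
masses quoted to one decimal or integer precision. PTM deltas are applied
verbatim as configured (e.g. +14, not +14.0157); if a user wants exact
elemental deltas they simply put them in the PTM table — the arithmetic is
the same code path.

A complex's theoretical mass is the plain sum of its members' adjusted
masses: non-covalent assembly adds no binding-induced mass change, and
adduction (salt, residual solvent) is deliberately not modelled — the 0.1%
assignment tolerance (≥ 30 Da at these masses) absorbs typical native-MS
adducts.

# Composition enumeration

The enumeration unit is the **αβ protomer**. Within each (source organism,
pigment family) group, every alpha-role subunit pairs with every beta-role
subunit; variant subunits (`alpha_variant`, `beta_variant`) pair like their
cognate role and are capped per composition by
`max_variant_substitutions` (defaults 3 for α-variants, 1 for β-variants,
mirroring how many copies are structurally plausible in a trimeric ring).
For each oligomer state *n* (default {1, 3}: free protomers and trimers),
all protomer multisets of size *n* are generated; a multiset spanning several
sources or families is kept only if the corresponding mixing flag allows it.
Linkers attach 0..`linker_max_copies` copies, and only to oligomers of at
least `linker_min_oligomer` protomers (default 3) — linker proteins decorate
rings, not free αβ pairs.

Two deliberate choices:

* **Mixing flags default to permissive.** Whether a hybrid ring exists
  should be an empirical verdict delivered by the spectrum, not an assumption
  baked into the candidate list. With mixing on, an absent hybrid yields a
  clean `not_detected` with expected-m/z evidence; with mixing off the
  query would simply be unposeable.
* **Crossed pairs are a separate flag.** Cross-source/cross-family mixing
  acts on whole protomers co-occupying one ring (so two sources A and B give
  exactly the four trimers (αβ_A)₃, 2αβ_A·αβ_B, αβ_A·2αβ_B, (αβ_B)₃ —
  the multiset count C(n+k−1, k−1)). The distinct hypothesis that an alpha of
  one isoform pairs directly with a beta of another (α₁β₂) is enabled by
  `allow_cross_pairs` (default off), because it multiplies the candidate list
  and is only meaningful for co-expressed isoform inventories.

Labels are canonical — members sorted by (role, id) with copy counts
appended, linkers suffixed with `+` — so joins across report tables are
stable. Hexamers and larger stacks are representable via `oligomer_states`
but not enumerated by default.

# Peak picking and noise

The noise scale is `1.4826 × MAD` of the residuals after subtracting a
rolling-median baseline (window `baseline_k = 101` points, i.e. several peak
widths at the default grid, so peaks do not inflate the baseline). The MAD is
used because peaks occupy a minority of grid points; a huge peak barely moves
the estimate (verified by Monte-Carlo in the test suite).

The S/N definition is sigma-based: `sn = apex height above baseline / noise`,
and the cut is `sn ≥ 3`. The peak-to-peak convention used by some instrument
software would correspond to a several-fold larger effective threshold; with
the sigma convention chosen, a 3σ exceedance is common in ~10⁵ points of
Gaussian noise, so a peak must additionally be a contiguous region above half
the intensity threshold containing at least `min_peak_points = 2` points
above the full threshold. One peak is reported per region (a noisy profile
peak therefore cannot fragment into several apices), the apex m/z is refined
by parabolic interpolation of log-intensity — exact for a sampled Gaussian —
and heights are raw apex heights above baseline, unbiased for narrow peaks.

A consequence worth stating: detection at the threshold is statistical. A
planted peak with true S/N 5 falls below the 3:1 cut with probability ≈ 2%
(its measured apex is `5σ + noise`). The recovery property test therefore
asserts aggregate recovery (≥ 95% at S/N ≥ 5, exact at S/N ≥ 10) plus a
spurious-peak budget, rather than literal always-recovery, which no
implementation of this S/N definition could deliver.

# Charge-state deconvolution

Every peak pair whose spacing is consistent with consecutive charges seeds a
ladder: `z = (mz_low − m_H)/(mz_high − mz_low)` must land within 0.15 of an
integer inside `z_range` (default 5–40, covering 20–150 kDa complexes at
native charging). Ladders grow in both charge directions, accepting peaks
whose implied neutral mass `z·(mz − m_H)` stays within **both**:

* `consistency_tol = 5e-4` (relative) of the running mean — half the
  assignment threshold, so series formation is stricter than assignment; and
* `extension_tol = 1e-4` (relative) of the running mean — a tighter guard
  needed because of harmonics: if one species weighs ≈ 2× another, the heavy
  species' even charge states land exactly where the light species' ladder
  extension predicts, with an implied-mass offset that can be well inside
  5e-4. The flat 5e-4 rule alone demonstrably absorbs such foreign peaks and
  drags the mass estimate off by ~1e-4 relative; the guard starves those
  extensions (and ladders seeded from an accidental cross-species pair)
  while leaving legitimate growth untouched, since centroid scatter
  translates to well under 1e-5 relative mass scatter at any usable S/N.

Accepted ladders need `min_series_length = 3` charge states ("multiple"
charge states, guarding against accidental two-peak ladders; configurable
down to 2) and at most one missing charge between neighbours. Unless
`allow_shared_peaks`, peaks are claimed greedily by series rank: summed
intensity, then ladder length, then lower neutral mass. The neutral mass is
the **unweighted mean** of per-peak masses (intensity weighting is available
but off by default — whether the original manual calculations weighted by
intensity is unknowable, and unweighted is the more conservative choice),
with the sample standard deviation reported as the spread; a single-peak
series (only reachable with a reconfigured minimum length) reports spread 0
and a degenerate flag.

# Assignment, abundance, verdicts

Percent error is computed against the theoretical mass
(`100·|M_exp − M_theo|/M_theo`) and the thresholds are strict inequalities
exactly as defined: `< 0.1%` assigns, relative intensity `< 5%` of the base
peak is low-abundant, `S/N ≥ 3` keeps a peak. All three constants live in one
place (`pipeline_defaults()`) and are echoed into every pipeline log.

If two enumerated compositions fall within 0.1% of one series — possible
when subunit masses nearly coincide — both are reported and the verdict is
`ambiguous_detected` rather than a silent choice: mass spectrometry alone
cannot separate them, only further purification could. `not_detected` means
"no series within threshold"; it does not assert absence below the noise
floor, and the verdict carries the expected m/z ladder of the queried complex
across the observed charge range so the spectrum can be inspected by eye.

# The synthetic world

`simulate_spectrum()` emulates: several co-occurring complexes of
30–130 kDa; charge-state envelopes centred at the empirical native-ESI
charge `z̄ = round(0.0778·√M)` (which puts a ~10⁵ Da complex at 21+/22+,
matching observed native charging) with Gaussian weights of width 1.5 charge
units; Gaussian peak shapes with FWHM = m/z / 15,000 on a 0.05 m/z grid over
1000–8000 m/z; relative abundances down to a few percent of the base peak;
and additive Gaussian noise on a small constant floor, seeded and
reproducible. The generated base peak has height 100, so `noise_sigma = 0.5`
(the default) makes a 3% species sit at apex S/N 6 — detectable but clearly
minor, which is what the canned scenarios need.

It does **not** emulate: isotope fine structure (unresolvable at this
resolving power and mass), salt adducts or charge-reduced satellites,
detector saturation, chemical (structured) baseline, or chromatographic
behaviour. A green end-to-end test therefore establishes that the inference
chain is correct under well-behaved instrument physics, not that it is robust
to every artefact of real spectra.

`make_inventory()` draws random sequences with realistic residue frequencies
and staggers lengths so all subunit masses differ pairwise by ≥ 0.3%,
keeping enumerated compositions resolvable at the 0.1% threshold. Its PTM
rules follow phycobiliprotein chemistry (one chromophore on alpha-type
subunits, two plus methylation on beta-type). The canned scenarios' minor
abundances (3% linker species, 10% variant dimer, the 1.0/0.6/0.3/0.1
substitution series, 20% planted hybrid) are the package's stated world —
the corresponding real relative abundances are not published quantities.

In the end-to-end acceptance world, the noise level is drawn so the smallest
planted species' apex S/N is uniform in [5, 25]: the stated constraint is a
floor (≥ 4), and pinning every scenario exactly at the floor would make every
scenario a boundary case, which is neither what the constraint says nor how
an experiment is run.

# Sequence identity

Pairwise global alignment is delegated to `Biostrings::pairwiseAlignment`
with BLOSUM62 and gap open 10 / extend 0.5 — the classic ClustalW protein
defaults, appropriate because ClustalW on two sequences reduces to a pairwise
global alignment. A gap run of length L costs `open + L·extend`; the test
suite checks the optimum against a hand-written brute-force enumeration of
all alignments for short sequences. Tie-breaking among co-optimal alignments
is the library's own; percent identity, the quantity that matters, is pinned
by the tests. The identity denominator is the full alignment length including
gap columns, with a `denominator = "shorter"` switch, since both conventions
are in circulation and the published isoform identities do not state which
produced them.

# Known limitations

* Overlapping charge-state envelopes are handled only by greedy claiming;
  peaks that physically merge (apices closer than ~1 FWHM) are centroided as
  one and can bias the weaker series' mass. The deconvolution oracle is
  accordingly stated, and verified, for non-overlapping envelopes.
* Harmonic mass coincidences tighter than `extension_tol` (≈ 1e-4 relative)
  remain genuinely ambiguous at this tolerance chain.
* The worked comparisons against printed real-data values (hybrid hexad m/z
  at 21+, isoform identities) require the real accession sequences, which the
  offline build cannot fetch; the package computes them trivially once the
  FASTA files are supplied.
* No Kd/affinity modelling, no spectral fitting of overlapping envelopes, no
  structure-based plausibility filtering of compositions.
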