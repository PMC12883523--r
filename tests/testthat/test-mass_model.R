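test_that("sequence_average_mass matches an elemental-formula oracle", {
  # free glycine from C2H5NO2 with standard atomic weights: 75.067
  expect_equal(sequence_average_mass("G"), oracle_glycine_mass(),
               tolerance = 0.01 / 75)
  # GG: two glycine residues plus one water
  expect_equal(sequence_average_mass("GG"),
               2 * (oracle_glycine_mass() - oracle_water_mass()) +
                 oracle_water_mass(),
               tolerance = 0.01 / 132)
  # additivity over concatenation minus (n-1) waters; the water term is
  # derived from the package itself (w = 2*m(G) - m(GG)) so the check is
  # exact to floating tolerance
  water <- 2 * sequence_average_mass("G") - sequence_average_mass("GG")
  a <- "ACDEFGHIK"; b <- "LMNPQRSTVWY"
  expect_equal(sequence_average_mass(paste0(a, b)),
               sequence_average_mass(a) + sequence_average_mass(b) - water,
               tolerance = 1e-9)
})

test_that("sequence_average_mass rejects bad input naming the offender", {
  expect_error(sequence_average_mass(""), "empty")
  expect_error(sequence_average_mass("ACXDE"), "'X' at position 3")
  expect_error(sequence_average_mass("ACDB"), "'B' at position 4")
})

test_that("resolve_subunit_mass applies the published PTM arithmetic", {
  pcb <- ptm_rule("PCB", 586.7, 1L)
  mloss <- ptm_rule("Met loss", -131.2, 1L)
  meth <- ptm_rule("methylation", 14, 1L)
  base <- function(...) subunit_spec("s", role = "alpha", fixed_mass = 17000,
                                     ptms = list(...))
  expect_equal(resolve_subunit_mass(base(pcb)), 17586.7)
  expect_equal(resolve_subunit_mass(base(pcb, mloss)), 17455.5)
  expect_equal(resolve_subunit_mass(base(ptm_rule("PCB", 586.7, 2L), meth)),
               18187.4)
  expect_equal(resolve_subunit_mass(base()), 17000)
})

test_that("subunit_spec enforces its invariants", {
  expect_error(subunit_spec("s", role = "alpha"), "exactly one")
  expect_error(subunit_spec("s", role = "alpha", sequence = "ACDE",
                            fixed_mass = 100), "exactly one")
  expect_error(subunit_spec("s", role = "alpha", sequence = "ACZDE"),
               "'Z' at position 3")
  expect_error(subunit_spec("s", role = "alpha", fixed_mass = -5), "positive")
  # PTMs can never push the resolved mass negative
  expect_error(subunit_spec("s", role = "alpha", fixed_mass = 100,
                            ptms = list(ptm_rule("x", -200, 1L))))
})

test_that("composition_mass sums member masses", {
  a <- subunit_spec("A", role = "alpha", fixed_mass = 17455.5)
  b <- subunit_spec("B", role = "beta", fixed_mass = 18187.4)
  reg <- subunit_registry(a, b)
  expect_equal(composition_mass(c(A = 1L), reg), 17455.5)
  expect_equal(composition_mass(c(A = 3L, B = 3L), reg), 106928.7)
  expect_error(composition_mass(integer(0L), reg), "empty composition")
  expect_error(composition_mass(c(Q = 1L), reg), "unknown subunit")
})

test_that("mass additivity holds for disjoint composition unions", {
  reg <- make_inventory(seed = 7L, n_families = 2L)
  ids <- names(reg)
  set.seed(11)
  for (rep in 1:20) {
    m1 <- stats::setNames(sample(0:3, 2), sample(ids, 2))
    m2 <- stats::setNames(sample(1:3, 2), setdiff(ids, names(m1)))
    m1 <- m1[m1 > 0]
    if (!length(m1)) next
    expect_equal(composition_mass(c(m1, m2), reg),
                 composition_mass(m1, reg) + composition_mass(m2, reg),
                 tolerance = 1e-9)
  }
})

make_basic_registry <- function(with_variant = FALSE, with_linker = FALSE) {
  subs <- list(
    subunit_spec("a", species = "S", family = "F", role = "alpha",
                 fixed_mass = 17000),
    subunit_spec("b", species = "S", family = "F", role = "beta",
                 fixed_mass = 18100))
  if (with_variant)
    subs <- c(subs, list(subunit_spec("aB", species = "S", family = "F",
                                      role = "alpha_variant",
                                      fixed_mass = 17600)))
  if (with_linker)
    subs <- c(subs, list(subunit_spec("Lc", species = "S", family = "F",
                                      role = "linker", fixed_mass = 7800)))
  subunit_registry(subs)
}

test_that("variant substitution enumerates k = 0..max copies", {
  reg <- make_basic_registry(with_variant = TRUE)
  rules <- assembly_rules(oligomer_states = 3L,
                          max_variant_substitutions = c(alpha_variant = 3L))
  comps <- enumerate_compositions(reg, rules)
  labels <- vapply(comps, `[[`, character(1L), "label")
  expect_setequal(labels, c("a3.b3", "a2.aB.b3", "a.aB2.b3", "aB3.b3"))
  # lowering the cap prunes the high-substitution species
  rules1 <- assembly_rules(oligomer_states = 3L,
                           max_variant_substitutions = c(alpha_variant = 1L))
  expect_setequal(
    vapply(enumerate_compositions(reg, rules1), `[[`, character(1L), "label"),
    c("a3.b3", "a2.aB.b3"))
})

test_that("cross-source protomer mixing gives the multiset count", {
  subs <- list(
    subunit_spec("aA", species = "A", family = "PC", role = "alpha", fixed_mass = 17000),
    subunit_spec("bA", species = "A", family = "PC", role = "beta",  fixed_mass = 18100),
    subunit_spec("aB", species = "B", family = "PC", role = "alpha", fixed_mass = 17900),
    subunit_spec("bB", species = "B", family = "PC", role = "beta",  fixed_mass = 19300))
  reg <- subunit_registry(subs)
  comps <- enumerate_compositions(reg, assembly_rules(oligomer_states = 3L))
  expect_length(comps, 4L)  # (ab_A)3, 2ab_A.ab_B, ab_A.2ab_B, (ab_B)3
  labels <- vapply(comps, `[[`, character(1L), "label")
  expect_true(all(c("aA3.bA3", "aA2.aB.bA2.bB", "aB3.bB3") %in% labels))
  # with mixing off, only the pure rings survive
  comps_off <- enumerate_compositions(
    reg, assembly_rules(oligomer_states = 3L,
                        allow_cross_source_protomers = FALSE))
  expect_setequal(
    vapply(comps_off, `[[`, character(1L), "label"),
    c("aA3.bA3", "aB3.bB3"))
})

test_that("linkers decorate rings but not free pairs", {
  reg <- make_basic_registry(with_linker = TRUE)
  comps <- enumerate_compositions(reg, assembly_rules(oligomer_states = c(1L, 3L)))
  labels <- vapply(comps, `[[`, character(1L), "label")
  expect_setequal(labels, c("a.b", "a3.b3", "a3.b3+Lc"))
})

test_that("enumeration counts match closed forms via brute force", {
  for (k in 1:3) for (n in 1:4) {
    subs <- unlist(lapply(seq_len(k), function(s) list(
      subunit_spec(paste0("a", s), species = paste0("S", s), role = "alpha",
                   fixed_mass = 16000 + 997 * s),
      subunit_spec(paste0("b", s), species = paste0("S", s), role = "beta",
                   fixed_mass = 18000 + 1013 * s))), recursive = FALSE)
    reg <- subunit_registry(subs)
    comps <- enumerate_compositions(reg, assembly_rules(oligomer_states = n))
    expect_identical(length(comps), as.integer(choose(n + k - 1, k - 1)),
                     info = sprintf("k=%d n=%d", k, n))
    expect_identical(length(comps), brute_force_multiset_count(k, n))
  }
  for (s in 0:3) {
    reg <- make_basic_registry(with_variant = TRUE)
    rules <- assembly_rules(oligomer_states = 3L,
                            max_variant_substitutions = c(alpha_variant = s))
    expect_length(enumerate_compositions(reg, rules), s + 1L)
  }
})

test_that("enumeration is deterministic and label-sorted", {
  reg <- make_inventory(seed = 5L, n_sources = 2L,
                        variants_per_family = c(alpha_variant = 1L))
  r1 <- enumerate_compositions(reg, assembly_rules())
  r2 <- enumerate_compositions(reg, assembly_rules())
  l1 <- vapply(r1, `[[`, character(1L), "label")
  expect_identical(l1, vapply(r2, `[[`, character(1L), "label"))
  expect_identical(l1, sort(l1, method = "radix"))
  expect_false(anyDuplicated(l1) > 0L)
})

test_that("labels are canonical: sorted by role then id, counts appended", {
  reg <- make_basic_registry(with_variant = TRUE, with_linker = TRUE)
  members <- c(b = 3L, aB = 2L, a = 1L, Lc = 1L)
  expect_identical(composition_label(members, reg), "a.aB2.b3+Lc")
  # label is invariant to member ordering
  expect_identical(composition_label(rev(members), reg), "a.aB2.b3+Lc")
})

test_that("FASTA and PTM-table readers round-trip an inventory", {
  fa <- tempfile(fileext = ".fasta")
  reg <- make_inventory(seed = 3L, variants_per_family = c(beta_variant = 1L),
                        include_linker = TRUE, fasta = fa)
  ptm_path <- tempfile(fileext = ".tsv")
  write.table(
    data.frame(subunit_id = c("a", "b", "b"),
               ptm_name = c("PCB", "PCB", "methylation"),
               delta_mass = c(586.7, 586.7, 14),
               count = c(1L, 2L, 1L)),
    ptm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  reg2 <- read_subunit_fasta(fa, ptms = read_ptm_rules(ptm_path))
  expect_setequal(names(reg2), names(reg))
  expect_identical(reg2[["a"]]$sequence, reg[["a"]]$sequence)
  expect_identical(reg2[["b18"]]$role, "beta_variant")
  # the PTM table drives the mass adjustment
  expect_equal(resolve_subunit_mass(reg2[["a"]]),
               sequence_average_mass(reg[["a"]]$sequence) + 586.7)
  expect_equal(resolve_subunit_mass(reg2[["b"]]),
               sequence_average_mass(reg[["b"]]$sequence) + 2 * 586.7 + 14)
})

test_that("assembly-rules config files parse", {
  path <- tempfile()
  writeLines(c("oligomer_states = 1,3,6",
               "max_variant_substitutions = alpha_variant:2, beta_variant:1",
               "linker_max_copies = 2",
               "allow_cross_family_protomers = FALSE",
               "# comment"), path)
  rules <- read_assembly_rules(path)
  expect_identical(rules$oligomer_states, c(1L, 3L, 6L))
  expect_identical(rules$max_variant_substitutions[["alpha_variant"]], 2L)
  expect_identical(rules$linker_max_copies, 2L)
  expect_false(rules$allow_cross_family_protomers)
  writeLines("no_such_key = 1", path)
  expect_error(read_assembly_rules(path), "unknown")
})
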