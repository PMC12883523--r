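#' Post-translational modification rule
#'
#' A named mass adjustment applied `count` times to a subunit's sequence mass.
#' Typical phycobiliprotein rules: phycocyanobilin chromophore attachment
#' (+586.7 Da per adduct), loss of the initiator methionine (-131.2 Da),
#' and Asn methylation (+14 Da).
#'
#' @param name Free-text label for the modification.
#' @param delta_mass Signed mass delta in Da; must be finite.
#' @param count Non-negative integer number of applications.
#' @return An object of class `ptm_rule`.
#' @export
ptm_rule <- function(name, delta_mass, count = 1L) {
  stopifnot(is.character(name), length(name) == 1L)
  delta_mass <- as.numeric(delta_mass)
  if (length(delta_mass) != 1L || !is.finite(delta_mass))
    stop("'delta_mass' must be a single finite number")
  count <- as.integer(count)
  if (length(count) != 1L || is.na(count) || count < 0L)
    stop("'count' must be a single non-negative integer")
  structure(list(name = name, delta_mass = delta_mass, count = count),
            class = "ptm_rule")
}

SUBUNIT_ROLES <- c("alpha", "beta", "alpha_variant", "beta_variant", "linker")

#' Phycobiliprotein subunit specification
#'
#' A named polypeptide with either an amino-acid sequence or a fixed mass
#' (exactly one of the two), a structural role within the complex, and a list
#' of PTM rules. `family` distinguishes pigment families (e.g. "PC" vs "APC")
#' and `species` the source organism; both drive the assembly rules during
#' composition enumeration.
#'
#' @param id Short unique label (e.g. "apcA", "a1").
#' @param species Source organism, free text.
#' @param role One of `"alpha"`, `"beta"`, `"alpha_variant"`, `"beta_variant"`,
#'   `"linker"`.
#' @param sequence Amino-acid sequence (canonical residues); mutually exclusive
#'   with `fixed_mass`.
#' @param fixed_mass Direct subunit mass in Da; mutually exclusive with
#'   `sequence`.
#' @param ptms List of [ptm_rule()] objects.
#' @param family Pigment family label, free text (default `""`).
#' @return An object of class `subunit_spec`.
#' @export
subunit_spec <- function(id, species = "", role, sequence = NULL,
                         fixed_mass = NULL, ptms = list(), family = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  role <- match.arg(role, SUBUNIT_ROLES)
  if (is.null(sequence) == is.null(fixed_mass))
    stop("exactly one of 'sequence' or 'fixed_mass' must be given")
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    bad <- which(!(residues %in% names(RESIDUE_AVERAGE_MASS)))
    if (length(bad))
      stop(sprintf("subunit '%s': unknown residue '%s' at position %d",
                   id, residues[bad[1L]], bad[1L]))
  }
  if (!is.null(fixed_mass)) {
    fixed_mass <- as.numeric(fixed_mass)
    if (!is.finite(fixed_mass) || fixed_mass <= 0)
      stop("'fixed_mass' must be a positive finite number")
  }
  if (inherits(ptms, "ptm_rule")) ptms <- list(ptms)
  if (!all(vapply(ptms, inherits, logical(1L), "ptm_rule")))
    stop("'ptms' must be a list of ptm_rule objects")
  obj <- structure(
    list(id = id, species = species, family = family, role = role,
         sequence = sequence, fixed_mass = fixed_mass, ptms = ptms),
    class = "subunit_spec")
  if (resolve_subunit_mass(obj) <= 0)
    stop(sprintf("subunit '%s': resolved mass must be positive", id))
  obj
}

#' @export
print.subunit_spec <- function(x, ...) {
  cat(sprintf("<subunit_spec> %s  role=%s  species=%s%s  mass=%.2f Da  (%d PTM rule%s)\n",
              x$id, x$role, x$species,
              if (nzchar(x$family)) paste0("/", x$family) else "",
              resolve_subunit_mass(x), length(x$ptms),
              if (length(x$ptms) == 1L) "" else "s"))
  invisible(x)
}

#' PTM-adjusted mass of a subunit
#'
#' Resolves the subunit base mass (fixed mass if given, otherwise the average
#' mass computed from the sequence) and applies every PTM rule as
#' `count * delta_mass`. This mirrors how theoretical phycobiliprotein masses
#' are adjusted for chromophore attachment, initiator-Met loss and Asn
#' methylation before comparison with native-MS measurements.
#'
#' @param subunit A [subunit_spec()].
#' @return Adjusted mass in Da.
#' @examples
#' pcb <- ptm_rule("PCB", 586.7, 1)
#' s <- subunit_spec("a", role = "alpha", fixed_mass = 17000, ptms = list(pcb))
#' resolve_subunit_mass(s)  # 17586.7
#' @export
resolve_subunit_mass <- function(subunit) {
  if (!inherits(subunit, "subunit_spec"))
    stop("'subunit' must be a subunit_spec")
  base <- if (!is.null(subunit$fixed_mass)) subunit$fixed_mass
          else sequence_average_mass(subunit$sequence)
  if (length(subunit$ptms)) {
    base <- base + sum(vapply(subunit$ptms,
                              function(p) p$count * p$delta_mass, numeric(1L)))
  }
  base
}

#' Build a subunit registry
#'
#' @param ... [subunit_spec()] objects, or a single list of them.
#' @return Named list of subunits keyed by id (class `subunit_registry`).
#' @export
subunit_registry <- function(...) {
  subs <- list(...)
  if (length(subs) == 1L && is.list(subs[[1L]]) &&
      !inherits(subs[[1L]], "subunit_spec"))
    subs <- subs[[1L]]
  if (!all(vapply(subs, inherits, logical(1L), "subunit_spec")))
    stop("all elements must be subunit_spec objects")
  ids <- vapply(subs, `[[`, character(1L), "id")
  if (anyDuplicated(ids))
    stop("duplicate subunit ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(stats::setNames(subs, ids), class = "subunit_registry")
}

#' Read subunit sequences from FASTA
#'
#' The description line is parsed as `id|species|role` with optional fourth
#' field `family` (pipe-separated). Sequences must use canonical residues.
#'
#' @param path FASTA file path.
#' @param ptms Optional named list mapping subunit id to a list of
#'   [ptm_rule()]s (e.g. from [read_ptm_rules()]).
#' @return A `subunit_registry`.
#' @export
read_subunit_fasta <- function(path, ptms = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  subs <- lapply(seq_along(seqs), function(i) {
    fields <- strsplit(trimws(names(seqs)[i]), "|", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("FASTA record %d: header must be 'id|species|role[|family]'", i))
    id <- trimws(fields[1L])
    rules <- if (!is.null(ptms) && id %in% names(ptms)) ptms[[id]] else list()
    subunit_spec(id = id, species = trimws(fields[2L]),
                 role = trimws(fields[3L]),
                 family = if (length(fields) >= 4L) trimws(fields[4L]) else "",
                 sequence = as.character(seqs[[i]]), ptms = rules)
  })
  subunit_registry(subs)
}

#' Write subunit sequences to FASTA
#'
#' Inverse of [read_subunit_fasta()]; only sequence-bearing subunits are
#' written. Headers are `id|species|role|family`.
#'
#' @param registry A `subunit_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subunit_fasta <- function(registry, path) {
  lines <- character(0L)
  for (s in registry) {
    if (is.null(s$sequence)) next
    lines <- c(lines,
               sprintf(">%s|%s|%s|%s", s$id, s$species, s$role, s$family),
               s$sequence)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the PTM rules of a registry as TSV
#'
#' Emits the `subunit_id`, `ptm_name`, `delta_mass`, `count` table that
#' [read_ptm_rules()] accepts, so a registry built in code (e.g. by
#' [make_inventory()]) can round-trip through the file interfaces.
#'
#' @param registry A `subunit_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ptm_rules <- function(registry, path) {
  rows <- list()
  for (s in registry) for (p in s$ptms)
    rows[[length(rows) + 1L]] <- data.frame(
      subunit_id = s$id, ptm_name = p$name,
      delta_mass = p$delta_mass, count = p$count)
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subunit_id = character(0L), ptm_name = character(0L),
               delta_mass = numeric(0L), count = integer(0L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read PTM rules from TSV
#'
#' Expected columns: `subunit_id`, `ptm_name`, `delta_mass`, `count`.
#'
#' @param path TSV file path.
#' @return Named list: subunit id -> list of [ptm_rule()].
#' @export
read_ptm_rules <- function(path) {
  if (!file.exists(path)) stop("PTM table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subunit_id", "ptm_name", "delta_mass", "count")
  if (!all(need %in% names(df)))
    stop("PTM table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(df))) {
    r <- ptm_rule(df$ptm_name[i], df$delta_mass[i], df$count[i])
    id <- as.character(df$subunit_id[i])
    out[[id]] <- c(out[[id]], list(r))
  }
  out
}
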