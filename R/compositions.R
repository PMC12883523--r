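ROLE_ORDER <- c(alpha = 1L, alpha_variant = 2L, beta = 3L, beta_variant = 4L,
                linker = 9L)

#' Canonical label for a complex composition
#'
#' Members are sorted by (role, id); each non-linker member contributes a token
#' `id` (copy 1) or `id<k>` (copy k), joined by `.`; linkers are appended as
#' `+id` tokens. The label is a deterministic function of the member multiset,
#' so it is safe to join on across reports.
#'
#' @param members Named integer vector: subunit id -> copy number.
#' @param registry A `subunit_registry` supplying roles.
#' @return Character scalar label, e.g. `"aB2.a1.b3+ApcC"`.
#' @export
composition_label <- function(members, registry) {
  ids <- names(members)
  roles <- vapply(ids, function(i) registry[[i]]$role, character(1L))
  ord <- order(ROLE_ORDER[roles], ids, method = "radix")
  ids <- ids[ord]; roles <- roles[ord]; counts <- as.integer(members[ord])
  tok <- ifelse(counts > 1L, paste0(ids, counts), ids)
  core <- tok[roles != "linker"]
  link <- tok[roles == "linker"]
  paste0(paste(core, collapse = "."),
         if (length(link)) paste0("+", paste(link, collapse = "+")) else "")
}

#' Complex composition: a multiset of subunits with a theoretical mass
#'
#' @param members Named integer vector of copy numbers (subunit id -> copies);
#'   total copy number must be >= 1.
#' @param registry A `subunit_registry`; all member ids must be present.
#' @return An object of class `complex_composition` with fields `members`,
#'   `label` and `theoretical_mass` (the sum of member PTM-adjusted masses; a
#'   non-covalent assembly adds no binding-induced mass change).
#' @export
complex_composition <- function(members, registry) {
  if (length(members) == 0L || sum(members) < 1L)
    stop("empty composition: total copy number must be >= 1")
  members <- members[members > 0L]
  storage.mode(members) <- "integer"
  missing <- setdiff(names(members), names(registry))
  if (length(missing))
    stop("unknown subunit id(s): ", paste(missing, collapse = ", "))
  structure(
    list(members = members,
         label = composition_label(members, registry),
         theoretical_mass = composition_mass_raw(members, registry)),
    class = "complex_composition")
}

composition_mass_raw <- function(members, registry) {
  sum(vapply(names(members),
             function(i) members[[i]] * resolve_subunit_mass(registry[[i]]),
             numeric(1L)))
}

#' Theoretical mass of a composition
#'
#' @param composition A `complex_composition` (or a bare named copy-number
#'   vector).
#' @param registry A `subunit_registry`.
#' @return Mass in Da.
#' @export
composition_mass <- function(composition, registry) {
  members <- if (inherits(composition, "complex_composition"))
    composition$members else composition
  if (length(members) == 0L || sum(members) < 1L)
    stop("empty composition: total copy number must be >= 1")
  missing <- setdiff(names(members), names(registry))
  if (length(missing))
    stop("unknown subunit id(s): ", paste(missing, collapse = ", "))
  composition_mass_raw(members, registry)
}

#' @export
print.complex_composition <- function(x, ...) {
  cat(sprintf("<complex_composition> %s  M = %.2f Da\n", x$label,
              x$theoretical_mass))
  invisible(x)
}

#' Assembly rules for composition enumeration
#'
#' Encodes which complexes are considered chemically plausible candidates:
#' which oligomer states occur, how many copies of a minor variant may
#' substitute for its cognate subunit, whether alpha-beta protomers from
#' different source organisms or different pigment families may co-occupy one
#' ring, and how linker proteins attach.
#'
#' Cross mixing flags default to permissive so that the *absence* of a hybrid
#' in data is an empirical finding rather than a modelling assumption.
#'
#' @param oligomer_states Integer set of protomer counts per complex
#'   (default `c(1, 3)`: free alpha-beta pairs and trimeric rings).
#' @param max_variant_substitutions Named integer map role -> maximum copies
#'   (default `alpha_variant = 3`, `beta_variant = 1`).
#' @param linker_max_copies Maximum copies of each linker per complex.
#' @param linker_min_oligomer Minimum oligomer state that can carry a linker
#'   (default 3: linkers decorate rings, not free pairs).
#' @param allow_cross_source_protomers Allow protomers from different source
#'   organisms in one ring.
#' @param allow_cross_family_protomers Allow protomers from different pigment
#'   families (e.g. PC and APC) in one ring.
#' @param allow_cross_pairs Also enumerate crossed alpha-beta pairs (alpha of
#'   one source/family with beta of another) as protomer types; off by
#'   default, matching the convention that mixing acts on whole protomers.
#' @return An object of class `assembly_rules`.
#' @export
assembly_rules <- function(oligomer_states = c(1L, 3L),
                           max_variant_substitutions = c(alpha_variant = 3L,
                                                         beta_variant = 1L),
                           linker_max_copies = 1L,
                           linker_min_oligomer = 3L,
                           allow_cross_source_protomers = TRUE,
                           allow_cross_family_protomers = TRUE,
                           allow_cross_pairs = FALSE) {
  oligomer_states <- sort(unique(as.integer(oligomer_states)))
  if (length(oligomer_states) == 0L || any(oligomer_states < 1L))
    stop("'oligomer_states' must be a non-empty set of positive integers")
  mvs <- c(alpha_variant = 3L, beta_variant = 1L)
  if (length(max_variant_substitutions)) {
    v <- as.integer(max_variant_substitutions)
    names(v) <- names(max_variant_substitutions)
    if (any(v < 0L)) stop("variant substitution caps must be >= 0")
    mvs[names(v)] <- v
  }
  linker_max_copies <- as.integer(linker_max_copies)
  if (linker_max_copies < 0L) stop("'linker_max_copies' must be >= 0")
  structure(list(oligomer_states = oligomer_states,
                 max_variant_substitutions = mvs,
                 linker_max_copies = linker_max_copies,
                 linker_min_oligomer = as.integer(linker_min_oligomer),
                 allow_cross_source_protomers = isTRUE(allow_cross_source_protomers),
                 allow_cross_family_protomers = isTRUE(allow_cross_family_protomers),
                 allow_cross_pairs = isTRUE(allow_cross_pairs)),
            class = "assembly_rules")
}

#' Read assembly rules from a flat key=value config file
#'
#' Recognised keys match the arguments of [assembly_rules()];
#' `oligomer_states` is comma-separated; `max_variant_substitutions` uses
#' `role:count` pairs separated by commas. Unknown keys are an error.
#'
#' @param path Config file path.
#' @return An `assembly_rules` object.
#' @export
read_assembly_rules <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1L), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1L)))
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- switch(k,
      oligomer_states = as.integer(strsplit(v, ",")[[1L]]),
      max_variant_substitutions = {
        pairs <- strsplit(strsplit(v, ",")[[1L]], ":")
        stats::setNames(as.integer(vapply(pairs, `[`, character(1L), 2L)),
                        trimws(vapply(pairs, `[`, character(1L), 1L)))
      },
      linker_max_copies = as.integer(v),
      linker_min_oligomer = as.integer(v),
      allow_cross_source_protomers = as.logical(v),
      allow_cross_family_protomers = as.logical(v),
      allow_cross_pairs = as.logical(v),
      stop("unknown assembly-rules key: ", k))
  }
  do.call(assembly_rules, args)
}

# all multisets of size n over k types, as an n-row index matrix per multiset
multisets_of_size <- function(k, n) {
  if (n == 0L) return(list(integer(0L)))
  out <- list()
  recurse <- function(prefix, start, left) {
    if (left == 0L) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (t in start:k) recurse(c(prefix, t), t, left - 1L)
  }
  recurse(integer(0L), 1L, n)
  out
}

#' Enumerate candidate complex compositions
#'
#' Builds alpha-beta protomer types from the inventory (variant subunits
#' pairing like their cognate role), then for every oligomer state enumerates
#' every protomer multiset allowed by the rules, applies variant-copy caps and
#' cross-source/cross-family co-occupancy constraints, and finally decorates
#' rings with 0..`linker_max_copies` copies of each linker. Output is
#' deduplicated by label and label-sorted, hence deterministic.
#'
#' @param inventory A `subunit_registry` (or list of [subunit_spec()]s) with at
#'   least one alpha-role and one beta-role subunit per source family.
#' @param rules An [assembly_rules()] object.
#' @return List of `complex_composition` objects sorted by label.
#' @export
enumerate_compositions <- function(inventory, rules = assembly_rules()) {
  if (!inherits(inventory, "subunit_registry"))
    inventory <- subunit_registry(inventory)
  roles <- vapply(inventory, `[[`, character(1L), "role")
  grp <- stats::setNames(
    paste(vapply(inventory, `[[`, character(1L), "species"),
          vapply(inventory, `[[`, character(1L), "family"), sep = "\r"),
    names(inventory))
  alphas <- names(inventory)[roles %in% c("alpha", "alpha_variant")]
  betas  <- names(inventory)[roles %in% c("beta", "beta_variant")]
  linkers <- names(inventory)[roles == "linker"]
  for (g in unique(grp[roles != "linker"])) {
    if (!any(grp[alphas] == g & roles[alphas] == "alpha") ||
        !any(grp[betas] == g & roles[betas] == "beta"))
      stop("each source family needs at least one alpha and one beta subunit")
  }

  # protomer types: (alpha-like, beta-like) pairs
  prot <- list()
  for (a in alphas) for (b in betas) {
    same <- grp[[a]] == grp[[b]]
    if (same || rules$allow_cross_pairs) {
      prot[[length(prot) + 1L]] <- list(
        a = a, b = b,
        sources = unique(c(inventory[[a]]$species, inventory[[b]]$species)),
        families = unique(c(inventory[[a]]$family, inventory[[b]]$family)))
    }
  }
  if (!length(prot)) stop("no protomer types can be formed from this inventory")

  variant_ids <- names(inventory)[roles %in% c("alpha_variant", "beta_variant")]
  caps <- rules$max_variant_substitutions

  out <- list()
  seen <- character(0L)
  add <- function(members) {
    comp <- complex_composition(members, inventory)
    if (!(comp$label %in% seen)) {
      seen <<- c(seen, comp$label)
      out[[length(out) + 1L]] <<- comp
    }
  }

  for (n in rules$oligomer_states) {
    for (ms in multisets_of_size(length(prot), n)) {
      types <- prot[unique(ms)]
      srcs <- unique(unlist(lapply(types, `[[`, "sources")))
      fams <- unique(unlist(lapply(types, `[[`, "families")))
      if (length(srcs) > 1L && !rules$allow_cross_source_protomers) next
      if (length(fams) > 1L && !rules$allow_cross_family_protomers) next
      ids <- unlist(lapply(prot[ms], function(p) c(p$a, p$b)))
      members <- table(ids)
      members <- stats::setNames(as.integer(members), names(members))
      ok <- TRUE
      for (v in variant_ids) {
        cnt <- if (v %in% names(members)) members[[v]] else 0L
        if (cnt > caps[[roles[[v]]]]) { ok <- FALSE; break }
      }
      if (!ok) next
      add(members)
      if (length(linkers) && n >= rules$linker_min_oligomer &&
          rules$linker_max_copies > 0L) {
        copy_opts <- lapply(linkers, function(l) 0:rules$linker_max_copies)
        combos <- do.call(expand.grid, copy_opts)
        for (r in seq_len(nrow(combos))) {
          lk <- stats::setNames(as.integer(combos[r, ]), linkers)
          lk <- lk[lk > 0L]
          if (!length(lk)) next
          add(c(members, lk))
        }
      }
    }
  }
  labels <- vapply(out, `[[`, character(1L), "label")
  out[order(labels, method = "radix")]
}

#' Tabulate compositions
#'
#' @param compositions List of `complex_composition` objects.
#' @return data.frame with columns `label`, `members` (id:count tokens) and
#'   `theoretical_mass`.
#' @export
composition_table <- function(compositions) {
  data.frame(
    label = vapply(compositions, `[[`, character(1L), "label"),
    members = vapply(compositions, function(cc)
      paste(sprintf("%s:%d", names(cc$members), cc$members), collapse = ","),
      character(1L)),
    theoretical_mass = vapply(compositions, `[[`, numeric(1L),
                              "theoretical_mass"),
    stringsAsFactors = FALSE)
}

#' Write a composition table as TSV
#'
#' @param compositions List of `complex_composition` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(compositions, path) {
  utils::write.table(composition_table(compositions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
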