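aa_alphabet <- function() names(RESIDUE_AVERAGE_MASS)

validate_protein <- function(x, arg) {
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    stop("'", arg, "' must be a non-empty sequence")
  x <- toupper(x)
  residues <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!(residues %in% aa_alphabet()))
  if (length(bad))
    stop(sprintf("'%s': invalid residue '%s' at position %d",
                 arg, residues[bad[1L]], bad[1L]))
  x
}

default_scoring <- function() {
  list(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5)
}

scoring_matrix <- function(scoring) {
  if (!is.null(scoring$matrix)) {
    env <- new.env()
    utils::data(list = scoring$matrix, package = "Biostrings", envir = env)
    return(get(scoring$matrix, envir = env))
  }
  aa <- aa_alphabet()
  m <- matrix(scoring$mismatch, length(aa), length(aa),
              dimnames = list(aa, aa))
  diag(m) <- scoring$match
  m
}

#' Global pairwise alignment with percent identity
#'
#' Optimal global (Needleman-Wunsch) alignment under affine gap penalties,
#' delegated to `Biostrings::pairwiseAlignment`. The default scoring —
#' BLOSUM62 substitution with gap open 10 / gap extend 0.5 — follows the
#' classic ClustalW protein defaults, since for two sequences ClustalW reduces
#' to a pairwise global alignment. A gap run of length L costs
#' `gap_open + L * gap_extend`.
#'
#' Percent identity is `100 * n_identical / alignment_length` where the
#' denominator includes gap columns; `denominator = "shorter"` divides by the
#' shorter sequence length instead (both conventions are in circulation).
#'
#' @param a,b Amino-acid sequences (canonical residues).
#' @param scoring List: either `matrix` (name of a substitution matrix shipped
#'   with Biostrings, e.g. `"BLOSUM62"`) or `match`/`mismatch` scores, plus
#'   `gap_open` and `gap_extend` penalties (positive numbers).
#' @param id_a,id_b Labels carried into the result.
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return Object of class `identity_result`: `id_a`, `id_b`, `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score`, `n_identical`,
#'   `alignment_length`, `percent_identity`.
#' @export
global_align <- function(a, b, scoring = default_scoring(),
                         id_a = "a", id_b = "b",
                         denominator = c("alignment", "shorter")) {
  a <- validate_protein(a, "a"); b <- validate_protein(b, "b")
  denominator <- match.arg(denominator)
  scoring <- utils::modifyList(default_scoring(), scoring)
  if (!is.null(scoring$match)) scoring$matrix <- NULL
  subst <- scoring_matrix(scoring)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = subst,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(ga, "", fixed = TRUE)[[1L]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1L]]
  n_ident <- sum(ca == cb & ca != "-")
  alen <- length(ca)
  denom <- if (denominator == "alignment") alen
           else min(nchar(a), nchar(b))
  structure(list(id_a = id_a, id_b = id_b,
                 aligned_a = ga, aligned_b = gb,
                 score = Biostrings::score(aln),
                 n_identical = n_ident, alignment_length = alen,
                 percent_identity = 100 * n_ident / denom),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("<identity_result> %s vs %s: %.1f%% identity (%d/%d), score %.1f\n",
              x$id_a, x$id_b, x$percent_identity, x$n_identical,
              x$alignment_length, x$score))
  invisible(x)
}

#' All-vs-all percent identity matrix
#'
#' @param sequences Named character vector (or `subunit_registry`) of at least
#'   two sequences.
#' @param ... Passed to [global_align()].
#' @return Symmetric numeric matrix of percent identities with 100 on the
#'   diagonal, dimnames from the input names.
#' @export
identity_matrix <- function(sequences, ...) {
  if (inherits(sequences, "subunit_registry"))
    sequences <- vapply(sequences, function(s) {
      if (is.null(s$sequence)) stop("subunit '", s$id, "' has no sequence")
      s$sequence
    }, character(1L))
  n <- length(sequences)
  if (n < 2L) stop("need at least 2 sequences")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- global_align(sequences[[i]], sequences[[j]],
                      id_a = names(sequences)[i], id_b = names(sequences)[j],
                      ...)
    m[i, j] <- m[j, i] <- r$percent_identity
  }
  m
}

#' Write a pairwise alignment in CLUSTAL-like text format
#'
#' @param result An `identity_result`.
#' @param path Output path.
#' @param width Residues per block.
#' @return `path`, invisibly.
#' @export
write_clustal <- function(result, path, width = 60L) {
  lines <- c("CLUSTAL format alignment (pairwise)", "")
  alen <- result$alignment_length
  ca <- strsplit(result$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(result$aligned_b, "", fixed = TRUE)[[1L]]
  cons <- ifelse(ca == cb & ca != "-", "*", " ")
  namew <- max(nchar(result$id_a), nchar(result$id_b)) + 3L
  for (start in seq(1L, alen, by = width)) {
    idx <- start:min(start + width - 1L, alen)
    lines <- c(lines,
      paste0(formatC(result$id_a, width = -namew),
             paste(ca[idx], collapse = "")),
      paste0(formatC(result$id_b, width = -namew),
             paste(cb[idx], collapse = "")),
      paste0(strrep(" ", namew), paste(cons[idx], collapse = "")),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}
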