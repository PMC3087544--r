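#' Affine-gap scoring scheme
#'
#' Holds the four alignment scores used by the global and local aligners. A
#' gap of length k costs `gap_open + (k - 1) * gap_extend`, so a single-base
#' gap costs `gap_open` alone. The default is a megablast-like scheme
#' (match +1, mismatch -2, gap open -5, gap extend -2).
#'
#' @param match Score for a matching column (> 0).
#' @param mismatch Score for a mismatching column (< 0).
#' @param gap_open Score for opening a gap (<= 0).
#' @param gap_extend Score for each additional gapped column (<= 0).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = -5,
                           gap_extend = -2) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

# IUPAC code sets; two symbols match when their base sets intersect
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# substitution matrix over the full IUPAC alphabet for a scoring scheme
iupac_substitution_matrix <- function(scheme) {
  nm <- names(iupac_sets)
  mat <- matrix(scheme$mismatch, length(nm), length(nm),
                dimnames = list(nm, nm))
  for (i in nm) {
    for (j in nm) {
      if (length(intersect(iupac_sets[[i]], iupac_sets[[j]])) > 0) {
        mat[i, j] <- scheme$match
      }
    }
  }
  mat
}

# Biostrings expresses a length-k gap as gapOpening + k * gapExtension
biostrings_gap_args <- function(scheme) {
  list(gapOpening = -(scheme$gap_open - scheme$gap_extend),
       gapExtension = -scheme$gap_extend)
}

check_ungapped <- function(..., what = "sequence") {
  for (s in list(...)) {
    if (length(s) != 1 || is.na(s) || !nzchar(s)) {
      stop("empty ", what)
    }
    if (grepl("-", s, fixed = TRUE)) {
      stop(what, " must be ungapped")
    }
  }
  invisible(TRUE)
}

#' Optimal global pairwise alignment (Needleman-Wunsch)
#'
#' Aligns two ungapped DNA sequences end to end under the affine-gap scheme.
#' IUPAC ambiguity codes score as a match when the two symbols' base sets
#' intersect, as a mismatch otherwise. The underlying dynamic program is
#' deterministic, so repeated calls return the identical alignment.
#'
#' @param a,b Ungapped IUPAC DNA strings.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `aligned_pair`: a list with gapped strings
#'   `seq_a` and `seq_b` (equal length, no column gap in both) and the
#'   alignment `score`.
#' @export
needleman_wunsch <- function(a, b, scheme = scoring_scheme()) {
  check_ungapped(a, b)
  gaps <- biostrings_gap_args(scheme)
  aln <- Biostrings::pairwiseAlignment(
    a, b,
    type = "global",
    substitutionMatrix = iupac_substitution_matrix(scheme),
    gapOpening = gaps$gapOpening, gapExtension = gaps$gapExtension
  )
  structure(
    list(seq_a = as.character(Biostrings::alignedPattern(aln)),
         seq_b = as.character(Biostrings::alignedSubject(aln)),
         score = Biostrings::score(aln)),
    class = "aligned_pair"
  )
}

#' Maximal local alignment score (Smith-Waterman)
#'
#' Exact local alignment score of a query against one or more subjects under
#' the affine-gap scheme; the best-hit surrogate used for BLAST1-style
#' identification. Returns 0 when no positive-scoring segment exists.
#'
#' @param query Ungapped IUPAC DNA string.
#' @param subject Character vector of ungapped IUPAC DNA strings.
#' @param scheme A [scoring_scheme()].
#' @return Numeric vector of local alignment scores, one per subject.
#' @export
smith_waterman_score <- function(query, subject, scheme = scoring_scheme()) {
  check_ungapped(query)
  for (s in subject) check_ungapped(s)
  gaps <- biostrings_gap_args(scheme)
  scores <- Biostrings::pairwiseAlignment(
    Biostrings::BStringSet(subject), query,
    type = "local",
    substitutionMatrix = iupac_substitution_matrix(scheme),
    gapOpening = gaps$gapOpening, gapExtension = gaps$gapExtension,
    scoreOnly = TRUE
  )
  pmax(scores, 0)
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("aligned_pair (score ", x$score, ")\n", sep = "")
  cat("  ", x$seq_a, "\n  ", x$seq_b, "\n", sep = "")
  invisible(x)
}
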