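#' Build a nucleotide profile HMM from a training alignment
#'
#' Constructs a match/insert/delete profile (Durbin-style architecture) from
#' aligned training sequences, e.g. curated fungal ITS2 sequences for a
#' contaminant screen. Alignment columns whose gap fraction is below
#' `gap_column_threshold` become match states; the remaining columns are
#' treated as insertions. Match emissions are Laplace-smoothed column
#' counts; insert states emit the background distribution (smoothed overall
#' residue frequencies of the training set). Transition probabilities are
#' estimated from the observed state paths of the training sequences with
#' `pseudocount` added to every structurally allowed transition.
#'
#' @param training A record `data.frame` or character vector of equal-length
#'   aligned sequences (gap character `-`), at least two.
#' @param gap_column_threshold Columns with a gap fraction at or above this
#'   value are insert columns. Default 0.5.
#' @param pseudocount Laplace weight for emissions and transitions.
#' @return An object of class `profile_hmm` with elements
#'   `n_match_states`, `match_emissions` (k x 4 probabilities over ACGT),
#'   `insert_emissions`, `background`, and `transitions` (list of matrices
#'   `M`, `I`, `D`, rows = source position, columns = destination type
#'   `M`/`I`/`D`; disallowed transitions have probability 0).
#' @export
build_profile_hmm <- function(training, gap_column_threshold = 0.5,
                              pseudocount = 1) {
  seqs <- if (is.data.frame(training)) training$sequence else training
  if (length(seqs) < 2) {
    stop("need at least two aligned training sequences")
  }
  if (length(unique(nchar(seqs))) != 1) {
    stop("training sequences must be aligned to equal length")
  }
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  gap_frac <- colMeans(chars == "-")
  is_match <- gap_frac < gap_column_threshold
  k <- sum(is_match)
  if (k == 0L) {
    stop("no column qualifies as a match state at threshold ",
         gap_column_threshold)
  }
  # background: smoothed residue frequencies over the whole training set
  resid <- chars[chars != "-"]
  bg_counts <- vapply(bases, function(b) sum(resid == b), numeric(1))
  background <- (bg_counts + pseudocount) / (sum(bg_counts) + 4 * pseudocount)
  # match emissions per match column
  match_cols <- which(is_match)
  match_emissions <- t(vapply(match_cols, function(col) {
    cc <- vapply(bases, function(b) sum(chars[, col] == b), numeric(1))
    (cc + pseudocount) / (sum(cc) + 4 * pseudocount)
  }, numeric(4)))
  colnames(match_emissions) <- bases
  # transition counts from observed state paths
  # rows: M has k+1 rows (positions 0..k, 0 = begin), I has k+1 (0..k),
  # D has k rows (1..k); the "M" column at position k means "to end"
  allowed <- function(nrows, no_D_last) {
    m <- matrix(pseudocount, nrows, 3, dimnames = list(NULL, c("M", "I", "D")))
    if (no_D_last) m[nrows, "D"] <- 0
    m
  }
  cnt <- list(M = allowed(k + 1, TRUE), I = allowed(k + 1, TRUE),
              D = if (k >= 1) allowed(k, TRUE) else NULL)
  col_type <- ifelse(is_match, "match", "insert")
  for (s in seq_along(seqs)) {
    state <- "M"   # begin treated as M at position 0
    pos <- 0L
    row <- chars[s, ]
    for (col in seq_along(row)) {
      if (col_type[col] == "match") {
        to <- if (row[col] == "-") "D" else "M"
        cnt[[state]][pos + rowoff(state), to] <-
          cnt[[state]][pos + rowoff(state), to] + 1
        state <- to
        pos <- pos + 1L
      } else if (row[col] != "-") {
        cnt[[state]][pos + rowoff(state), "I"] <-
          cnt[[state]][pos + rowoff(state), "I"] + 1
        state <- "I"
      }
    }
    cnt[[state]][pos + rowoff(state), "M"] <-
      cnt[[state]][pos + rowoff(state), "M"] + 1   # to end
  }
  transitions <- lapply(cnt, function(m) {
    if (is.null(m)) return(NULL)
    sweep(m, 1, rowSums(m), "/")
  })
  structure(
    list(n_match_states = k, match_emissions = match_emissions,
         insert_emissions = background, background = background,
         transitions = transitions,
         gap_column_threshold = gap_column_threshold,
         pseudocount = pseudocount),
    class = "profile_hmm"
  )
}

# row offset: M/I matrices carry position 0 in row 1; D starts at position 1
rowoff <- function(state) if (state == "D") 0L else 1L

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm: %d match states\n", x$n_match_states))
  invisible(x)
}

# emission log-odds (and log-probs) for one symbol; IUPAC codes marginalize
emission_prob <- function(probs, symbol) {
  set <- iupac_sets[[symbol]]
  if (is.null(set)) {
    stop("symbol outside the IUPAC alphabet: ", symbol)
  }
  mean(probs[set])
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Forward log-odds score of a sequence against a profile HMM
#'
#' Computes `log2(P(seq | profile) / P(seq | background))` with the forward
#' algorithm, summing over all state paths. In `"global"` mode the whole
#' sequence must pass through the whole profile (begin to end). In
#' `"local"` mode (default, suited to fragment-like contaminants) the model
#' may enter at any match state (uniform weight `1/k`) and leave after any
#' match state; flanking residues are emitted by the background model, so
#' they cancel in the log-odds.
#'
#' @param hmm A [build_profile_hmm()] profile.
#' @param seq Ungapped IUPAC DNA string.
#' @param mode `"local"` (default) or `"global"`.
#' @param algorithm `"forward"` (default; sums over paths) or `"viterbi"`
#'   (best single path; always `<=` the forward score).
#' @return Log-odds score in bits.
#' @export
forward_log_odds <- function(hmm, seq, mode = c("local", "global"),
                             algorithm = c("forward", "viterbi")) {
  mode <- match.arg(mode)
  algorithm <- match.arg(algorithm)
  viterbi <- algorithm == "viterbi"
  check_ungapped(seq)
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  k <- hmm$n_match_states
  tr <- lapply(hmm$transitions, log)
  # per-position emission log-probabilities at match states and background
  lem <- vapply(x, function(s) {
    vapply(seq_len(k), function(j) {
      log(emission_prob(hmm$match_emissions[j, ], s))
    }, numeric(1))
  }, numeric(k))
  lem <- matrix(lem, nrow = k)
  lbg <- vapply(x, function(s) log(emission_prob(hmm$background, s)),
                numeric(1))
  if (mode == "local") {
    em <- sweep(lem, 2, lbg)   # emission log-odds; inserts cancel
    .profile_forward_local(em, tr$M, tr$I, tr$D, viterbi) / log(2)
  } else {
    lp <- .profile_forward_global(lem, lbg, tr$M, tr$I, tr$D, viterbi)
    (lp - sum(lbg)) / log(2)
  }
}

#' Screen records against a contaminant profile
#'
#' Scores every record with [forward_log_odds()] and separates those
#' resembling the profile (score at or above `threshold_bits`) from the
#' rest, mirroring an HMM-based fungal-contamination filter. Two scoring
#' modes are offered: by default the score is the absolute log-odds against
#' the background model; when a `null_hmm` is supplied (e.g. a profile
#' trained on curated target-taxon sequences) the score is the competitive
#' log-odds `bits(contaminant profile) - bits(null profile)`, which asks
#' which family the record resembles more and is far more discriminative
#' when the two families are only moderately diverged.
#'
#' @param records A record `data.frame`.
#' @param hmm A [build_profile_hmm()] contaminant profile.
#' @param threshold_bits Records scoring `>=` this value (bits) are
#'   flagged. Default 0.
#' @param mode Scoring mode passed to [forward_log_odds()].
#' @param null_hmm Optional second profile for competitive scoring.
#' @return A list with `kept` and `flagged` record `data.frame`s, each with
#'   an added `score_bits` column.
#' @export
screen_contaminants <- function(records, hmm, threshold_bits = 0,
                                mode = "local", null_hmm = NULL) {
  if (nrow(records) == 0L) {
    records$score_bits <- numeric(0)
    return(list(kept = records, flagged = records))
  }
  scores <- vapply(records$sequence, function(s) {
    s <- gsub("-", "", s, fixed = TRUE)
    b <- forward_log_odds(hmm, s, mode = mode)
    if (!is.null(null_hmm)) {
      b <- b - forward_log_odds(null_hmm, s, mode = mode)
    }
    b
  }, numeric(1), USE.NAMES = FALSE)
  records$score_bits <- scores
  flag <- scores >= threshold_bits
  list(kept = records[!flag, , drop = FALSE],
       flagged = records[flag, , drop = FALSE])
}
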