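#' Count site patterns from an aligned pair
#'
#' Classifies every alignment column for Kimura 2-parameter estimation using
#' complete-pair deletion: columns where either symbol is a gap or is not one
#' of A, C, G, T are excluded from the comparable length `L`. Transitions are
#' the purine and pyrimidine exchanges (A<->G, C<->T); every other differing
#' pair is a transversion.
#'
#' @param pair An `aligned_pair` (see [needleman_wunsch()]) or a list with
#'   equal-length gapped strings `seq_a` and `seq_b`.
#' @return A list of class `site_counts` with `L` (comparable sites), `n_ts`
#'   (transitions), `n_tv` (transversions), and the proportions `P = n_ts/L`
#'   and `Q = n_tv/L` (both `NaN` when `L = 0`).
#' @export
count_site_patterns <- function(pair) {
  a <- strsplit(pair$seq_a, "", fixed = TRUE)[[1]]
  b <- strsplit(pair$seq_b, "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) {
    stop("aligned sequences must have equal length")
  }
  acgt <- c("A", "C", "G", "T")
  ok <- a %in% acgt & b %in% acgt
  a <- a[ok]
  b <- b[ok]
  L <- length(a)
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  n_ts <- sum(ts)
  n_tv <- sum(diff) - n_ts
  structure(
    list(L = L, n_ts = n_ts, n_tv = n_tv, P = n_ts / L, Q = n_tv / L),
    class = "site_counts"
  )
}

#' Kimura 2-parameter distance from site counts
#'
#' Evaluates `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with `P` and `Q` the
#' transition and transversion proportions. The distance is undefined
#' (returned as `NA`) when there are no comparable sites or when divergence
#' saturates the logarithms (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`).
#'
#' @param counts A `site_counts` object from [count_site_patterns()].
#' @return The K2P distance in substitutions per site, or `NA_real_` when
#'   undefined.
#' @export
k2p_distance <- function(counts) {
  if (counts$L == 0L) {
    return(NA_real_)
  }
  P <- counts$P
  Q <- counts$Q
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(NA_real_)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix for a dataset
#'
#' Computes all unordered pairwise K2P distances. In `"pairwise-global"` mode
#' (the default, self-contained) every pair is aligned with
#' [needleman_wunsch()] before counting; in `"pre-aligned"` mode the stored
#' sequences must already form a multiple alignment of equal length and are
#' compared column-wise (complete-pair deletion per pair). Undefined
#' distances are kept as `NA`, never coerced to zero.
#'
#' @param dataset A [barcode_dataset()].
#' @param mode `"pairwise-global"` or `"pre-aligned"`.
#' @param scheme Scoring scheme for pairwise-global mode.
#' @return A symmetric numeric matrix with zero diagonal, record ids as
#'   dimnames, `NA` for undefined entries, and attributes `mode`, `scheme`
#'   and `n_undefined`.
#' @export
distance_matrix <- function(dataset,
                            mode = c("pairwise-global", "pre-aligned"),
                            scheme = scoring_scheme()) {
  mode <- match.arg(mode)
  rec <- dataset$records
  n <- nrow(rec)
  ids <- rec$record_id
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  if (mode == "pre-aligned" && n > 1 &&
      length(unique(nchar(rec$sequence))) != 1) {
    stop("pre-aligned mode requires equal-length (gapped) sequences")
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        pair <- if (mode == "pre-aligned") {
          list(seq_a = rec$sequence[i], seq_b = rec$sequence[j])
        } else {
          needleman_wunsch(gsub("-", "", rec$sequence[i], fixed = TRUE),
                           gsub("-", "", rec$sequence[j], fixed = TRUE),
                           scheme)
        }
        d[i, j] <- d[j, i] <- k2p_distance(count_site_patterns(pair))
      }
    }
  }
  attr(d, "mode") <- mode
  attr(d, "scheme") <- scheme
  attr(d, "n_undefined") <- sum(is.na(d[upper.tri(d)]))
  d
}

#' Write a distance matrix as square TSV
#'
#' @param d A distance matrix from [distance_matrix()].
#' @param path Output path; undefined entries are written as `NA`.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(d, path) {
  out <- data.frame(record_id = rownames(d), d, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
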