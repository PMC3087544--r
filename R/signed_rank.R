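#' Paired per-genus divergence vectors for two markers
#'
#' Builds the paired observations for a signed-rank comparison of two
#' markers: the per-genus mean inter-specific distances, restricted to genera
#' qualifying (at least two species, at least one defined pair) in both
#' markers. The pairing order (genus names) is recorded.
#'
#' @param metrics_a,metrics_b `inter_metrics` for the two markers (see
#'   [interspecific_metrics()]).
#' @return A list with numeric vectors `x` and `y` (marker a and b) and the
#'   character vector `genera` giving the pairing order.
#' @export
paired_divergence_vectors <- function(metrics_a, metrics_b) {
  pa <- metrics_a$per_genus
  pb <- metrics_b$per_genus
  pa <- pa[pa$n_pairs > 0, , drop = FALSE]
  pb <- pb[pb$n_pairs > 0, , drop = FALSE]
  shared <- sort(intersect(pa$genus, pb$genus))
  if (length(shared) == 0L) {
    stop("no genus qualifies for both markers; markers cannot be paired")
  }
  list(
    x = pa$mean[match(shared, pa$genus)],
    y = pb$mean[match(shared, pb$genus)],
    genera = shared
  )
}

#' Wilcoxon signed-rank test for paired marker divergences
#'
#' Computes the signed-rank statistics W+ and W- from paired values. Zero
#' differences are dropped before ranking; absolute differences receive
#' midranks in case of ties. The default p-value uses the two-sided normal
#' approximation `z = (W+ - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` without
#' continuity correction and without tie correction (set
#' `tie_correction = TRUE` to subtract the tie term from the variance).
#' `method = "exact"` enumerates the full null distribution of W+ over all
#' 2^n sign assignments (allowed for n <= 25; ties handled by enumerating
#' the observed midranks).
#'
#' @param x,y Equal-length numeric vectors of paired values.
#' @param method `"normal-approx"` (default) or `"exact"`.
#' @param tie_correction Apply the rank-tie variance correction in the
#'   normal approximation? Default `FALSE`.
#' @param alpha Significance level used only to call the `direction` verdict.
#' @return A list of class `rank_test_result` with `W_plus`, `W_minus`, `n`
#'   (non-zero differences), `z` (`NA` for exact), `p_two_sided`,
#'   `direction` (`"first > second"`, `"second > first"` or `"equal"`) and
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 method = c("normal-approx", "exact"),
                                 tie_correction = FALSE, alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(
      list(W_plus = 0, W_minus = 0, n = 0L, z = NA_real_, p_two_sided = 1,
           direction = "equal", method = method),
      class = "rank_test_result"
    ))
  }
  r <- rank(abs(d))
  W_plus <- sum(r[d > 0])
  W_minus <- sum(r[d < 0])
  if (method == "normal-approx") {
    mu <- n * (n + 1) / 4
    v <- n * (n + 1) * (2 * n + 1) / 24
    if (tie_correction) {
      ties <- table(r)
      v <- v - sum(ties^3 - ties) / 48
    }
    z <- (W_plus - mu) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  } else {
    if (n > 25) {
      stop("exact enumeration limited to n <= 25")
    }
    z <- NA_real_
    p <- exact_signed_rank_pvalue(W_plus, r)
  }
  direction <- if (p >= alpha) {
    "equal"
  } else if (W_plus > W_minus) {
    "first > second"
  } else {
    "second > first"
  }
  structure(
    list(W_plus = W_plus, W_minus = W_minus, n = n, z = z, p_two_sided = p,
         direction = direction, method = method),
    class = "rank_test_result"
  )
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W+ = %g, W- = %g, n = %d, p = %.4g [%s]\n",
              x$method, x$W_plus, x$W_minus, x$n, x$p_two_sided, x$direction))
  invisible(x)
}

# two-sided exact p over all 2^n sign assignments of the observed midranks,
# by dynamic-programming convolution (midranks doubled to stay integer)
exact_signed_rank_pvalue <- function(W_plus, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # counts[w + 1] = number of sign vectors with doubled W+ equal to w
  counts <- c(1, rep(0, total))
  for (rk in r2) {
    shifted <- c(rep(0, rk), counts[seq_len(total + 1 - rk)])
    counts <- counts + shifted
  }
  w2 <- as.integer(round(2 * W_plus))
  p_ge <- sum(counts[(w2 + 1):(total + 1)]) / 2^length(r2)
  p_le <- sum(counts[1:(w2 + 1)]) / 2^length(r2)
  min(1, 2 * min(p_ge, p_le))
}

#' Exact two-sided p-value for the tie-free signed-rank null
#'
#' Validation oracle for the normal approximation: the exact two-sided tail
#' probability of W+ under the symmetric null distribution over untied ranks
#' 1..n (via the exact signed-rank distribution).
#'
#' @param W Observed rank sum W+ (0 <= W <= n(n+1)/2).
#' @param n Number of non-zero differences (1 <= n <= 25).
#' @return Two-sided exact p-value.
#' @export
exact_null_pvalue <- function(W, n) {
  if (n < 1 || n > 25) {
    stop("n must be between 1 and 25")
  }
  if (W < 0 || W > n * (n + 1) / 2) {
    stop("W must lie in [0, n(n+1)/2]")
  }
  p_ge <- 1 - stats::psignrank(W - 1, n)
  p_le <- stats::psignrank(W, n)
  min(1, 2 * min(p_ge, p_le))
}

#' Pairwise signed-rank comparison table across markers
#'
#' Runs [wilcoxon_signed_rank()] on every unordered pair of markers using
#' per-genus mean inter-specific distances, yielding one row per pair with
#' the W statistics, n, p and a verdict at `alpha`.
#'
#' @param inter_list Named list, marker -> `inter_metrics`.
#' @param method Passed to [wilcoxon_signed_rank()].
#' @param alpha Significance level for the verdict column.
#' @return A `data.frame` with columns `marker_a`, `marker_b`, `W_plus`,
#'   `W_minus`, `n`, `p`, `verdict` (e.g. `"A>B"`, `"A=B"`).
#' @export
wilcoxon_table <- function(inter_list, method = "normal-approx",
                           alpha = 0.05) {
  markers <- names(inter_list)
  rows <- list()
  if (length(markers) >= 2) {
    for (i in seq_len(length(markers) - 1)) {
      for (j in seq((i + 1), length(markers))) {
        pv <- paired_divergence_vectors(inter_list[[i]], inter_list[[j]])
        res <- wilcoxon_signed_rank(pv$x, pv$y, method = method,
                                    alpha = alpha)
        verdict <- switch(res$direction,
                          "first > second" = "A>B",
                          "second > first" = "B>A",
                          "A=B")
        rows[[length(rows) + 1]] <- data.frame(
          marker_a = markers[i], marker_b = markers[j],
          W_plus = res$W_plus, W_minus = res$W_minus, n = res$n,
          p = res$p_two_sided, verdict = verdict, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(marker_a = character(0), marker_b = character(0),
                      W_plus = numeric(0), W_minus = numeric(0),
                      n = integer(0), p = numeric(0),
                      verdict = character(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
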