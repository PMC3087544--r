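#' Intra-specific divergence metrics
#'
#' Computes the three intra-specific summaries of a barcoding-gap analysis
#' over all species sampled more than once: the pooled average intra-specific
#' K2P distance over all conspecific pairs, theta (the mean of per-species
#' mean pairwise distances, which removes unequal-sampling bias), and the
#' average coalescent depth (the mean of per-species maximum pairwise
#' distances). Undefined distances are skipped and counted.
#'
#' @param d A distance matrix from [distance_matrix()].
#' @param dataset The [barcode_dataset()] the matrix was computed from.
#' @return A list of class `intra_metrics` with `avg_intra`, `theta`,
#'   `avg_coalescent_depth` (all `NA` when no species qualifies),
#'   `per_species` (data.frame: species, mean, max, n_pairs), `n_species`
#'   (qualifying species count) and `n_undefined` (skipped pairs).
#' @export
intraspecific_metrics <- function(d, dataset) {
  groups <- dataset$species_index
  groups <- groups[lengths(groups) >= 2]
  per <- group_pair_stats(d, lapply(groups, function(ids) list(ids)))
  pooled <- attr(per, "pooled")
  qual <- per[per$n_pairs > 0, , drop = FALSE]
  structure(
    list(
      avg_intra = if (length(pooled)) mean(pooled) else NA_real_,
      theta = if (nrow(qual)) mean(qual$mean) else NA_real_,
      avg_coalescent_depth = if (nrow(qual)) mean(qual$max) else NA_real_,
      per_species = data.frame(species = per$group, mean = per$mean,
                               max = per$max, n_pairs = per$n_pairs,
                               stringsAsFactors = FALSE),
      n_species = nrow(qual),
      n_undefined = attr(per, "n_undefined")
    ),
    class = "intra_metrics"
  )
}

#' Inter-specific divergence metrics
#'
#' Computes the three inter-specific summaries over all genera holding at
#' least two species: the pooled average inter-specific K2P distance over all
#' heterospecific record pairs within a genus, theta prime (the mean of
#' per-genus mean distances, which removes unequal-species-count bias), and
#' the mean of per-genus minimum inter-specific distances (the smallest
#' inter-specific distance). Pairs are taken at the individual level; by
#' default conspecific pairs inside a genus are excluded
#' (`include_conspecific = TRUE` gives the all-pairs variant of theta prime).
#'
#' @param d A distance matrix from [distance_matrix()].
#' @param dataset The [barcode_dataset()] the matrix was computed from.
#' @param include_conspecific Also pool conspecific pairs within each genus?
#'   Default `FALSE`.
#' @return A list of class `inter_metrics` with `avg_inter`, `theta_prime`,
#'   `min_inter` (all `NA` when no genus qualifies), `per_genus`
#'   (data.frame: genus, mean, min, n_pairs), `n_genera` and `n_undefined`.
#' @export
interspecific_metrics <- function(d, dataset, include_conspecific = FALSE) {
  rec <- dataset$records
  sp_of <- stats::setNames(rec$species, rec$record_id)
  groups <- dataset$genus_index
  multi <- vapply(groups, function(ids) length(unique(sp_of[ids])) >= 2,
                  logical(1))
  groups <- groups[multi]
  specs <- lapply(groups, function(ids) {
    list(ids, if (include_conspecific) NULL else sp_of[ids])
  })
  per <- group_pair_stats(d, specs, stat2 = "min")
  pooled <- attr(per, "pooled")
  qual <- per[per$n_pairs > 0, , drop = FALSE]
  structure(
    list(
      avg_inter = if (length(pooled)) mean(pooled) else NA_real_,
      theta_prime = if (nrow(qual)) mean(qual$mean) else NA_real_,
      min_inter = if (nrow(qual)) mean(qual$min) else NA_real_,
      per_genus = data.frame(genus = per$group, mean = per$mean,
                             min = per$min, n_pairs = per$n_pairs,
                             stringsAsFactors = FALSE),
      n_genera = nrow(qual),
      n_undefined = attr(per, "n_undefined")
    ),
    class = "inter_metrics"
  )
}

# shared per-group pair statistics; spec[[1]] = ids, spec[[2]] = optional
# species labels (pairs sharing a label are excluded)
group_pair_stats <- function(d, specs, stat2 = c("max", "min")) {
  stat2 <- match.arg(stat2)
  f2 <- if (stat2 == "max") max else min
  pooled <- numeric(0)
  n_undefined <- 0L
  rows <- lapply(names(specs), function(g) {
    ids <- specs[[g]][[1]]
    labels <- if (length(specs[[g]]) >= 2) specs[[g]][[2]] else NULL
    sub <- d[ids, ids, drop = FALSE]
    keep <- upper.tri(sub)
    if (!is.null(labels)) {
      keep <- keep & outer(labels, labels, "!=")
    }
    vals <- sub[keep]
    n_undefined <<- n_undefined + sum(is.na(vals))
    vals <- vals[!is.na(vals)]
    pooled <<- c(pooled, vals)
    data.frame(group = g,
               mean = if (length(vals)) mean(vals) else NA_real_,
               stat2 = if (length(vals)) f2(vals) else NA_real_,
               n_pairs = length(vals), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(group = character(0), mean = numeric(0),
               stat2 = numeric(0), n_pairs = integer(0))
  }
  names(out)[names(out) == "stat2"] <- stat2
  attr(out, "pooled") <- pooled
  attr(out, "n_undefined") <- n_undefined
  out
}

#' Divergence summary table across markers
#'
#' One row per marker with the six divergence metrics plus the qualifying
#' group and pair counts.
#'
#' @param metrics A named list, marker -> list(intra = `intra_metrics`,
#'   inter = `inter_metrics`).
#' @return A `data.frame` with columns `marker`, `avg_intra`, `theta`,
#'   `avg_coalescent_depth`, `avg_inter`, `theta_prime`, `min_inter`,
#'   `n_species`, `n_genera`, `n_intra_pairs`, `n_inter_pairs`.
#' @export
divergence_table <- function(metrics) {
  rows <- lapply(names(metrics), function(m) {
    x <- metrics[[m]]
    data.frame(
      marker = m,
      avg_intra = x$intra$avg_intra,
      theta = x$intra$theta,
      avg_coalescent_depth = x$intra$avg_coalescent_depth,
      avg_inter = x$inter$avg_inter,
      theta_prime = x$inter$theta_prime,
      min_inter = x$inter$min_inter,
      n_species = x$intra$n_species,
      n_genera = x$inter$n_genera,
      n_intra_pairs = sum(x$intra$per_species$n_pairs),
      n_inter_pairs = sum(x$inter$per_genus$n_pairs),
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(marker = character(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
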