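#' Best-hit (BLAST1-style) species identification of one query
#'
#' Assigns the query to the species of its best local-alignment hit in the
#' reference set. In `"self-inclusive"` mode the query's own record remains
#' in the database; `"leave-one-out"` removes it first. All references tied
#' at the maximal score form the best-hit set: the assignment is the unique
#' species of that set, or `"ambiguous"` when the set spans several species
#' (ties count as failures). A correct species assignment requires every
#' best hit to be conspecific with the query; genus-level correctness
#' likewise requires every best hit to share the query's genus.
#'
#' @param query_id Record id of the query (must be in `db`).
#' @param db A [barcode_dataset()] serving as reference database.
#' @param mode `"self-inclusive"` (default) or `"leave-one-out"`.
#' @param scheme Scoring scheme for the local aligner.
#' @return A list of class `assignment` with `query_id`, `method`,
#'   `best_refs`, `assigned_species`, `species_correct`, `genus_correct`.
#' @export
blast1_identify <- function(query_id, db,
                            mode = c("self-inclusive", "leave-one-out"),
                            scheme = scoring_scheme()) {
  mode <- match.arg(mode)
  rec <- db$records
  qi <- match(query_id, rec$record_id)
  if (is.na(qi)) {
    stop("query ", query_id, " not found in database")
  }
  refs <- if (mode == "leave-one-out") rec[-qi, , drop = FALSE] else rec
  if (nrow(refs) == 0L) {
    stop("leave-one-out leaves an empty database")
  }
  query_seq <- gsub("-", "", rec$sequence[qi], fixed = TRUE)
  ref_seqs <- gsub("-", "", refs$sequence, fixed = TRUE)
  scores <- smith_waterman_score(query_seq, ref_seqs, scheme)
  best <- refs[scores == max(scores), , drop = FALSE]
  finalize_assignment(query_id, "BLAST1", best,
                      rec$species[qi], rec$genus[qi])
}

#' Nearest-distance species identification of one query
#'
#' Assigns the query to the species of the reference(s) at minimal K2P
#' distance, with the same tie-failure convention as [blast1_identify()].
#' Undefined distances are treated as infinite; when every distance is
#' undefined the assignment is `"ambiguous"` and flagged.
#'
#' @param query_id Record id of the query.
#' @param db A [barcode_dataset()].
#' @param d A distance matrix covering the database records.
#' @param mode `"self-inclusive"` (default) or `"leave-one-out"`.
#' @return An `assignment` list; the element `all_undefined` is `TRUE` when
#'   no reference had a defined distance.
#' @export
nearest_distance_identify <- function(query_id, db, d,
                                      mode = c("self-inclusive",
                                               "leave-one-out")) {
  mode <- match.arg(mode)
  rec <- db$records
  qi <- match(query_id, rec$record_id)
  if (is.na(qi)) {
    stop("query ", query_id, " not found in database")
  }
  refs <- if (mode == "leave-one-out") rec[-qi, , drop = FALSE] else rec
  if (nrow(refs) == 0L) {
    stop("leave-one-out leaves an empty database")
  }
  dist <- d[query_id, refs$record_id]
  dist[is.na(dist)] <- Inf
  if (all(is.infinite(dist))) {
    out <- finalize_assignment(query_id, "distance", refs,
                               rec$species[qi], rec$genus[qi],
                               force_ambiguous = TRUE)
    out$all_undefined <- TRUE
    return(out)
  }
  best <- refs[dist == min(dist), , drop = FALSE]
  out <- finalize_assignment(query_id, "distance", best,
                             rec$species[qi], rec$genus[qi])
  out$all_undefined <- FALSE
  out
}

finalize_assignment <- function(query_id, method, best, true_species,
                                true_genus, force_ambiguous = FALSE) {
  sp <- unique(best$species)
  ge <- unique(best$genus)
  ambiguous <- force_ambiguous || length(sp) > 1
  structure(
    list(
      query_id = query_id,
      method = method,
      best_refs = best$record_id,
      assigned_species = if (ambiguous) "ambiguous" else sp,
      species_correct = !ambiguous && identical(sp, true_species),
      genus_correct = !force_ambiguous && length(ge) == 1 &&
        identical(ge, true_genus)
    ),
    class = "assignment"
  )
}

#' Evaluate identification success over a whole dataset
#'
#' Queries every record of the dataset in turn with the chosen method and
#' aggregates species- and genus-level success rates overall and per genus.
#'
#' @param db A [barcode_dataset()] with at least two records.
#' @param method `"BLAST1"` or `"distance"`.
#' @param mode `"self-inclusive"` (default) or `"leave-one-out"`.
#' @param scheme Scoring scheme (BLAST1 method).
#' @param d Optional precomputed distance matrix (distance method); computed
#'   with [distance_matrix()] defaults when missing.
#' @param align_mode Alignment mode for the distance matrix when it has to
#'   be computed here.
#' @return A list of class `identification_report` with `method`, `mode`,
#'   `n_queries`, `species_rate` and `genus_rate` (percent),
#'   `per_genus_rates` (data.frame: genus, n, species_rate, genus_rate) and
#'   `assignments` (one row per query).
#' @export
evaluate_identification <- function(db, method = c("BLAST1", "distance"),
                                    mode = c("self-inclusive",
                                             "leave-one-out"),
                                    scheme = scoring_scheme(), d = NULL,
                                    align_mode = "pairwise-global") {
  method <- match.arg(method)
  mode <- match.arg(mode)
  rec <- db$records
  if (nrow(rec) < 2) {
    stop("identification needs at least two records")
  }
  if (method == "distance" && is.null(d)) {
    d <- distance_matrix(db, mode = align_mode, scheme = scheme)
  }
  assignments <- lapply(rec$record_id, function(id) {
    a <- if (method == "BLAST1") {
      blast1_identify(id, db, mode = mode, scheme = scheme)
    } else {
      nearest_distance_identify(id, db, d, mode = mode)
    }
    data.frame(query_id = a$query_id,
               assigned_species = a$assigned_species,
               n_best = length(a$best_refs),
               species_correct = a$species_correct,
               genus_correct = a$genus_correct,
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, c(assignments, list(make.row.names = FALSE)))
  per_genus <- do.call(rbind, lapply(split(seq_len(nrow(rec)), rec$genus),
    function(idx) {
      data.frame(
        genus = rec$genus[idx[1]],
        n = length(idx),
        species_rate = 100 * mean(assignments$species_correct[idx]),
        genus_rate = 100 * mean(assignments$genus_correct[idx]),
        stringsAsFactors = FALSE
      )
    }))
  rownames(per_genus) <- NULL
  structure(
    list(
      method = method, mode = mode, n_queries = nrow(rec),
      species_rate = 100 * mean(assignments$species_correct),
      genus_rate = 100 * mean(assignments$genus_correct),
      per_genus_rates = per_genus,
      assignments = assignments
    ),
    class = "identification_report"
  )
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("identification_report: %s, %s, %d queries\n",
              x$method, x$mode, x$n_queries))
  cat(sprintf("  species-level success: %.1f%%\n", x$species_rate))
  cat(sprintf("  genus-level success:   %.1f%%\n", x$genus_rate))
  invisible(x)
}

#' Traffic-light combination of markers
#'
#' Evaluates a marker combination on the biological samples sequenced for
#' every member marker: a sample is identified by the combination if any
#' member marker identifies it (at the species level, respectively genus
#' level). Samples missing from any member marker are excluded.
#'
#' @param reports Named list, marker -> `identification_report`.
#' @param sample_map A `data.frame` with columns `sample_id`, `marker`,
#'   `record_id` linking the same biological sample across markers.
#' @return A list of class `combination_report` with `member_markers`,
#'   `n_common_samples`, `species_rate` and `genus_rate` (percent).
#' @export
combine_markers <- function(reports, sample_map) {
  markers <- names(reports)
  stopifnot(length(markers) >= 2)
  per_marker <- lapply(markers, function(m) {
    map <- sample_map[sample_map$marker == m, , drop = FALSE]
    a <- reports[[m]]$assignments
    idx <- match(map$record_id, a$query_id)
    data.frame(sample_id = map$sample_id,
               species_correct = a$species_correct[idx],
               genus_correct = a$genus_correct[idx],
               stringsAsFactors = FALSE)
  })
  common <- Reduce(intersect, lapply(per_marker, `[[`, "sample_id"))
  if (length(common) == 0L) {
    stop("no sample is sequenced for all member markers")
  }
  sp_ok <- rep(FALSE, length(common))
  ge_ok <- rep(FALSE, length(common))
  for (pm in per_marker) {
    idx <- match(common, pm$sample_id)
    sp_ok <- sp_ok | pm$species_correct[idx]
    ge_ok <- ge_ok | pm$genus_correct[idx]
  }
  structure(
    list(
      member_markers = markers,
      n_common_samples = length(common),
      species_rate = 100 * mean(sp_ok),
      genus_rate = 100 * mean(ge_ok)
    ),
    class = "combination_report"
  )
}
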