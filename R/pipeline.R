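#' Run the full marker-evaluation pipeline
#'
#' Orchestrates every stage of a barcode-marker evaluation on one or more
#' markers: quality filtering, dataset composition summary, K2P distance
#' matrices, the six divergence metrics, pairwise Wilcoxon signed-rank
#' comparison of markers, BLAST1 and nearest-distance identification with
#' species/genus success rates, traffic-light combinations of all marker
#' pairs, and (optionally) the profile-HMM contaminant screen. Every
#' artifact is written as plain TSV/JSON into `out_dir` together with a
#' provenance record (configuration, seed, package version).
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{markers}{named list, marker -> FASTA path, or marker ->
#'       [sim_config()] for simulated input (mixing is allowed).}
#'     \item{header_scheme}{FASTA header scheme (default `"pipe"`).}
#'     \item{min_len, max_ambig, drop_unnamed}{filter thresholds (defaults
#'       100, 15, `TRUE`).}
#'     \item{align_mode}{`"pairwise-global"` (default) or `"pre-aligned"`.}
#'     \item{id_mode}{`"self-inclusive"` (default) or `"leave-one-out"`.}
#'     \item{wilcoxon_method}{`"normal-approx"` (default) or `"exact"`.}
#'     \item{scheme}{a [scoring_scheme()].}
#'     \item{screen}{optional list with `training` (aligned FASTA path or
#'       record data.frame) and `threshold_bits`.}
#'     \item{out_dir}{output directory (created if missing).}
#'     \item{seed}{integer seed for simulated markers.}
#'   }
#' @return Invisibly, a list with all in-memory results (`datasets`,
#'   `filter_reports`, `summaries`, `distances`, `metrics`,
#'   `divergence_table`, `wilcoxon_table`, `identification`,
#'   `combinations`, `screen`) plus `artifacts` (the written file paths).
#' @export
run_full_evaluation <- function(config) {
  defaults <- list(header_scheme = "pipe", min_len = 100L, max_ambig = 15L,
                   drop_unnamed = TRUE, align_mode = "pairwise-global",
                   id_mode = "self-inclusive",
                   wilcoxon_method = "normal-approx",
                   scheme = scoring_scheme(), screen = NULL,
                   out_dir = tempfile("barcodeval_run_"), seed = 1)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$markers) || length(config$markers) == 0L) {
    stop("stage 'input': config$markers must name at least one marker")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    write_tsv_report(x, path)
    artifacts[[name]] <<- path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- input + filtering ---------------------------------------------------
  datasets <- list()
  filter_reports <- list()
  summaries <- list()
  for (m in names(config$markers)) {
    src <- config$markers[[m]]
    records <- stage("input", {
      if (inherits(src, "sim_config")) {
        src$seed <- substream_seed(config$seed, paste0("marker_", m))
        simulate_dataset(src, marker = m)$records
      } else {
        read_barcode_fasta(src, marker = m,
                           header_scheme = config$header_scheme)
      }
    })
    fr <- stage("filter", quality_filter(records, config$min_len,
                                         config$max_ambig,
                                         config$drop_unnamed))
    filter_reports[[m]] <- fr$report
    datasets[[m]] <- barcode_dataset(fr$kept, marker = m)
    summaries[[m]] <- dataset_summary(datasets[[m]])
  }
  emit(do.call(rbind, lapply(names(filter_reports), function(m) {
    data.frame(marker = m, as.data.frame(unclass(filter_reports[[m]])))
  })), "filter_report.tsv")
  emit(do.call(rbind, lapply(names(summaries), function(m) {
    data.frame(marker = m, as.data.frame(summaries[[m]]))
  })), "dataset_summary.tsv")

  # --- optional contaminant screen ----------------------------------------
  screen_result <- NULL
  if (!is.null(config$screen)) {
    screen_result <- stage("screen", {
      tr <- config$screen$training
      if (is.character(tr)) {
        tr <- read_barcode_fasta(tr, marker = "training",
                                 header_scheme = config$header_scheme)
      }
      hmm <- build_profile_hmm(tr)
      thr <- if (is.null(config$screen$threshold_bits)) 0 else
        config$screen$threshold_bits
      out <- lapply(datasets, function(ds) {
        sc <- screen_contaminants(ds$records, hmm, threshold_bits = thr)
        sc
      })
      for (m in names(out)) {
        datasets[[m]] <- barcode_dataset(out[[m]]$kept[, setdiff(
          names(out[[m]]$kept), "score_bits")], marker = m)
      }
      flagged <- do.call(rbind, lapply(names(out), function(m) {
        f <- out[[m]]$flagged
        if (nrow(f)) data.frame(marker = m, record_id = f$record_id,
                                score_bits = f$score_bits) else NULL
      }))
      if (is.null(flagged)) {
        flagged <- data.frame(marker = character(0),
                              record_id = character(0),
                              score_bits = numeric(0))
      }
      emit(flagged, "contaminant_flags.tsv")
      out
    })
  }

  # --- distances + divergence metrics -------------------------------------
  distances <- list()
  metrics <- list()
  for (m in names(datasets)) {
    distances[[m]] <- stage("distances",
      distance_matrix(datasets[[m]], mode = config$align_mode,
                      scheme = config$scheme))
    metrics[[m]] <- stage("metrics", list(
      intra = intraspecific_metrics(distances[[m]], datasets[[m]]),
      inter = interspecific_metrics(distances[[m]], datasets[[m]])
    ))
  }
  div_table <- divergence_table(metrics)
  emit(div_table, "divergence_table.tsv")

  # --- signed-rank marker comparison --------------------------------------
  wtab <- stage("wilcoxon", {
    if (length(metrics) >= 2) {
      wilcoxon_table(lapply(metrics, `[[`, "inter"),
                     method = config$wilcoxon_method)
    } else {
      wilcoxon_table(list())
    }
  })
  emit(wtab, "wilcoxon_table.tsv")

  # --- identification ------------------------------------------------------
  id_reports <- list()
  id_rows <- list()
  for (m in names(datasets)) {
    for (method in c("BLAST1", "distance")) {
      rep <- stage("identify",
        evaluate_identification(datasets[[m]], method = method,
                                mode = config$id_mode,
                                scheme = config$scheme,
                                d = distances[[m]]))
      id_reports[[m]][[method]] <- rep
      id_rows[[length(id_rows) + 1]] <- data.frame(
        marker = m, method = method, mode = rep$mode,
        n_queries = rep$n_queries, species_rate = rep$species_rate,
        genus_rate = rep$genus_rate, stringsAsFactors = FALSE)
    }
  }
  emit(do.call(rbind, c(id_rows, list(make.row.names = FALSE))),
       "identification_report.tsv")

  # --- traffic-light combinations (all marker pairs, per method) ----------
  comb_rows <- list()
  combinations <- list()
  ms <- names(datasets)
  if (length(ms) >= 2) {
    sample_map <- do.call(rbind, lapply(ms, function(m) {
      data.frame(sample_id = datasets[[m]]$records$record_id, marker = m,
                 record_id = datasets[[m]]$records$record_id,
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_len(length(ms) - 1)) {
      for (j in seq((i + 1), length(ms))) {
        for (method in c("BLAST1", "distance")) {
          cr <- stage("combine", combine_markers(
            stats::setNames(list(id_reports[[ms[i]]][[method]],
                                 id_reports[[ms[j]]][[method]]),
                            c(ms[i], ms[j])),
            sample_map))
          combinations[[paste(ms[i], ms[j], method, sep = "+")]] <- cr
          comb_rows[[length(comb_rows) + 1]] <- data.frame(
            combination = paste(ms[i], ms[j], sep = "+"), method = method,
            n_common_samples = cr$n_common_samples,
            species_rate = cr$species_rate, genus_rate = cr$genus_rate,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  emit(if (length(comb_rows)) {
    do.call(rbind, c(comb_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(combination = character(0), method = character(0),
               n_common_samples = integer(0), species_rate = numeric(0),
               genus_rate = numeric(0))
  }, "combination_report.tsv")

  # --- provenance ----------------------------------------------------------
  prov <- list(
    package = "barcodeval",
    version = as.character(utils::packageVersion("barcodeval")),
    seed = config$seed,
    align_mode = config$align_mode,
    id_mode = config$id_mode,
    wilcoxon_method = config$wilcoxon_method,
    filter = list(min_len = config$min_len, max_ambig = config$max_ambig,
                  drop_unnamed = config$drop_unnamed),
    scheme = unclass(config$scheme),
    markers = names(config$markers)
  )
  prov_path <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA)
  artifacts[["provenance.json"]] <- prov_path

  invisible(list(
    datasets = datasets, filter_reports = filter_reports,
    summaries = summaries, distances = distances, metrics = metrics,
    divergence_table = div_table, wilcoxon_table = wtab,
    identification = id_reports, combinations = combinations,
    screen = screen_result, artifacts = artifacts
  ))
}
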