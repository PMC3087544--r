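#' Read taxonomy-annotated barcode sequences from FASTA
#'
#' Parses a multi-FASTA file whose headers carry a record identifier plus a
#' Latin binomial, and returns one row per sequence. Two header schemes are
#' built in: `"pipe"` expects `id|Genus species` and `"whitespace"` expects
#' `id Genus species`. Sequences are uppercased and RNA `U` is mapped to `T`;
#' no quality filtering happens here (see [quality_filter()]).
#'
#' @param path Path to a FASTA file (plain or aligned; gap character `-`).
#' @param marker Marker name attached to every record (e.g. `"ITS2"`,
#'   `"rbcL"`). Free-form; used only for labelling.
#' @param header_scheme Either the name of a built-in scheme (`"pipe"` or
#'   `"whitespace"`) or a regular expression with exactly two capture groups,
#'   the first matching the record id and the second the binomial.
#' @return A `data.frame` of barcode records with columns `record_id`,
#'   `marker`, `genus`, `species`, `sequence`. `genus` is the first
#'   whitespace-delimited token of `species`.
#' @seealso [write_barcode_fasta()] for the inverse operation.
#' @export
read_barcode_fasta <- function(path, marker = "marker",
                               header_scheme = c("pipe", "whitespace")) {
  if (is.character(header_scheme) && length(header_scheme) == 1 &&
      !header_scheme %in% c("pipe", "whitespace")) {
    pattern <- header_scheme
  } else {
    pattern <- switch(match.arg(header_scheme),
      pipe       = "^([^|]+)\\|(\\S+\\s+\\S.*)$",
      whitespace = "^(\\S+)\\s+(\\S+\\s+\\S.*)$"
    )
  }
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(seqs)
  if (any(is.na(headers) | headers == "")) {
    stop("FASTA entry ", which(is.na(headers) | headers == "")[1],
         " has an empty header")
  }
  empty <- Biostrings::width(seqs) == 0
  if (any(empty)) {
    stop("FASTA entry with empty sequence: '", headers[which(empty)[1]], "'")
  }
  m <- regmatches(headers, regexec(pattern, headers))
  bad <- lengths(m) != 3
  if (any(bad)) {
    stop("FASTA header(s) not matching the header scheme: ",
         paste(sQuote(headers[bad]), collapse = ", "))
  }
  ids <- vapply(m, `[`, character(1), 2)
  binomials <- trimws(vapply(m, `[`, character(1), 3))
  seq_chr <- chartr("u", "t", as.character(seqs))
  seq_chr <- chartr("U", "T", toupper(seq_chr))
  barcode_records(
    record_id = ids,
    marker    = marker,
    species   = binomials,
    sequence  = unname(seq_chr)
  )
}

#' Construct a barcode record table
#'
#' Validates and assembles the canonical record `data.frame` used throughout
#' the package. `genus` is always derived as the first whitespace token of
#' `species`.
#'
#' @param record_id Character vector of unique identifiers.
#' @param marker Marker name (recycled).
#' @param species Latin binomial strings (at least two tokens).
#' @param sequence IUPAC DNA strings; may contain ambiguity codes and, in
#'   aligned contexts, the gap character `-`.
#' @return A `data.frame` with columns `record_id`, `marker`, `genus`,
#'   `species`, `sequence`.
#' @export
barcode_records <- function(record_id, marker, species, sequence) {
  record_id <- as.character(record_id)
  species <- as.character(species)
  sequence <- as.character(sequence)
  if (anyDuplicated(record_id)) {
    stop("duplicate record_id: ",
         paste(unique(record_id[duplicated(record_id)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for record ", record_id[!nzchar(sequence)][1])
  }
  bad_alpha <- grepl("[^ACGTRYSWKMBDHVN-]", sequence)
  if (any(bad_alpha)) {
    stop("non-IUPAC characters in sequence of record ",
         record_id[bad_alpha][1])
  }
  genus <- sub("\\s.*$", "", species)
  data.frame(
    record_id = record_id,
    marker    = rep_len(as.character(marker), length(record_id)),
    genus     = genus,
    species   = species,
    sequence  = sequence,
    stringsAsFactors = FALSE
  )
}

#' Write barcode records to FASTA
#'
#' Emits records with `id|Genus species` headers so that
#' [read_barcode_fasta()] round-trips them exactly.
#'
#' @param records A record `data.frame` (see [barcode_records()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_barcode_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(records$sequence)
  names(seqs) <- paste0(records$record_id, "|", records$species)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Quality-filter barcode records
#'
#' Applies the standard acquisition filters in a fixed order: records shorter
#' than `min_len` bases are removed first, then records with more than
#' `max_ambig` `N` bases, then records of unnamed species (a species string
#' containing the token `sp.`, case-insensitive; `cf.` and `aff.` qualifiers
#' are kept). Each record is counted under the first rule that removes it, so
#' the report categories always sum to the input count. Gap characters are
#' ignored when measuring length.
#'
#' @param records A record `data.frame`.
#' @param min_len Minimum sequence length kept (strict: length `min_len - 1`
#'   is removed, `min_len` is kept). Default 100.
#' @param max_ambig Maximum number of `N` bases kept (strict: `max_ambig + 1`
#'   is removed). Default 15.
#' @param drop_unnamed Remove records whose species contains the token
#'   `sp.`? Default `TRUE`.
#' @return A list with elements `kept` (the surviving record `data.frame`)
#'   and `report`, a `filter_report` list with counts `n_input`,
#'   `n_too_short`, `n_too_ambiguous`, `n_unnamed`, `n_kept`.
#' @export
quality_filter <- function(records, min_len = 100L, max_ambig = 15L,
                           drop_unnamed = TRUE) {
  n_input <- nrow(records)
  if (n_input == 0L) {
    report <- filter_report(0L, 0L, 0L, 0L, 0L)
    return(list(kept = records, report = report))
  }
  ungapped <- gsub("-", "", records$sequence, fixed = TRUE)
  len <- nchar(ungapped)
  n_count <- nchar(ungapped) - nchar(gsub("N", "", ungapped, fixed = TRUE))
  too_short <- len < min_len
  too_ambig <- !too_short & n_count > max_ambig
  unnamed <- if (drop_unnamed) {
    !too_short & !too_ambig & is_unnamed_species(records$species)
  } else {
    rep(FALSE, n_input)
  }
  keep <- !(too_short | too_ambig | unnamed)
  report <- filter_report(
    n_input        = n_input,
    n_too_short    = sum(too_short),
    n_too_ambiguous = sum(too_ambig),
    n_unnamed      = sum(unnamed),
    n_kept         = sum(keep)
  )
  list(kept = records[keep, , drop = FALSE], report = report)
}

filter_report <- function(n_input, n_too_short, n_too_ambiguous, n_unnamed,
                          n_kept) {
  stopifnot(n_input == n_too_short + n_too_ambiguous + n_unnamed + n_kept)
  structure(
    list(n_input = n_input, n_too_short = n_too_short,
         n_too_ambiguous = n_too_ambiguous, n_unnamed = n_unnamed,
         n_kept = n_kept),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Quality filter report\n")
  cat(sprintf("  input:        %d\n", x$n_input))
  cat(sprintf("  too short:    %d\n", x$n_too_short))
  cat(sprintf("  too ambiguous:%d\n", x$n_too_ambiguous))
  cat(sprintf("  unnamed sp.:  %d\n", x$n_unnamed))
  cat(sprintf("  kept:         %d\n", x$n_kept))
  invisible(x)
}

# token "sp." anywhere in the species string, case-insensitive
is_unnamed_species <- function(species) {
  grepl("(^|\\s)sp\\.(\\s|$)", species, ignore.case = TRUE)
}

#' Build an indexed barcode dataset
#'
#' Wraps a record table together with species and genus indices used by the
#' divergence and identification modules.
#'
#' @param records A record `data.frame`.
#' @param marker Optional marker label; defaults to the records' common
#'   marker.
#' @return An object of class `barcode_dataset`: a list with `marker`,
#'   `records`, `species_index` (species -> record ids) and `genus_index`
#'   (genus -> record ids).
#' @export
barcode_dataset <- function(records, marker = NULL) {
  if (is.null(marker)) {
    marker <- if (nrow(records)) unique(records$marker)[1] else "marker"
  }
  structure(
    list(
      marker = marker,
      records = records,
      species_index = split(records$record_id, records$species),
      genus_index = split(records$record_id, records$genus)
    ),
    class = "barcode_dataset"
  )
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat(sprintf("barcode_dataset: marker %s, %d records, %d species, %d genera\n",
              x$marker, nrow(x$records), length(x$species_index),
              length(x$genus_index)))
  invisible(x)
}

#' Summarize dataset composition
#'
#' Counts sequences overall, sequences in genera holding more than one
#' species, and sequences in species sampled more than once — the standard
#' composition summary of a barcode study dataset.
#'
#' @param dataset A `barcode_dataset`.
#' @return A named list with `n_total`, `n_in_multispecies_genera`,
#'   `n_in_multisample_species`, `n_species`, `n_genera`.
#' @export
dataset_summary <- function(dataset) {
  rec <- dataset$records
  if (nrow(rec) == 0L) {
    return(list(n_total = 0L, n_in_multispecies_genera = 0L,
                n_in_multisample_species = 0L, n_species = 0L, n_genera = 0L))
  }
  sp_per_genus <- tapply(rec$species, rec$genus,
                         function(s) length(unique(s)))
  multi_sp_genera <- names(sp_per_genus)[sp_per_genus >= 2]
  samp_per_species <- table(rec$species)
  multi_samp_species <- names(samp_per_species)[samp_per_species >= 2]
  list(
    n_total = nrow(rec),
    n_in_multispecies_genera = sum(rec$genus %in% multi_sp_genera),
    n_in_multisample_species = sum(rec$species %in% multi_samp_species),
    n_species = length(unique(rec$species)),
    n_genera = length(unique(rec$genus))
  )
}

#' Write a named list or table as TSV
#'
#' Small convenience used by the pipeline stage outputs: a one-row TSV for
#' named lists (reports, summaries) or a plain TSV for data frames.
#'
#' @param x A named list of scalars or a `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_report <- function(x, path) {
  if (!is.data.frame(x)) {
    x <- as.data.frame(lapply(x, function(v) if (is.null(v)) NA else v))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
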