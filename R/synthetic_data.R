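#' Simulation configuration
#'
#' Parameters of the taxonomically structured sequence simulator: a star
#' phylogeny at each rank (genera off a family root, species off each genus
#' ancestor, individuals off each species ancestor), with every branch
#' evolved under the Kimura 2-parameter substitution process. Star
#' topologies keep expected pairwise divergences analytically known: two
#' individuals of different species in one genus are separated by
#' `2 * inter_branch + 2 * intra_branch` expected substitutions per site.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus (scalar or length-2 range
#'   sampled uniformly per genus).
#' @param individuals_per_species Individuals per species (scalar or range).
#' @param seq_length Sequence length in bases (>= 100 so simulated fixtures
#'   pass the default length filter).
#' @param genus_branch Expected substitutions/site from family root to each
#'   genus ancestor.
#' @param inter_branch Expected substitutions/site from genus ancestor to
#'   each species ancestor.
#' @param intra_branch Expected substitutions/site from species ancestor to
#'   each individual.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param n_cross_species_identicals Planted identical sequence pairs
#'   spanning species (see [plant_cross_species_identicals()]).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genera = 5, species_per_genus = 3,
                       individuals_per_species = 2, seq_length = 300,
                       genus_branch = 0.15, inter_branch = 0.05,
                       intra_branch = 0.005, kappa = 2,
                       n_cross_species_identicals = 0, seed = 1) {
  cfg <- list(n_genera = n_genera, species_per_genus = species_per_genus,
              individuals_per_species = individuals_per_species,
              seq_length = seq_length, genus_branch = genus_branch,
              inter_branch = inter_branch, intra_branch = intra_branch,
              kappa = kappa,
              n_cross_species_identicals = n_cross_species_identicals,
              seed = seed)
  for (f in c("genus_branch", "inter_branch", "intra_branch")) {
    if (cfg[[f]] < 0) stop("invalid config: ", f, " must be >= 0")
  }
  if (cfg$kappa <= 0) stop("invalid config: kappa must be > 0")
  if (cfg$seq_length < 100) {
    stop("invalid config: seq_length must be >= 100")
  }
  if (cfg$n_genera < 1) stop("invalid config: n_genera must be >= 1")
  for (f in c("species_per_genus", "individuals_per_species")) {
    if (any(cfg[[f]] < 1) || length(cfg[[f]]) > 2) {
      stop("invalid config: ", f, " must be a positive count or range")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Derive a named random substream seed
#'
#' Deterministically derives an integer seed for a named operation from a
#' master seed, so that independent simulation steps draw from independent
#' streams and adding an operation never perturbs existing fixtures. The
#' result always lies in `[0, 2^31 - 1)`.
#'
#' @param seed Master integer seed.
#' @param name Stream name (any string).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) + h * 2654435) %% 2147483647)
}

#' K80 transition probability matrix
#'
#' Closed-form substitution probabilities of the Kimura 2-parameter process
#' for a branch of `t` expected substitutions per site with
#' transition/transversion rate ratio `kappa` (rates normalized so that
#' branch length is measured in expected substitutions per site).
#'
#' @param t Branch length (expected substitutions/site, >= 0).
#' @param kappa Transition/transversion rate ratio.
#' @return A 4x4 row-stochastic matrix over A, C, G, T.
#' @export
k80_probability_matrix <- function(t, kappa = 2) {
  stopifnot(t >= 0, kappa > 0)
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  bases <- c("A", "C", "G", "T")
  P <- matrix(p_tv, 4, 4, dimnames = list(bases, bases))
  diag(P) <- p_same
  P["A", "G"] <- P["G", "A"] <- P["C", "T"] <- P["T", "C"] <- p_ts
  P
}

# evolve a character vector of bases along one branch
evolve_sequence <- function(seq_chars, t, kappa) {
  if (t == 0) return(seq_chars)
  P <- k80_probability_matrix(t, kappa)
  bases <- c("A", "C", "G", "T")
  out <- seq_chars
  for (b in bases) {
    idx <- which(seq_chars == b)
    if (length(idx)) {
      out[idx] <- sample(bases, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  out
}

sample_count <- function(spec) {
  if (length(spec) == 2) sample(seq(spec[1], spec[2]), 1) else spec
}

#' Simulate a taxonomically structured barcode dataset
#'
#' Draws a uniform-random family root sequence and evolves genus, species
#' and individual lineages along the configured branch lengths under the
#' Kimura 2-parameter process (exact closed-form site probabilities, so
#' `kappa` is honored). Output is deterministic for a fixed seed. Genus and
#' species names are synthetic (`Genus01`, `Genus01 species02`).
#'
#' @param config A [sim_config()].
#' @param marker Marker label for the emitted records.
#' @return A list with `records` (a record `data.frame`) and `truth` (a
#'   `data.frame` with `record_id`, `genus`, `species`, `identical_partner`
#'   — `NA` unless [plant_cross_species_identicals()] is applied — and
#'   `is_contaminant`).
#' @export
simulate_dataset <- function(config, marker = "SIM") {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(config$seed, "simulate_dataset"))
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, config$seq_length, replace = TRUE)
  ids <- character(0)
  species <- character(0)
  seqs <- character(0)
  for (g in seq_len(config$n_genera)) {
    genus_anc <- evolve_sequence(root, config$genus_branch, config$kappa)
    n_sp <- sample_count(config$species_per_genus)
    for (s in seq_len(n_sp)) {
      sp_anc <- evolve_sequence(genus_anc, config$inter_branch, config$kappa)
      n_ind <- sample_count(config$individuals_per_species)
      for (i in seq_len(n_ind)) {
        ind <- evolve_sequence(sp_anc, config$intra_branch, config$kappa)
        ids <- c(ids, sprintf("G%02dS%02dI%02d", g, s, i))
        species <- c(species, sprintf("Genus%02d species%02d", g, s))
        seqs <- c(seqs, paste(ind, collapse = ""))
      }
    }
  }
  records <- barcode_records(record_id = ids, marker = marker,
                             species = species, sequence = seqs)
  truth <- data.frame(record_id = records$record_id,
                      genus = records$genus, species = records$species,
                      identical_partner = NA_character_,
                      is_contaminant = FALSE, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Plant cross-species identical sequence pairs
#'
#' Overwrites the sequences of `k` records so that each becomes identical to
#' a record of a different species in the same genus — the failure mode that
#' produces sub-100% identification rates with the tie-failure convention.
#' The expected number of failing queries is exactly `2k` (both members of
#' each planted pair).
#'
#' @param records A record `data.frame`.
#' @param truth The matching truth table.
#' @param k Number of pairs to plant.
#' @param seed Integer seed for pair selection.
#' @return A list with updated `records` and `truth` (partner ids filled
#'   in).
#' @export
plant_cross_species_identicals <- function(records, truth, k, seed = 1) {
  if (k == 0) {
    return(list(records = records, truth = truth))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "plant_identicals"))
  available <- records
  pairs <- list()
  for (i in seq_len(k)) {
    genera <- split(seq_len(nrow(available)), available$genus)
    genera <- genera[vapply(genera, function(idx) {
      length(unique(available$species[idx])) >= 2
    }, logical(1))]
    if (length(genera) == 0L) {
      stop("not enough species remain to plant ", k, " identical pairs")
    }
    gsel <- genera[[sample(length(genera), 1)]]
    sp <- unique(available$species[gsel])
    two <- sample(sp, 2)
    a <- gsel[available$species[gsel] == two[1]][1]
    b <- gsel[available$species[gsel] == two[2]][1]
    pairs[[i]] <- c(available$record_id[a], available$record_id[b])
    available <- available[-c(a, b), , drop = FALSE]
  }
  for (p in pairs) {
    ia <- match(p[1], records$record_id)
    ib <- match(p[2], records$record_id)
    records$sequence[ib] <- records$sequence[ia]
    truth$identical_partner[match(p, truth$record_id)] <- rev(p)
  }
  list(records = records, truth = truth)
}

#' Simulate contaminant sequences
#'
#' Evolves a contaminant root away from a given plant-like root by
#' `profile_divergence` expected substitutions per site and draws `n`
#' contaminant sequences from it, mimicking e.g. fungal reads mixed into a
#' plant ITS2 set.
#'
#' @param root_seq Plant root sequence (character string) to diverge from.
#' @param profile_divergence Expected substitutions/site between the plant
#'   root and the contaminant root.
#' @param n Number of contaminant sequences.
#' @param branch Within-contaminant branch length (expected
#'   substitutions/site from the contaminant root to each sequence).
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed.
#' @param marker Marker label.
#' @return A record `data.frame` of `n` contaminant records (species
#'   `"Contaminans synthetica"`).
#' @export
simulate_contaminants <- function(root_seq, profile_divergence, n,
                                  branch = 0.02, kappa = 2, seed = 1,
                                  marker = "SIM") {
  if (n == 0) {
    return(barcode_records(character(0), marker, character(0),
                           character(0)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "simulate_contaminants"))
  root <- strsplit(root_seq, "", fixed = TRUE)[[1]]
  cont_root <- evolve_sequence(root, profile_divergence, kappa)
  seqs <- vapply(seq_len(n), function(i) {
    paste(evolve_sequence(cont_root, branch, kappa), collapse = "")
  }, character(1))
  barcode_records(
    record_id = sprintf("CONT%03d", seq_len(n)),
    marker = marker,
    species = rep("Contaminans synthetica", n),
    sequence = seqs
  )
}
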