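# shared fixture builders and independent oracles

# write records to a temporary FASTA and return the path
tmp_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  write_barcode_fasta(records, path)
  path
}

# quick record table: species like "Genus species", sequences given
rec_fixture <- function(ids, species, seqs, marker = "ITS2") {
  barcode_records(record_id = ids, marker = marker, species = species,
                  sequence = seqs)
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = "")
  }, character(1))
}

# --- independent alignment oracle: recursive enumeration of all global
# affine-gap alignments (state-aware so gap runs are scored correctly)
enum_global_score <- function(a, b, scheme) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  subst <- function(x, y) if (x == y) scheme$match else scheme$mismatch
  rec <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      best <- max(best, subst(a[i], b[j]) + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(a)) {
      gp <- if (state == "ga") scheme$gap_extend else scheme$gap_open
      best <- max(best, gp + rec(i + 1, j, "ga"))
    }
    if (j <= length(b)) {
      gp <- if (state == "gb") scheme$gap_extend else scheme$gap_open
      best <- max(best, gp + rec(i, j + 1, "gb"))
    }
    best
  }
  rec(1, 1, "m")
}

# independent local oracle: best global score over all substring pairs
enum_local_score <- function(a, b, scheme) {
  na <- nchar(a)
  nb <- nchar(b)
  best <- 0
  for (i in seq_len(na)) for (j in i:na) {
    for (k in seq_len(nb)) for (l in k:nb) {
      best <- max(best, enum_global_score(substr(a, i, j), substr(b, k, l),
                                          scheme))
    }
  }
  best
}

# --- independent K2P site-pattern oracle: explicit per-column loop
oracle_site_counts <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  L <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    x <- a[i]; y <- b[i]
    if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
      L <- L + 1L
      if (x != y) {
        if ((x == "A" && y == "G") || (x == "G" && y == "A") ||
            (x == "C" && y == "T") || (x == "T" && y == "C")) {
          ts <- ts + 1L
        } else {
          tv <- tv + 1L
        }
      }
    }
  }
  list(L = L, n_ts = ts, n_tv = tv)
}

# --- independent signed-rank oracle: enumerate all 2^n sign vectors
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  W_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  p_ge <- mean(W_all >= W_obs)
  p_le <- mean(W_all <= W_obs)
  min(1, 2 * min(p_ge, p_le))
}

# --- independent profile-HMM oracle: exhaustive path enumeration ---------
# global mode: enumerate all state paths through the full profile emitting
# exactly the sequence; returns log(P(seq | profile)).
enum_global_forward <- function(hmm, seq) {
  x <- strsplit(seq, "")[[1]]
  k <- hmm$n_match_states
  tr <- hmm$transitions
  total <- 0
  # state: type in M/I/D, pos; begin = (M, 0); end reached via "M" from pos k
  recurse <- function(type, pos, i, prob) {
    # transition rows: M/I row pos+1; D row pos
    row <- if (type == "D") pos else pos + 1
    # to end
    if (pos == k && i > length(x)) {
      total <<- total + prob * tr[[type]][row, "M"]
      return(invisible())
    }
    # to M_{pos+1}
    if (pos < k && i <= length(x)) {
      p <- tr[[type]][row, "M"] *
        mean(hmm$match_emissions[pos + 1, iupac_base_set(x[i])])
      recurse("M", pos + 1, i + 1, prob * p)
    }
    # to I_pos
    if (i <= length(x)) {
      p <- tr[[type]][row, "I"] *
        mean(hmm$background[iupac_base_set(x[i])])
      recurse("I", pos, i + 1, prob * p)
    }
    # to D_{pos+1}
    if (pos < k) {
      p <- tr[[type]][row, "D"]
      if (p > 0) recurse("D", pos + 1, i, prob * p)
    }
  }
  recurse("M", 0, 1, 1)
  as.numeric(log(total))
}

iupac_base_set <- function(s) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", N = c("A", "C", "G", "T"))
  sets[[s]]
}

# local mode: enumerate entry position/state, core path, exit after match;
# returns log-odds (natural log), flanks cancel by construction.
enum_local_forward_odds <- function(hmm, seq) {
  x <- strsplit(seq, "")[[1]]
  k <- hmm$n_match_states
  tr <- hmm$transitions
  L <- length(x)
  odds <- function(pos, s) {
    mean(hmm$match_emissions[pos, iupac_base_set(s)]) /
      mean(hmm$background[iupac_base_set(s)])
  }
  total <- 0
  # paths end after a match state (exit weight 1)
  recurse <- function(type, pos, i, w) {
    if (type == "M") total <<- total + w   # may exit here
    row <- if (type == "D") pos else pos + 1
    if (pos < k && i <= L) {
      recurse("M", pos + 1, i + 1,
              w * tr[[type]][row, "M"] * odds(pos + 1, x[i]))
    }
    if (i <= L) {
      recurse("I", pos, i + 1, w * tr[[type]][row, "I"])
    }
    if (pos < k) {
      p <- tr[[type]][row, "D"]
      if (p > 0) recurse("D", pos + 1, i, w * p)
    }
  }
  for (start in seq_len(L)) {
    for (j in seq_len(k)) {
      recurse("M", j, start + 1, (1 / k) * odds(j, x[start]))
    }
  }
  as.numeric(log(total))
}

# default simulated dataset used by several tests
sim_fixture <- function(seed = 7, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_dataset(cfg)
  list(cfg = cfg, records = sim$records, truth = sim$truth,
       dataset = barcode_dataset(sim$records))
}
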