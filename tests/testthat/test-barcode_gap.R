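# build a dataset + distance matrix directly from a hand-specified distance
# table (sequences are placeholders; the matrix is what the metrics consume)
manual_matrix <- function(ids, species, dists) {
  rec <- rec_fixture(ids, species, random_dna(length(ids), 100))
  ds <- barcode_dataset(rec)
  d <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  diag(d) <- 0
  for (k in seq_len(nrow(dists))) {
    d[dists$a[k], dists$b[k]] <- d[dists$b[k], dists$a[k]] <- dists$d[k]
  }
  list(ds = ds, d = d)
}

test_that("intra-specific metrics reproduce hand-enumerated fixtures", {
  # one species, 3 individuals, pairwise distances 0.01/0.02/0.03
  fx <- manual_matrix(
    c("a", "b", "c"), rep("Aster tataricus", 3),
    data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"),
               d = c(0.01, 0.02, 0.03))
  )
  m <- intraspecific_metrics(fx$d, fx$ds)
  expect_equal(m$avg_intra, 0.02)
  expect_equal(m$theta, 0.02)
  expect_equal(m$avg_coalescent_depth, 0.03)

  # two species: means 0.01 (1 pair) and 0.03 (3 pairs); theta unweighted,
  # avg_intra pair-weighted
  fx2 <- manual_matrix(
    c("a1", "a2", "b1", "b2", "b3"),
    c("Aster tataricus", "Aster tataricus",
      "Aster alpinus", "Aster alpinus", "Aster alpinus"),
    data.frame(a = c("a1", "b1", "b1", "b2"),
               b = c("a2", "b2", "b3", "b3"),
               d = c(0.01, 0.03, 0.03, 0.03))
  )
  m2 <- intraspecific_metrics(fx2$d, fx2$ds)
  expect_equal(m2$theta, 0.02)
  expect_equal(m2$avg_intra, (0.01 * 1 + 0.03 * 3) / 4)

  # all individuals identical -> all zero
  same <- barcode_dataset(rec_fixture(c("x", "y"),
                                      rep("Aster tataricus", 2),
                                      rep(strrep("ACGT", 30), 2)))
  d0 <- distance_matrix(same, mode = "pre-aligned")
  m3 <- intraspecific_metrics(d0, same)
  expect_equal(m3$avg_intra, 0)
  expect_equal(m3$avg_coalescent_depth, 0)

  # no species with two individuals -> not computable
  singletons <- manual_matrix(c("a", "b"),
                              c("Aster tataricus", "Aster alpinus"),
                              data.frame(a = "a", b = "b", d = 0.1))
  m4 <- intraspecific_metrics(singletons$d, singletons$ds)
  expect_true(is.na(m4$avg_intra) && is.na(m4$theta) &&
                is.na(m4$avg_coalescent_depth))
  expect_equal(m4$n_species, 0L)
})

test_that("inter-specific metrics reproduce hand-enumerated fixtures", {
  # one genus, two singleton species at distance 0.2
  fx <- manual_matrix(c("a", "b"), c("Aster tataricus", "Aster alpinus"),
                      data.frame(a = "a", b = "b", d = 0.2))
  m <- interspecific_metrics(fx$d, fx$ds)
  expect_equal(m$avg_inter, 0.2)
  expect_equal(m$theta_prime, 0.2)
  expect_equal(m$min_inter, 0.2)

  # G1: three singleton species, pairs {0.1, 0.2, 0.3}; G2: one pair {0.1}
  fx2 <- manual_matrix(
    c("g1a", "g1b", "g1c", "g2a", "g2b"),
    c("Aster tataricus", "Aster alpinus", "Aster amellus",
      "Carduus crispus", "Carduus nutans"),
    data.frame(a = c("g1a", "g1a", "g1b", "g2a"),
               b = c("g1b", "g1c", "g1c", "g2b"),
               d = c(0.1, 0.2, 0.3, 0.1))
  )
  m2 <- interspecific_metrics(fx2$d, fx2$ds)
  expect_equal(m2$avg_inter, (0.1 + 0.2 + 0.3 + 0.1) / 4)
  expect_equal(m2$theta_prime, (0.2 + 0.1) / 2)
  expect_equal(m2$min_inter, (0.1 + 0.1) / 2)

  # genus where both species share one sequence -> all zero
  same <- barcode_dataset(rec_fixture(c("x", "y"),
                                      c("Aster tataricus", "Aster alpinus"),
                                      rep(strrep("ACGT", 30), 2)))
  d0 <- distance_matrix(same, mode = "pre-aligned")
  m3 <- interspecific_metrics(d0, same)
  expect_equal(m3$avg_inter, 0)
  expect_equal(m3$min_inter, 0)

  # no genus with two species -> not computable
  solo <- manual_matrix(c("a", "b"),
                        c("Aster tataricus", "Carduus crispus"),
                        data.frame(a = "a", b = "b", d = 0.4))
  m4 <- interspecific_metrics(solo$d, solo$ds)
  expect_true(is.na(m4$avg_inter) && is.na(m4$theta_prime) &&
                is.na(m4$min_inter))
  expect_equal(m4$n_genera, 0L)
})

test_that("conspecific pairs inside a genus are excluded unless asked for", {
  # genus with 2 species x 2 individuals: 4 heterospecific pairs, 2
  # conspecific pairs
  fx <- manual_matrix(
    c("a1", "a2", "b1", "b2"),
    c("Aster tataricus", "Aster tataricus", "Aster alpinus",
      "Aster alpinus"),
    data.frame(a = c("a1", "a1", "a1", "a2", "a2", "b1"),
               b = c("a2", "b1", "b2", "b1", "b2", "b2"),
               d = c(0.01, 0.2, 0.2, 0.2, 0.2, 0.01))
  )
  m <- interspecific_metrics(fx$d, fx$ds)
  expect_equal(m$per_genus$n_pairs, 4L)
  expect_equal(m$avg_inter, 0.2)
  m_all <- interspecific_metrics(fx$d, fx$ds, include_conspecific = TRUE)
  expect_equal(m_all$per_genus$n_pairs, 6L)
  expect_equal(m_all$theta_prime, mean(c(0.01, 0.2, 0.2, 0.2, 0.2, 0.01)))
})

test_that("metrics are invariant to record relabeling and input order", {
  fx <- sim_fixture(seed = 21, n_genera = 3, species_per_genus = 3,
                    individuals_per_species = 2, seq_length = 150)
  d <- distance_matrix(fx$dataset, mode = "pre-aligned")
  m_intra <- intraspecific_metrics(d, fx$dataset)
  m_inter <- interspecific_metrics(d, fx$dataset)

  set.seed(6)
  perm <- sample(nrow(fx$records))
  rec2 <- fx$records[perm, ]
  rec2$record_id <- paste0("relabel_", rec2$record_id)
  ds2 <- barcode_dataset(rec2)
  d2 <- distance_matrix(ds2, mode = "pre-aligned")
  m_intra2 <- intraspecific_metrics(d2, ds2)
  m_inter2 <- interspecific_metrics(d2, ds2)
  for (f in c("avg_intra", "theta", "avg_coalescent_depth")) {
    expect_equal(m_intra2[[f]], m_intra[[f]])
  }
  for (f in c("avg_inter", "theta_prime", "min_inter")) {
    expect_equal(m_inter2[[f]], m_inter[[f]])
  }
})

test_that("avg_inter equals theta_prime when genera have equal pair counts", {
  fx <- sim_fixture(seed = 8, n_genera = 4, species_per_genus = 3,
                    individuals_per_species = 1, seq_length = 150)
  d <- distance_matrix(fx$dataset, mode = "pre-aligned")
  m <- interspecific_metrics(d, fx$dataset)
  expect_true(all(m$per_genus$n_pairs == m$per_genus$n_pairs[1]))
  expect_equal(m$avg_inter, m$theta_prime, tolerance = 1e-12)
})

test_that("divergence table aggregates one row per marker and ranks planted scales", {
  fx <- sim_fixture(seed = 13, n_genera = 3, species_per_genus = 3,
                    individuals_per_species = 2, seq_length = 150)
  d <- distance_matrix(fx$dataset, mode = "pre-aligned")
  one <- list(ITS2 = list(intra = intraspecific_metrics(d, fx$dataset),
                          inter = interspecific_metrics(d, fx$dataset)))
  tab <- divergence_table(one)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$avg_inter, one$ITS2$inter$avg_inter)
  expect_equal(nrow(divergence_table(list())), 0L)

  # a marker simulated with a larger inter-specific scale ranks above a
  # smaller-scale one on all three inter metrics
  lo <- sim_fixture(seed = 41, n_genera = 4, species_per_genus = 3,
                    individuals_per_species = 1, seq_length = 400,
                    inter_branch = 0.02)
  hi <- sim_fixture(seed = 42, n_genera = 4, species_per_genus = 3,
                    individuals_per_species = 1, seq_length = 400,
                    inter_branch = 0.12)
  m_lo <- interspecific_metrics(distance_matrix(lo$dataset,
                                                mode = "pre-aligned"),
                                lo$dataset)
  m_hi <- interspecific_metrics(distance_matrix(hi$dataset,
                                                mode = "pre-aligned"),
                                hi$dataset)
  expect_gt(m_hi$avg_inter, m_lo$avg_inter)
  expect_gt(m_hi$theta_prime, m_lo$theta_prime)
  expect_gt(m_hi$min_inter, m_lo$min_inter)
})
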