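test_that("best-hit assignment is correct for unique matches and fails on cross-species ties", {
  rec <- rec_fixture(
    ids = c("q", "same_sp", "other_sp"),
    species = c("Aster tataricus", "Aster tataricus", "Aster alpinus"),
    seqs = c(strrep("ACGT", 30),
             paste0(strrep("ACGT", 29), "ACGA"),   # 1 substitution away
             random_dna(1, 120))
  )
  db <- barcode_dataset(rec)
  a <- blast1_identify("q", db)
  # self-inclusive: the query record itself is the unique best hit
  expect_equal(a$best_refs, "q")
  expect_true(a$species_correct)
  expect_true(a$genus_correct)

  # a verbatim copy of the query sequence in another species ties the top hit
  rec2 <- rec
  rec2$sequence[3] <- rec2$sequence[1]
  db2 <- barcode_dataset(rec2)
  a2 <- blast1_identify("q", db2)
  expect_setequal(a2$best_refs, c("q", "other_sp"))
  expect_equal(a2$assigned_species, "ambiguous")
  expect_false(a2$species_correct)
  # both best refs still share the genus
  expect_true(a2$genus_correct)

  # leave-one-out drops the self hit
  a3 <- blast1_identify("q", db, mode = "leave-one-out")
  expect_false("q" %in% a3$best_refs)
  expect_equal(a3$best_refs, "same_sp")
  expect_true(a3$species_correct)
})

test_that("nearest-distance assignment follows the same conventions and handles undefined distances", {
  fx <- sim_fixture(seed = 33, n_genera = 2, species_per_genus = 3,
                    individuals_per_species = 2, seq_length = 200)
  d <- distance_matrix(fx$dataset, mode = "pre-aligned")
  a <- nearest_distance_identify(fx$records$record_id[1], fx$dataset, d)
  expect_true(a$species_correct)
  expect_false(a$all_undefined)

  # two references of different species exactly equidistant -> ambiguous
  ids <- c("q", "r1", "r2")
  dd <- matrix(0, 3, 3, dimnames = list(ids, ids))
  dd["q", "r1"] <- dd["r1", "q"] <- 0.1
  dd["q", "r2"] <- dd["r2", "q"] <- 0.1
  dd["r1", "r2"] <- dd["r2", "r1"] <- 0.2
  rec <- rec_fixture(ids, c("Aster tataricus", "Aster alpinus",
                            "Carduus crispus"), random_dna(3, 100))
  db <- barcode_dataset(rec)
  a2 <- nearest_distance_identify("q", db, dd, mode = "leave-one-out")
  expect_equal(a2$assigned_species, "ambiguous")
  expect_false(a2$species_correct)
  expect_false(a2$genus_correct)

  # all distances undefined -> flagged ambiguous
  dna <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  diag(dna) <- 0
  a3 <- nearest_distance_identify("q", db, dna, mode = "leave-one-out")
  expect_true(a3$all_undefined)
  expect_equal(a3$assigned_species, "ambiguous")
})

test_that("species-correct implies genus-correct across simulated assignments", {
  fx <- sim_fixture(seed = 44, n_genera = 3, species_per_genus = 2,
                    individuals_per_species = 2, seq_length = 150)
  d <- distance_matrix(fx$dataset, mode = "pre-aligned")
  for (method in c("BLAST1", "distance")) {
    rep <- evaluate_identification(fx$dataset, method = method, d = d)
    expect_true(all(!rep$assignments$species_correct |
                      rep$assignments$genus_correct))
  }
})

test_that("identification rates recover planted truth exactly", {
  # unique haplotypes, self-inclusive -> 100% by both methods
  fx <- sim_fixture(seed = 55, n_genera = 3, species_per_genus = 3,
                    individuals_per_species = 2, seq_length = 500,
                    intra_branch = 0.02)
  expect_equal(anyDuplicated(fx$records$sequence), 0L)
  d <- distance_matrix(fx$dataset, mode = "pre-aligned")
  for (method in c("BLAST1", "distance")) {
    rep <- evaluate_identification(fx$dataset, method = method, d = d)
    expect_equal(rep$species_rate, 100)
    expect_equal(rep$genus_rate, 100)
  }

  # k planted cross-species identical pairs -> species rate 100 (N - 2k) / N
  k <- 2
  planted <- plant_cross_species_identicals(fx$records, fx$truth, k,
                                            seed = 9)
  ds <- barcode_dataset(planted$records)
  d2 <- distance_matrix(ds, mode = "pre-aligned")
  N <- nrow(planted$records)
  rep2 <- evaluate_identification(ds, method = "distance", d = d2)
  expect_equal(rep2$species_rate, 100 * (N - 2 * k) / N)
  # exactly the planted pair members fail, per query
  should_fail <- !is.na(planted$truth$identical_partner)
  expect_equal(rep2$assignments$species_correct,
               !should_fail[match(rep2$assignments$query_id,
                                  planted$truth$record_id)])

  # leave-one-out with all-singleton species can never be species-correct
  singles <- sim_fixture(seed = 66, n_genera = 3, species_per_genus = 3,
                         individuals_per_species = 1, seq_length = 200)
  d3 <- distance_matrix(singles$dataset, mode = "pre-aligned")
  rep3 <- evaluate_identification(singles$dataset, method = "distance",
                                  mode = "leave-one-out", d = d3)
  expect_equal(rep3$species_rate, 0)
  expect_gt(rep3$genus_rate, 0)
})

test_that("best-hit and nearest-distance agree when both rankings are unambiguous", {
  fx <- sim_fixture(seed = 77, n_genera = 3, species_per_genus = 2,
                    individuals_per_species = 2, seq_length = 300)
  d <- distance_matrix(fx$dataset, mode = "pre-aligned")
  blast <- evaluate_identification(fx$dataset, method = "BLAST1")
  dist <- evaluate_identification(fx$dataset, method = "distance", d = d)
  expect_equal(blast$assignments$assigned_species,
               dist$assignments$assigned_species)
  expect_equal(blast$assignments$species_correct,
               dist$assignments$species_correct)
})

test_that("traffic-light combination equals set arithmetic on the common samples", {
  # hand case: A correct on {s1, s2}, B correct on {s2, s3} -> union = all
  mk_report <- function(correct_ids, all_ids) {
    structure(list(
      method = "BLAST1", mode = "self-inclusive",
      n_queries = length(all_ids),
      species_rate = 100 * mean(all_ids %in% correct_ids),
      genus_rate = 100,
      assignments = data.frame(
        query_id = all_ids,
        species_correct = all_ids %in% correct_ids,
        genus_correct = TRUE, stringsAsFactors = FALSE)
    ), class = "identification_report")
  }
  ids <- c("s1", "s2", "s3")
  map <- rbind(
    data.frame(sample_id = ids, marker = "A", record_id = ids),
    data.frame(sample_id = ids, marker = "B", record_id = ids)
  )
  comb <- combine_markers(list(A = mk_report(c("s1", "s2"), ids),
                               B = mk_report(c("s2", "s3"), ids)), map)
  expect_equal(comb$species_rate, 100)
  expect_equal(comb$n_common_samples, 3L)

  # identical correct sets -> no gain over the single marker
  comb2 <- combine_markers(list(A = mk_report("s1", ids),
                                B = mk_report("s1", ids)), map)
  expect_equal(comb2$species_rate, 100 / 3)

  # random planted failures: rate = 100 |union| / n over 20 replicates,
  # and the combination never falls below the best member
  set.seed(123)
  for (i in 1:20) {
    n <- 12
    all_ids <- sprintf("s%02d", 1:n)
    ca <- sample(all_ids, sample(0:n, 1))
    cb <- sample(all_ids, sample(0:n, 1))
    m <- rbind(
      data.frame(sample_id = all_ids, marker = "A", record_id = all_ids),
      data.frame(sample_id = all_ids, marker = "B", record_id = all_ids)
    )
    reports <- list(A = mk_report(ca, all_ids), B = mk_report(cb, all_ids))
    cc <- combine_markers(reports, m)
    expect_equal(cc$species_rate, 100 * length(union(ca, cb)) / n)
    expect_gte(cc$species_rate, max(reports$A$species_rate,
                                    reports$B$species_rate))
  }

  # empty common-sample set is an error
  m2 <- rbind(
    data.frame(sample_id = "x", marker = "A", record_id = "x"),
    data.frame(sample_id = "y", marker = "B", record_id = "y")
  )
  expect_error(combine_markers(list(A = mk_report("x", "x"),
                                    B = mk_report("y", "y")), m2),
               "no sample")
})
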