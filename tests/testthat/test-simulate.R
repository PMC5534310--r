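test_that("the error process edits sequences at the configured rates", {
  set.seed(90)
  s <- rand_seq(200)
  clean <- mutate_sequence(s, error_model(0, 0, 0), seed = 1)
  expect_equal(as.character(clean), s)
  expect_equal(attr(clean, "n_edits"), 0)

  gone <- mutate_sequence(s, error_model(0, 0, 0.999999), seed = 1)
  expect_equal(nchar(gone), 0)

  # identity lands where the total edit load predicts (~0.90 here)
  big <- rand_seq(10000)
  model <- error_model(0.05, 0.025, 0.025)
  for (seed in 1:20) {
    noisy <- mutate_sequence(big, model, seed = seed)
    idn <- segment_identity(big, as.character(noisy))
    expect_gte(idn, 0.88)
    expect_lte(idn, 0.93)
  }
  expect_error(error_model(0.5, 0.3, 0.3), "sum to < 1")
})

test_that("simulation is reproducible bit for bit per seed", {
  s1 <- synth_genomes(3, operons_per_genome = 2, divergence = 0.1, seed = 5)
  s2 <- synth_genomes(3, operons_per_genome = 2, divergence = 0.1, seed = 5)
  expect_identical(s1, s2)
  s3 <- synth_genomes(3, operons_per_genome = 2, divergence = 0.1, seed = 6)
  expect_false(identical(s1$genomes$seq, s3$genomes$seq))

  db <- s1$truth
  db$record_id <- sprintf("r%d", seq_len(nrow(db)))
  specs <- package_specs()
  design <- data.frame(taxon = unique(db$species), proportion = rep(1 / 3, 3))
  r1 <- simulate_reads(db, list(HM782D = design), specs, 25,
                       model = error_model_preset("R9"), seed = 11)
  r2 <- simulate_reads(db, list(HM782D = design), specs, 25,
                       model = error_model_preset("R9"), seed = 11)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$reads), 25)
  expect_identical(r1$truth$read_id, r1$reads$id)

  r0 <- simulate_reads(db, list(HM782D = design), specs, 0,
                       model = error_model_preset("R9"), seed = 11)
  expect_equal(nrow(r0$reads), 0)
  expect_equal(nrow(r0$truth), 0)
})

test_that("clones at divergence zero collapse into one cluster", {
  sim <- synth_genomes(2, divergence = 0, seed = 8)
  recs <- extract_rrn_regions(sim$genomes, sim$features, sim$taxonomy)
  expect_equal(nrow(recs), 2)
  cl <- greedy_cluster(recs, radius_pct = 0)
  expect_equal(cl$n_clusters, 1)
})

test_that("simulated species counts follow the community design", {
  sim <- synth_genomes(8, divergence = 0.05, seed = 9)
  db <- sim$truth
  db$record_id <- sprintf("r%d", seq_len(nrow(db)))
  design <- read_community_design(
    system.file("extdata", "design_d6305.tsv", package = "rrnprofile"))
  design$taxon <- unique(db$species)
  specs <- package_specs()
  rs <- simulate_reads(db, list(D6305 = design), specs, 5000,
                       model = error_model(0, 0, 0), seed = 13)
  counts <- table(factor(rs$truth$species, levels = design$taxon))
  chi <- chisq.test(as.integer(counts), p = design$proportion)
  expect_gt(chi$p.value, 0.001)
})

test_that("truncation keeps a 5-prime prefix of bounded length", {
  sim <- synth_genomes(2, divergence = 0.05, seed = 10)
  db <- sim$truth
  db$record_id <- c("r1", "r2")
  design <- data.frame(taxon = unique(db$species), proportion = c(0.5, 0.5))
  rs <- simulate_reads(db, list(HM782D = design), package_specs(), 40,
                       model = error_model(0, 0, 0), seed = 3,
                       trunc_prob = 1, trunc_min_frac = 0.3)
  full_len <- nchar(db$seq[match(rs$truth$species, db$species)]) +
    nchar(table1_bc01F) + nchar(table1_bc01R)
  expect_true(all(rs$truth$truncated))
  expect_true(all(nchar(rs$reads$seq) <= full_len))
  expect_true(all(nchar(rs$reads$seq) >= 0.3 * full_len - 1))
})

test_that("error presets realize their target identity regimes", {
  q9 <- simulated_identity_quartiles(error_model_preset("R9"), n = 60,
                                     len = 3000, seed = 2)
  expect_gte(q9[["50%"]], 0.65)
  expect_lte(q9[["50%"]], 0.73)
  q94 <- simulated_identity_quartiles(error_model_preset("R9.4"), n = 60,
                                      len = 3000, seed = 2)
  expect_gte(q94[["50%"]], 0.81)
  expect_lte(q94[["50%"]], 0.89)
})
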