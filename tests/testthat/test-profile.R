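small_db <- function(seed = 14, n = 3) {
  sim <- synth_genomes(n, divergence = 0.1, seed = seed)
  recs <- extract_rrn_regions(sim$genomes, sim$features, sim$taxonomy)
  recs
}

test_that("read length filter keeps the inclusive 1500-7000 window", {
  reads <- data.frame(id = sprintf("r%d", 1:5),
                      seq = vapply(c(1000, 1500, 3000, 7000, 7001),
                                   function(n) strrep("A", n), character(1)))
  lf <- length_filter_reads(reads)
  expect_equal(lf$reads$id, c("r2", "r3", "r4"))
  expect_equal(unname(lf$report), c(5, 3, 2))

  all_in <- length_filter_reads(reads[2:4, ])
  expect_equal(nrow(all_in$reads), 3)
  empty <- length_filter_reads(reads[0, ])
  expect_equal(nrow(empty$reads), 0)
  expect_equal(unname(empty$report["n_in"]), 0L)
})

test_that("competitive mapping returns the highest-scoring reference", {
  db <- small_db()
  slice <- substr(db$seq[2], 501, 2500)
  reads <- data.frame(id = "q1", seq = slice)
  h <- competitive_map(reads, db)
  expect_equal(h$ref_id, db$record_id[2])
  expect_equal(h$score, 2000)
  expect_equal(h$identity, 1.0)
  expect_equal(h$strand, "+")
  expect_false(h$ambiguous)

  # reverse-complement reads map on the minus strand
  h2 <- competitive_map(data.frame(id = "q2", seq = revcomp(slice)), db)
  expect_equal(h2$ref_id, db$record_id[2])
  expect_equal(h2$strand, "-")
  expect_equal(h2$score, 2000)

  # a mutated slice still beats the unrelated references, matching full DP
  noisy <- as.character(mutate_sequence(slice, error_model(0.005, 0, 0),
                                        seed = 4))
  hh <- competitive_map(data.frame(id = "q3", seq = noisy), db)
  hf <- competitive_map(data.frame(id = "q3", seq = noisy), db,
                        method = "full")
  expect_equal(hh$ref_id, db$record_id[2])
  expect_identical(hh$score, hf$score)
  expect_identical(hh$ref_id, hf$ref_id)

  expect_error(competitive_map(data.frame(id = "tiny", seq = "ACGT"), db),
               "shorter than 50")
})

test_that("score ties break to smallest ref id and are flagged ambiguous", {
  db <- small_db()
  twin <- rbind(db[1, ], db[1, ])
  twin$record_id <- c("B_copy", "A_copy")
  reads <- data.frame(id = "q1", seq = substr(db$seq[1], 1001, 3000))
  h <- competitive_map(reads, twin)
  expect_equal(h$ref_id, "A_copy")
  expect_true(h$ambiguous)
})

test_that("identity filter keeps hits strictly above the percentile threshold", {
  hits <- data.frame(read_id = sprintf("r%d", 1:4), identity = c(0.60, 0.65, 0.70, 0.75))
  f <- identity_filter(hits, 50)
  expect_equal(f$threshold, 0.65)
  expect_equal(nrow(f$hits), 2)
  expect_equal(f$n_removed, 2)

  f0 <- identity_filter(hits, 0)
  expect_equal(f0$threshold, 0.60)
  expect_equal(nrow(f0$hits), 3)

  same <- data.frame(read_id = sprintf("r%d", 1:3), identity = rep(0.8, 3))
  expect_warning(fs <- identity_filter(same, 50), "no hits above")
  expect_equal(nrow(fs$hits), 0)
  expect_error(identity_filter(hits[0, ], 50), "no hits")
})

test_that("profiles remove singletons and flag predominant taxa at 1 percent", {
  mk_hits <- function(counts) {
    data.frame(read_id = sprintf("r%d", seq_len(sum(counts))),
               species = rep(names(counts), counts),
               ambiguous = FALSE)
  }
  p <- build_profile(mk_hits(c("Aa x" = 50, "Bb y" = 49, "Cc z" = 1)))
  expect_equal(nrow(p$taxa), 2)
  expect_equal(p$n_singletons, 1)
  expect_equal(p$taxa$proportion, c(50 / 99, 49 / 99))
  expect_true(all(p$taxa$predominant))
  expect_equal(sum(p$taxa$proportion), 1)

  p2 <- build_profile(mk_hits(c("Aa x" = 990, "Bb y" = 10)))
  expect_true(p2$taxa$predominant[p2$taxa$taxon == "Bb y"])
  p3 <- build_profile(mk_hits(c("Aa x" = 995, "Bb y" = 5)))
  expect_false(p3$taxa$predominant[p3$taxa$taxon == "Bb y"])

  single <- build_profile(mk_hits(c("Aa x" = 7)))
  expect_equal(single$taxa$proportion, 1.0)

  g <- build_profile(mk_hits(c("Aa x" = 5, "Aa y" = 5, "Bb y" = 5)),
                     rank = "genus")
  expect_equal(sort(g$taxa$taxon), c("Aa", "Bb"))
  expect_equal(g$taxa$count[g$taxa$taxon == "Aa"], 10)

  expect_error(build_profile(mk_hits(c("Aa x" = 1))), "no taxa left")
})

test_that("coverage bias is the rounded log2 observed/expected fold change", {
  hits <- data.frame(read_id = sprintf("r%d", 1:1000),
                     species = rep(c("Pseudomonas spp.", "Other spp."),
                                   c(60, 940)),
                     ambiguous = FALSE)
  prof <- build_profile(hits)
  design <- data.frame(taxon = c("Pseudomonas spp.", "Other spp.",
                                 "Absent spp."),
                       proportion = c(0.058, 0.7, 0.242))
  cb <- coverage_bias(prof, design)
  expect_equal(cb$bias[cb$taxon == "Pseudomonas spp."], 0.05)
  expect_true(is.na(cb$bias[cb$taxon == "Absent spp."]))
  expect_equal(cb$observed[cb$taxon == "Absent spp."], 0)

  even <- coverage_bias(prof, data.frame(taxon = c("Pseudomonas spp.",
                                                   "Other spp."),
                                         proportion = c(0.06, 0.94)))
  expect_equal(even$bias[1], 0.00)

  bad <- data.frame(taxon = c("Pseudomonas spp.", "Other spp."),
                    proportion = c(0, 1))
  expect_error(coverage_bias(prof, bad), "zero")
})

test_that("per-sample pipeline accounting conserves every input read", {
  set.seed(71)
  db <- small_db(seed = 15, n = 4)
  specs <- package_specs()
  design <- data.frame(taxon = db$species, proportion = rep(0.25, 4))
  rs <- simulate_reads(db, list(D6305 = design), specs, n_reads = 60,
                       model = error_model_preset("R9.4"), seed = 72)
  ps <- profile_sample(rs$reads, db, identity_percentile = 25)
  acct <- ps$accounting
  expect_equal(unname(acct["n_in"]),
               unname(sum(acct[c("n_length_removed", "n_identity_removed",
                                 "n_ambiguous_removed", "n_singletons",
                                 "n_profiled")])))
  expect_equal(sum(ps$profile$taxa$proportion), 1)
  # the identity threshold reported is the nearest-rank 25th percentile
  expect_gte(mean(ps$hits$identity > ps$identity_threshold), 1 - 1e-9)
})
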