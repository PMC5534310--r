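make_contig_with_operon <- function() {
  # 16S at 101-1600 (+), ITS gap 400, 23S at 2001-5000 (+), contig 5200 nt
  set.seed(12)
  seq <- rand_seq(5200)
  genomes <- data.frame(id = "chr1", seq = seq, assembly_id = "ASM1")
  features <- data.frame(
    contig = "chr1", type = c("rRNA_16S", "rRNA_23S"),
    start = c(101, 2001), end = c(1600, 5000), strand = "+",
    attr = c("16S ribosomal RNA", "23S ribosomal RNA"))
  list(genomes = genomes, features = features)
}

test_that("rrn extraction spans 16S start to 23S end with correct sub-regions", {
  fx <- make_contig_with_operon()
  recs <- extract_rrn_regions(fx$genomes, fx$features)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$length, 4900)
  expect_equal(recs$len_16s, 1500)
  expect_equal(recs$len_its, 400)
  expect_equal(recs$len_23s, 3000)
  # sub-regions partition the record: (0,1500), (1500,1900), (1900,4900)
  expect_equal(recs$len_16s + recs$len_its + recs$len_23s, recs$length)
  expect_equal(recs$start, 100)  # 0-based half-open on the contig
  expect_equal(recs$end, 5000)
  expect_equal(recs$seq, substr(fx$genomes$seq, 101, 5000))
  expect_equal(recs$species, "unclassified ASM1")
})

test_that("minus-strand regions are reverse-complemented to 16S->ITS->23S", {
  fx <- make_contig_with_operon()
  plus <- extract_rrn_regions(fx$genomes, fx$features)
  # same operon planted on the minus strand of a fresh contig
  rc_genomes <- data.frame(id = "chr1", seq = revcomp(fx$genomes$seq),
                           assembly_id = "ASM1")
  L <- nchar(fx$genomes$seq)
  f <- fx$features
  rc_features <- data.frame(
    contig = "chr1", type = f$type,
    start = L - f$end + 1, end = L - f$start + 1, strand = "-",
    attr = f$attr)
  minus <- extract_rrn_regions(rc_genomes, rc_features)
  expect_equal(minus$strand, "-")
  expect_identical(minus$seq, plus$seq)
  expect_equal(minus$len_its, plus$len_its)
})

test_that("a 16S without a 23S within max_its_len yields no record", {
  fx <- make_contig_with_operon()
  recs <- extract_rrn_regions(fx$genomes, fx$features, max_its_len = 399)
  expect_equal(nrow(recs), 0)
})

test_that("overlapping 16S/23S pairs are skipped with a warning", {
  fx <- make_contig_with_operon()
  fx$features$start[2] <- 1500  # 23S overlaps the 16S
  expect_warning(recs <- extract_rrn_regions(fx$genomes, fx$features),
                 "overlapping")
  expect_equal(nrow(recs), 0)
})

test_that("features beyond the contig end raise an error", {
  fx <- make_contig_with_operon()
  fx$features$end[2] <- 9000
  expect_error(extract_rrn_regions(fx$genomes, fx$features), "beyond contig")
})

test_that("two-sided length filter uses nearest-rank percentile bounds", {
  recs <- make_records(strrep("A", 3), ids = as.character(1:1000))
  recs$length <- 1:1000
  lf <- length_filter(recs, 0.5, 99.5)
  expect_equal(unname(lf$bounds), c(5, 995))
  expect_equal(nrow(lf$records), 991)

  same <- make_records(rep(strrep("A", 10), 5))
  lf2 <- length_filter(same)
  expect_equal(nrow(lf2$records), 5)
  expect_equal(unname(lf2$bounds), c(10, 10))

  lf3 <- length_filter(recs, 0, 100)  # identity on any input
  expect_equal(nrow(lf3$records), 1000)
  expect_error(length_filter(recs[0, ]), "no records")
})

test_that("greedy clustering follows the length-order centroid rule", {
  s <- rand_seq(100)
  id3 <- make_records(rep(s, 3))
  cl <- greedy_cluster(id3, radius_pct = 0)
  expect_equal(cl$n_clusters, 1)
  expect_equal(cl$clusters$n_members, 3)

  mutate_at <- function(seq, k) {
    x <- strsplit(seq, "")[[1]]
    pos <- seq(1, by = 7, length.out = k)
    x[pos] <- vapply(x[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                     character(1))
    paste(x, collapse = "")
  }
  # 95% identity: below the 97% threshold at radius 3 -> two clusters
  cl2 <- greedy_cluster(make_records(c(s, mutate_at(s, 5))), radius_pct = 3)
  expect_equal(cl2$n_clusters, 2)
  # 98% identity: joins; first record (input order on equal length) is centroid
  cl3 <- greedy_cluster(make_records(c(s, mutate_at(s, 2)),
                                     ids = c("A", "B")), radius_pct = 3)
  expect_equal(cl3$n_clusters, 1)
  expect_equal(cl3$clusters$centroid_id, "A")
})

test_that("clustering partitions the input and respects the identity radius", {
  set.seed(21)
  base <- replicate(4, rand_seq(120))
  seqs <- unlist(lapply(base, function(b) {
    c(b, vapply(1:3, function(i) mutate_sequence(b, error_model(0.01, 0, 0),
                                                 seed = i), character(1)))
  }))
  recs <- make_records(seqs)
  prev <- Inf
  for (r in 0:3) {
    cl <- greedy_cluster(recs, radius_pct = r)
    # partition: every record in exactly one cluster
    expect_setequal(cl$membership$record_id, recs$record_id)
    expect_false(anyDuplicated(cl$membership$record_id) > 0)
    expect_equal(sum(cl$clusters$n_members), nrow(recs))
    # member-to-centroid identity >= threshold
    expect_true(all(cl$membership$identity >= (100 - r) / 100 - 1e-12))
    # radius monotonicity
    expect_lte(cl$n_clusters, prev)
    prev <- cl$n_clusters
  }
})

test_that("normalized diversity is referenced to 16S at 97 percent identity", {
  counts <- data.frame(region = c("rrn", "16S"), radius_pct = c(0, 3),
                       n_clusters = c(200, 50))
  med <- c(rrn = 5.0, `16S` = 1.6)
  d <- normalized_diversity(counts, med)
  expect_equal(d$normalized_diversity[d$region == "16S"], 1.0)
  expect_equal(d$normalized_diversity[d$region == "rrn"], 1.28)
  # scale invariance in the cluster counts
  counts2 <- counts; counts2$n_clusters <- counts2$n_clusters * 2
  d2 <- normalized_diversity(counts2, med)
  expect_equal(d2$normalized_diversity, d$normalized_diversity)
  expect_error(normalized_diversity(counts[1, , drop = FALSE], med),
               "reference cell")
})

test_that("the diversity table covers all regions with a unit reference cell", {
  sim <- synth_genomes(5, divergence = 0.1, seed = 27)
  recs <- extract_rrn_regions(sim$genomes, sim$features, sim$taxonomy)
  d <- rrn_diversity(recs, radii = c(0, 3))
  expect_setequal(unique(d$region), c("rrn", "16S", "ITS", "23S"))
  ref <- d$normalized_diversity[d$region == "16S" & d$radius_pct == 3]
  expect_equal(ref, 1.0)
  # per region, loosening the radius cannot increase the cluster count
  for (reg in unique(d$region)) {
    sub <- d[d$region == reg, ]
    expect_lte(sub$n_clusters[sub$radius_pct == 3],
               sub$n_clusters[sub$radius_pct == 0])
  }
})

test_that("the database round-trips through FASTA + sidecar TSV", {
  sim <- synth_genomes(3, divergence = 0.05, seed = 33)
  recs <- extract_rrn_regions(sim$genomes, sim$features, sim$taxonomy)
  prefix <- tempfile()
  write_rrn_db(recs, prefix)
  back <- read_rrn_db(prefix)
  expect_identical(back$seq, recs$seq)
  expect_identical(back$record_id, recs$record_id)
  expect_identical(back$species, recs$species)
})

test_that("extraction recovers planted operons from simulated genomes exactly", {
  sim <- synth_genomes(4, operons_per_genome = 2, divergence = 0.08, seed = 19)
  recs <- extract_rrn_regions(sim$genomes, sim$features, sim$taxonomy)
  expect_equal(nrow(recs), nrow(sim$truth))
  expect_identical(recs$seq, sim$truth$seq)
  expect_identical(recs$species, sim$truth$species)
  expect_equal(recs$len_its, sim$truth$len_its)
  ids <- vapply(seq_len(nrow(recs)),
                function(i) segment_identity(recs$seq[i], sim$truth$seq[i]),
                numeric(1))
  expect_true(all(ids == 1))
})
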