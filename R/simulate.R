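#' Nanopore-style read error model
#'
#' Per-base substitution, insertion and deletion probabilities defining a
#' simulated chemistry. The two presets are calibrated so the median
#' edit-distance identity between a template and its noisy read matches what
#' the respective pore chemistries deliver on 1D reads: `"R9"` (sub 0.19,
#' ins 0.10, del 0.10; ~0.69 median identity) and `"R9.4"` (sub 0.078,
#' ins 0.045, del 0.045; ~0.85). The applied edit load is higher than the
#' realized edit distance because the optimal alignment explains part of the
#' noise more cheaply. The presets target identity regimes only -- they make
#' no claim about the true nanopore error structure, and homopolymer-aware
#' errors are deliberately out of scope.
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities in `[0, 1)`,
#'   summing to less than 1.
#' @return An `error_model` list.
#' @export
error_model <- function(sub_rate, ins_rate, del_rate) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1) {
    stop("rates must be in [0, 1) and sum to < 1")
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate), class = "error_model")
}

#' @rdname error_model
#' @param preset `"R9"` or `"R9.4"`.
#' @export
error_model_preset <- function(preset = c("R9.4", "R9")) {
  preset <- match.arg(preset)
  if (preset == "R9") error_model(0.19, 0.10, 0.10)
  else error_model(0.078, 0.045, 0.045)
}

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitutions only, at the given per-base rate
point_mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  hit <- runif(length(x)) < rate
  if (any(hit)) {
    shift <- sample.int(3, sum(hit), replace = TRUE)
    x[hit] <- DNA_BASES[(match(x[hit], DNA_BASES) - 1L + shift) %% 4L + 1L]
  }
  paste(x, collapse = "")
}

# concrete instantiation of degenerate primer positions
resolve_iupac <- function(seq) {
  x <- strsplit(seq, "")[[1]]
  degen <- !x %in% DNA_BASES
  if (any(degen)) {
    x[degen] <- vapply(x[degen],
                       function(c) sample(IUPAC_SETS[[c]], 1), character(1))
  }
  paste(x, collapse = "")
}

#' Apply a read error model to a sequence
#'
#' Per-position process: each base is deleted with `del_rate`, otherwise
#' substituted to a different base with `sub_rate`; independently, a random
#' base is inserted at each of the sequence's insertion slots (before each
#' surviving base and at the end) with `ins_rate`. Deterministic for a fixed
#' seed. The number of edit operations applied is attached as attribute
#' `n_edits` so callers can record the planted identity without re-aligning.
#'
#' @param seq Non-empty nucleotide string.
#' @param model An [error_model()].
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return The noisy sequence, with attribute `n_edits`.
#' @export
mutate_sequence <- function(seq, model, seed = NULL) {
  if (!nzchar(seq)) stop("sequence must be non-empty")
  run <- function() {
    x <- strsplit(toupper(seq), "")[[1]]
    del <- runif(length(x)) < model$del_rate
    x <- x[!del]
    n_sub <- 0L
    if (length(x) > 0 && model$sub_rate > 0) {
      sub <- runif(length(x)) < model$sub_rate
      n_sub <- sum(sub)
      if (n_sub > 0) {
        pos <- match(x[sub], DNA_BASES)
        pos[is.na(pos)] <- sample.int(4, sum(is.na(pos)), replace = TRUE)
        shift <- sample.int(3, n_sub, replace = TRUE)
        x[sub] <- DNA_BASES[(pos - 1L + shift) %% 4L + 1L]
      }
    }
    ins <- runif(length(x) + 1L) < model$ins_rate
    n_ins <- sum(ins)
    if (n_ins > 0) {
      out <- character(length(x) + n_ins)
      cum <- cumsum(ins)
      if (length(x) > 0) out[seq_along(x) + cum[seq_along(x)]] <- x
      slot <- which(ins)
      out[slot - 1L + cum[slot]] <- sample(DNA_BASES, n_ins, replace = TRUE)
      x <- out
    }
    structure(paste(x, collapse = ""), n_edits = sum(del) + n_sub + n_ins)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate annotated synthetic genomes with planted rrn operons
#'
#' Each species genome is one contig carrying `operons_per_genome` copies of a
#' species-specific rrn region (16S ~1.6 kb, ITS ~0.5 kb, 23S ~3.0 kb; region
#' lengths drawn around the empirical bacterial means 1612 +/- 75, 488 +/-
#' 186 and 3036 +/- 160 nt) on random strands, separated by random spacers.
#' Species sequences diverge from a shared ancestor by roughly `divergence`
#' pairwise substitutions; the ITS additionally varies in length and may carry
#' a tRNA-like insert, the main structural signal distinguishing close
#' species. At `divergence = 0` species are exact clones (no length variation
#' either), so downstream clustering collapses them into one cluster.
#'
#' @param n_species Number of species (>= 1).
#' @param operons_per_genome rrn copies planted per genome (copies are
#'   identical within a genome).
#' @param divergence Pairwise substitution fraction between species, in
#'   `[0, 0.3]`.
#' @param seed Optional integer seed; output is byte-identical per seed.
#' @param species_names Optional character vector of binomials (defaults to
#'   synthetic binomials with one genus per species).
#' @return A `synth_genomes` list: `genomes` (data frame `id`, `seq`,
#'   `assembly_id`), `features` (GFF3-style 1-based feature table as from
#'   [read_gff_features()]), `taxonomy` (`assembly_id`, `species`), and
#'   `truth` (one row per planted operon, with the oriented rrn sequence and
#'   sub-region lengths).
#' @export
synth_genomes <- function(n_species, operons_per_genome = 1, divergence = 0.1,
                          seed = NULL, species_names = NULL) {
  if (n_species < 1) stop("n_species must be >= 1")
  if (divergence < 0 || divergence > 0.3) stop("divergence must be in [0, 0.3]")
  if (is.null(species_names)) {
    species_names <- sprintf("Synthbacter%02d simulatus", seq_len(n_species))
  }
  stopifnot(length(species_names) == n_species)
  run <- function() {
    anc16 <- rand_dna(1612)
    anc23 <- rand_dna(3036)
    ancITS <- rand_dna(488)
    genomes <- vector("list", n_species)
    feats <- list()
    truth <- list()
    for (si in seq_len(n_species)) {
      s16 <- point_mutate(anc16, divergence / 2)
      s23 <- point_mutate(anc23, divergence / 2)
      its <- point_mutate(ancITS, divergence / 2)
      if (divergence > 0) {
        # structural ITS variation: resize and optional tRNA-like insert
        target <- round(rnorm(1, 488, 186))
        target <- min(max(target, 80L), 1400L)
        if (target <= nchar(its)) {
          its <- substr(its, 1, target)
        } else {
          its <- paste0(its, rand_dna(target - nchar(its)))
        }
        if (runif(1) < 0.5) {
          at <- sample.int(nchar(its) - 1L, 1)
          its <- paste0(substr(its, 1, at), rand_dna(sample(74:95, 1)),
                        substr(its, at + 1, nchar(its)))
        }
      }
      rrn <- paste0(s16, its, s23)
      assembly <- sprintf("SYN%03d", si)
      contig <- paste0(assembly, "_c1")
      parts <- rand_dna(sample(200:400, 1))
      for (oi in seq_len(operons_per_genome)) {
        strand <- sample(c("+", "-"), 1)
        g_start <- nchar(parts) + 1L  # 1-based start of the operon
        segment <- if (strand == "+") rrn else revcomp(rrn)
        parts <- paste0(parts, segment)
        g_end <- nchar(parts)
        if (strand == "+") {
          c16 <- c(g_start, g_start + nchar(s16) - 1L)
          c23 <- c(g_end - nchar(s23) + 1L, g_end)
        } else {
          c23 <- c(g_start, g_start + nchar(s23) - 1L)
          c16 <- c(g_end - nchar(s16) + 1L, g_end)
        }
        feats[[length(feats) + 1L]] <- data.frame(
          contig = contig, type = c("rRNA_16S", "rRNA_23S"),
          start = c(c16[1], c23[1]), end = c(c16[2], c23[2]),
          strand = strand,
          attr = c("16S ribosomal RNA", "23S ribosomal RNA"))
        truth[[length(truth) + 1L]] <- data.frame(
          species = species_names[si], assembly_id = assembly,
          contig = contig, start = g_start - 1L, end = g_end,
          strand = strand, seq = rrn, len_16s = nchar(s16),
          len_its = nchar(its), len_23s = nchar(s23))
        parts <- paste0(parts, rand_dna(sample(300:800, 1)))
      }
      genomes[[si]] <- data.frame(id = contig, seq = parts,
                                  assembly_id = assembly)
    }
    structure(list(
      genomes = do.call(rbind, genomes),
      features = do.call(rbind, feats),
      taxonomy = data.frame(assembly_id = sprintf("SYN%03d", seq_len(n_species)),
                            species = species_names),
      truth = do.call(rbind, truth)), class = "synth_genomes")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write a synthetic genome set to FASTA + GFF3 + taxonomy TSV
#'
#' @param sim A [synth_genomes()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synth_genomes <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genomes.fna")
  gff <- file.path(dir, "annotations.gff3")
  tax <- file.path(dir, "taxonomy.tsv")
  write_seqs(sim$genomes, fa, format = "fasta")
  f <- sim$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$contig,
    ranges = IRanges::IRanges(start = f$start, end = f$end),
    strand = f$strand,
    type = "rRNA", source = "rrnprofile", product = f$attr)
  rtracklayer::export(gr, gff, format = "gff3")
  write.table(sim$taxonomy, tax, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, gff = gff, taxonomy = tax))
}

#' Simulate dual-barcoded noisy amplicon reads with truth labels
#'
#' Emulates a multiplexed long-amplicon run: per sample, species are drawn
#' multinomially from the community design; each read's template is
#' `probe_F + rrn + revcomp(probe_R)` (degenerate primer positions resolved to
#' concrete bases per read); the read is flipped to the minus strand with
#' `strand_flip_prob`, truncated (keeping a 5' prefix of at least
#' `trunc_min_frac` of the amplicon) with `trunc_prob`, and run through the
#' error model. Reads from all samples are pooled and shuffled. One truth row
#' is emitted per read.
#'
#' @param db rrn records providing templates (`record_id`, `species`, `seq`);
#'   typically the `truth` table of [synth_genomes()] or an extracted
#'   database. Design taxa must be resolvable to db species.
#' @param designs Named list of community designs (name = sample id), each a
#'   data frame `taxon`, `proportion` summing to 1.
#' @param specs Barcode specs covering all sample ids
#'   (see [read_barcode_specs()]).
#' @param n_reads Reads per sample: a single number or a vector named by
#'   sample id.
#' @param model An [error_model()].
#' @param seed Optional integer seed.
#' @param strand_flip_prob Probability a read is reported minus-strand
#'   (default 0.5).
#' @param trunc_prob,trunc_min_frac Truncation probability (default 0.2) and
#'   minimum retained fraction (default 0.3).
#' @return List with `reads` (data frame `id`, `seq`, `qual`; qualities are a
#'   constant placeholder) and `truth` (`read_id`, `sample_id`, `species`,
#'   `record_id`, `strand`, `truncated`, `planted_identity`).
#' @export
simulate_reads <- function(db, designs, specs, n_reads,
                           model = error_model_preset("R9.4"), seed = NULL,
                           strand_flip_prob = 0.5, trunc_prob = 0.2,
                           trunc_min_frac = 0.3) {
  if (is.null(names(designs)) || any(!nzchar(names(designs)))) {
    stop("designs must be a named list (names = sample ids)")
  }
  miss <- setdiff(names(designs), specs$sample_id)
  if (length(miss)) stop("no barcode spec for sample(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(names(n_reads))) {
    n_reads <- stats::setNames(rep(n_reads, length.out = length(designs)),
                               names(designs))
  }
  if (!is.null(db$record_id) && anyDuplicated(db$record_id)) {
    stop("duplicate record_id in db")
  }
  run <- function() {
    reads <- list()
    truth <- list()
    for (s in names(designs)) {
      design <- designs[[s]]
      if (abs(sum(design$proportion) - 1) > 1e-6) {
        stop("design proportions for ", s, " sum to ", sum(design$proportion))
      }
      spec <- specs[specs$sample_id == s, , drop = FALSE]
      pF <- paste0(spec$barcode, spec$fwd_primer)
      pR <- paste0(spec$barcode, spec$rev_primer)
      n <- n_reads[[s]]
      if (n == 0) next
      counts <- drop(rmultinom(1, n, design$proportion))
      for (ti in seq_along(counts)) {
        if (counts[ti] == 0) next
        taxon <- design$taxon[ti]
        recs <- which(db$species == taxon)
        if (length(recs) == 0) stop("design taxon not in db: ", taxon)
        for (r in seq_len(counts[ti])) {
          rec <- if (length(recs) == 1) recs else sample(recs, 1)
          amplicon <- paste0(resolve_iupac(pF), db$seq[rec],
                             revcomp(resolve_iupac(pR)))
          strand <- if (runif(1) < strand_flip_prob) "-" else "+"
          if (strand == "-") amplicon <- revcomp(amplicon)
          truncated <- runif(1) < trunc_prob
          if (truncated) {
            keep <- ceiling(runif(1, trunc_min_frac, 1) * nchar(amplicon))
            amplicon <- substr(amplicon, 1, keep)
          }
          noisy <- mutate_sequence(amplicon, model)
          planted <- 1 - attr(noisy, "n_edits") /
            max(nchar(amplicon), nchar(noisy))
          reads[[length(reads) + 1L]] <- data.frame(
            id = "", seq = as.character(noisy))
          truth[[length(truth) + 1L]] <- data.frame(
            read_id = "", sample_id = s, species = taxon,
            record_id = if (!is.null(db$record_id)) db$record_id[rec] else
              as.character(rec),
            strand = strand, truncated = truncated,
            planted_identity = planted)
        }
      }
    }
    if (length(reads) == 0) {
      return(list(reads = data.frame(id = character(), seq = character(),
                                     qual = character()),
                  truth = data.frame(read_id = character(),
                                     sample_id = character(),
                                     species = character(),
                                     record_id = character(),
                                     strand = character(),
                                     truncated = logical(),
                                     planted_identity = numeric())))
    }
    reads <- do.call(rbind, reads)
    truth <- do.call(rbind, truth)
    ids <- sprintf("read_%06d", seq_len(nrow(reads)))
    reads$id <- ids
    truth$read_id <- ids
    shuffle <- sample.int(nrow(reads))
    reads <- reads[shuffle, , drop = FALSE]
    truth <- truth[shuffle, , drop = FALSE]
    rownames(reads) <- rownames(truth) <- NULL
    reads$qual <- strrep("I", nchar(reads$seq))
    list(reads = reads, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
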