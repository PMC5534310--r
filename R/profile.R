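#' Length-filter a read set
#'
#' Keeps reads with `min_len <= length <= max_len` (bounds inclusive). The
#' defaults, 1500-7000 nt, retain reads carrying at least one full 16S-gene
#' equivalent of sequence while discarding concatemers and fragments.
#'
#' @param reads Data frame with columns `id`, `seq`.
#' @param min_len,max_len Inclusive length bounds (defaults 1500 and 7000).
#' @return List with `reads` (kept rows) and `report` (named counts:
#'   `n_in`, `n_kept`, `n_removed`).
#' @export
length_filter_reads <- function(reads, min_len = 1500, max_len = 7000) {
  lens <- nchar(reads$seq)
  keep <- lens >= min_len & lens <= max_len
  rrn_log("length_filter_reads: kept ", sum(keep), "/", length(keep))
  list(reads = reads[keep, , drop = FALSE],
       report = c(n_in = length(keep), n_kept = sum(keep),
                  n_removed = sum(!keep)))
}

#' Competitive best-hit mapping of reads against an rrn database
#'
#' Every read is aligned against every database record on both strands and the
#' single highest-scoring hit is kept (competitive mapping). Score ties are
#' broken by higher matched-segment identity, then by lexicographically
#' smallest `record_id`, and the hit is flagged ambiguous. Identity is the
#' edit-distance identity of the matched query and target segments
#' ([segment_identity()]).
#'
#' The default seed-and-extend heuristic aligner gives a large speedup on
#' multi-kb reads; `method = "full"` forces full dynamic programming.
#'
#' @param reads Data frame with columns `id`, `seq`; every read must be at
#'   least 50 nt (shorter fragments cannot be plausible amplicon pieces).
#' @param db rrn database data frame (`record_id`, `species`, `seq`).
#' @param scoring A [scoring_scheme()].
#' @param method `"heuristic"` (default) or `"full"`, see [local_align()].
#' @param k,band Heuristic seeding parameters, see [local_align()].
#' @return Data frame of best hits, one row per read: `read_id`, `ref_id`,
#'   `species`, `strand`, `score`, `identity`, `aln_len`, `qstart`, `qend`,
#'   `tstart`, `tend` (0-based half-open, on the aligned orientation of the
#'   read), `ambiguous`.
#' @export
competitive_map <- function(reads, db, scoring = scoring_scheme(),
                            method = c("heuristic", "full"), k = 11,
                            band = 151) {
  method <- match.arg(method)
  if (nrow(db) == 0) stop("empty reference database")
  if (any(nchar(reads$seq) < 50)) {
    stop("read shorter than 50 nt: ",
         reads$id[nchar(reads$seq) < 50][1])
  }
  ord_db <- order(db$record_id)
  db <- db[ord_db, , drop = FALSE]
  db_seq <- toupper(db$seq)
  n_db <- nrow(db)
  empty_aln <- list(score = 0L, qstart = 0L, qend = 0L, tstart = 0L,
                    tend = 0L, n_match = 0L, n_mismatch = 0L, n_gap = 0L,
                    n_gap_cols = 0L)
  hits <- vector("list", nrow(reads))
  for (ri in seq_len(nrow(reads))) {
    fwd <- toupper(reads$seq[ri])
    rev <- revcomp(fwd)
    # candidates indexed 1..n_db on the + strand, then 1..n_db on -
    cand_strand <- rep(c("+", "-"), each = n_db)
    cand_di <- rep(seq_len(n_db), 2)
    aln_cache <- vector("list", 2L * n_db)
    if (method == "heuristic") {
      mf <- cpp_map_read(fwd, db_seq, as.integer(k), as.integer(band),
                         scoring$match, scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend)
      mr <- cpp_map_read(rev, db_seq, as.integer(k), as.integer(band),
                         scoring$match, scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend)
      scores <- c(mf$score, mr$score)
      # traceback alignment recomputed over the stored band, winner(s) only
      aln_for <- function(i) {
        if (!is.null(aln_cache[[i]])) return(aln_cache[[i]])
        a <- if (scores[i] <= 0) empty_aln else {
          row <- if (i <= n_db) mf[i, ] else mr[i - n_db, ]
          q <- if (cand_strand[i] == "+") fwd else rev
          cpp_banded_local_align(q, db_seq[cand_di[i]], row$band_lo,
                                 row$band_hi, scoring$match, scoring$mismatch,
                                 scoring$gap_open, scoring$gap_extend, FALSE)
        }
        aln_cache[[i]] <<- a
        a
      }
    } else {
      for (i in seq_len(2L * n_db)) {
        q <- if (cand_strand[i] == "+") fwd else rev
        aln_cache[[i]] <- cpp_local_align(q, db_seq[cand_di[i]],
                                          scoring$match, scoring$mismatch,
                                          scoring$gap_open,
                                          scoring$gap_extend, FALSE)
      }
      scores <- vapply(aln_cache, `[[`, integer(1), "score")
      aln_for <- function(i) aln_cache[[i]]
    }
    identity_for <- function(i) {
      a <- aln_for(i)
      if (a$score <= 0) return(0)
      q <- if (cand_strand[i] == "+") fwd else rev
      qseg <- substr(q, a$qstart + 1, a$qend)
      tseg <- substr(db_seq[cand_di[i]], a$tstart + 1, a$tend)
      # long matched segments use a banded (width 151) edit distance; the
      # optimal path virtually never drifts further under these error rates
      bd <- if (max(nchar(qseg), nchar(tseg)) > 2000) 151L else 0L
      d <- cpp_banded_edit_distance(qseg, tseg, bd)
      1 - d / max(nchar(qseg), nchar(tseg))
    }
    top <- which(scores == max(scores))
    if (length(top) > 1) {
      idns <- vapply(top, identity_for, numeric(1))
      # best identity wins; db order (sorted by record_id) breaks exact ties
      best <- top[order(-idns)[1]]
      idn <- max(idns)
      # a +/- tie on the same reference is not an ambiguous taxon call
      ambiguous <- length(unique(cand_di[top])) > 1
    } else {
      best <- top
      idn <- identity_for(best)
      ambiguous <- FALSE
    }
    a <- aln_for(best)
    hits[[ri]] <- data.frame(
      read_id = reads$id[ri], ref_id = db$record_id[cand_di[best]],
      species = db$species[cand_di[best]], strand = cand_strand[best],
      score = a$score, identity = idn,
      aln_len = a$n_match + a$n_mismatch + a$n_gap_cols,
      qstart = a$qstart, qend = a$qend, tstart = a$tstart, tend = a$tend,
      ambiguous = ambiguous)
  }
  out <- do.call(rbind, hits)
  rrn_log("competitive_map: ", nrow(out), " reads mapped against ",
          nrow(db), " references")
  out
}

hit_identity <- function(cc, oriented_read, db) {
  a <- cc$aln
  if (a$score <= 0) return(0)
  qseg <- substr(oriented_read, a$query_span[1] + 1, a$query_span[2])
  tseg <- substr(db$seq[cc$di], a$target_span[1] + 1, a$target_span[2])
  segment_identity(qseg, tseg)
}

#' Percentile identity filter for alignment hits
#'
#' Removes hits with identity up to (and including) the nearest-rank
#' percentile of the per-sample identity distribution; only hits strictly
#' above the threshold survive. Run per sample, never on identities pooled
#' across samples. The 50th percentile suits higher-error chemistries (R9);
#' 25 suits R9.4-grade reads.
#'
#' @param hits Hit data frame from [competitive_map()] (non-empty).
#' @param identity_percentile Percentile in `[0, 100]` (default 50).
#' @return List with `hits` (surviving rows), `threshold` (the effective
#'   identity cut), and `n_removed`.
#' @export
identity_filter <- function(hits, identity_percentile = 50) {
  if (nrow(hits) == 0) stop("no hits to filter")
  pt <- percentile_threshold(hits$identity, identity_percentile)
  keep <- hits$identity > pt$threshold
  if (!any(keep)) {
    warning("no hits above the identity threshold (all identities equal?)")
  }
  rrn_log("identity_filter: kept ", sum(keep), "/", nrow(hits),
          " hits above identity ", round(pt$threshold, 4))
  list(hits = hits[keep, , drop = FALSE], threshold = pt$threshold,
       n_removed = sum(!keep))
}

#' Abundance profile from filtered hits
#'
#' Aggregates identity-filtered hits per taxon, removes singleton taxa (taxa
#' supported by exactly one read), and computes relative proportions over the
#' remaining reads. Taxa at or above the predominance threshold
#' (`min_abundance`, default 1%) are flagged predominant -- the reporting rule
#' for calling a species present in a mock community.
#'
#' @param hits Hit data frame (already identity-filtered).
#' @param min_abundance Predominance threshold on relative proportion
#'   (default 0.01).
#' @param remove_singletons Drop taxa with exactly one read (default `TRUE`).
#' @param rank `"species"` (default) or `"genus"`; genus is the first word of
#'   the species binomial (used when comparing with short-read platforms that
#'   cannot resolve species).
#' @param drop_ambiguous Drop hits flagged ambiguous before aggregating
#'   (default `FALSE`: ambiguous hits count toward their chosen taxon).
#' @return An `abundance_profile` list: `taxa` (data frame `taxon`, `count`,
#'   `proportion`, `predominant`, ordered by decreasing count), `n_reads`
#'   (reads profiled), `n_singletons` (reads removed as singletons),
#'   `rank`, `min_abundance`.
#' @export
build_profile <- function(hits, min_abundance = 0.01, remove_singletons = TRUE,
                          rank = c("species", "genus"), drop_ambiguous = FALSE) {
  rank <- match.arg(rank)
  if (drop_ambiguous) hits <- hits[!hits$ambiguous, , drop = FALSE]
  if (nrow(hits) == 0) stop("no hits to profile")
  taxon <- if (rank == "genus") sub("\\s.*$", "", hits$species) else hits$species
  counts <- sort(table(taxon), decreasing = TRUE)
  n_singletons <- 0L
  if (remove_singletons) {
    single <- counts == 1
    n_singletons <- sum(counts[single])
    counts <- counts[!single]
  }
  if (length(counts) == 0) stop("no taxa left after singleton removal")
  prop <- as.numeric(counts) / sum(counts)
  taxa <- data.frame(taxon = names(counts), count = as.integer(counts),
                     proportion = prop, predominant = prop >= min_abundance,
                     row.names = NULL)
  structure(list(taxa = taxa, n_reads = sum(taxa$count),
                 n_singletons = n_singletons, rank = rank,
                 min_abundance = min_abundance),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("abundance profile (%s level): %d taxa over %d reads, %d predominant\n",
              x$rank, nrow(x$taxa), x$n_reads, sum(x$taxa$predominant)))
  print(utils::head(x$taxa, 10))
  invisible(x)
}

#' Coverage bias against a community design
#'
#' For every taxon of the design, the coverage bias is the log2 fold-change of
#' its observed relative proportion against the theoretically expected one:
#' `bias = log2(observed / expected)`, rounded to `decimals`. Taxa the design
#' expects but the profile does not contain get observed proportion 0 and an
#' undefined bias (`NA`, printed as `"ND"`). Observed taxa absent from the
#' design are returned separately in the `"unexpected"` attribute.
#'
#' @param profile An [build_profile()] result.
#' @param design Community design data frame (`taxon`, `proportion`), see
#'   [read_community_design()].
#' @param decimals Rounding of the reported bias (default 2).
#' @return Data frame `taxon`, `expected`, `observed`, `bias`, with attribute
#'   `unexpected` (profile rows not covered by the design).
#' @export
coverage_bias <- function(profile, design, decimals = 2) {
  taxa <- profile$taxa
  if (any(design$proportion <= 0 & design$taxon %in% taxa$taxon)) {
    stop("design proportion is zero for an observed taxon")
  }
  i <- match(design$taxon, taxa$taxon)
  observed <- ifelse(is.na(i), 0, taxa$proportion[i])
  bias <- ifelse(observed > 0, round(log2(observed / design$proportion),
                                     decimals), NA_real_)
  out <- data.frame(taxon = design$taxon, expected = design$proportion,
                    observed = observed, bias = bias)
  attr(out, "unexpected") <- taxa[!taxa$taxon %in% design$taxon, , drop = FALSE]
  out
}

#' Per-sample profiling pipeline
#'
#' Chains the per-sample stages: read length filter, competitive best-hit
#' mapping, per-sample percentile identity filter, singleton removal and
#' abundance estimation. The returned accounting satisfies the conservation
#' identity: every input read is either removed by the length filter, removed
#' by the identity filter, removed as a singleton, or counted in the profile.
#'
#' @param reads Data frame with columns `id`, `seq` (one demultiplexed
#'   sample).
#' @param db rrn database data frame.
#' @param min_len,max_len Read length bounds, see [length_filter_reads()].
#' @param identity_percentile Identity percentile cut, see
#'   [identity_filter()]; use 50 for R9-grade reads, 25 for R9.4.
#' @param min_abundance,remove_singletons,rank,drop_ambiguous See
#'   [build_profile()].
#' @param scoring,method,k,band See [competitive_map()].
#' @return List: `profile`, `hits` (surviving hits), `identity_threshold`,
#'   and `accounting` (named integer vector with `n_in`, `n_length_removed`,
#'   `n_identity_removed`, `n_singletons`, `n_profiled`).
#' @export
profile_sample <- function(reads, db, min_len = 1500, max_len = 7000,
                           identity_percentile = 50, min_abundance = 0.01,
                           remove_singletons = TRUE,
                           rank = c("species", "genus"),
                           drop_ambiguous = FALSE,
                           scoring = scoring_scheme(),
                           method = c("heuristic", "full"), k = 11,
                           band = 151) {
  rank <- match.arg(rank)
  method <- match.arg(method)
  lf <- length_filter_reads(reads, min_len, max_len)
  if (nrow(lf$reads) == 0) stop("no reads left after length filtering")
  hits <- competitive_map(lf$reads, db, scoring, method, k, band)
  idf <- identity_filter(hits, identity_percentile)
  prof <- build_profile(idf$hits, min_abundance, remove_singletons, rank,
                        drop_ambiguous)
  n_ambig_dropped <- if (drop_ambiguous) sum(idf$hits$ambiguous) else 0L
  acct <- c(n_in = nrow(reads),
            n_length_removed = unname(lf$report["n_removed"]),
            n_identity_removed = idf$n_removed,
            n_ambiguous_removed = n_ambig_dropped,
            n_singletons = prof$n_singletons,
            n_profiled = prof$n_reads)
  stopifnot(acct["n_in"] == sum(acct[c("n_length_removed", "n_identity_removed",
                                       "n_ambiguous_removed", "n_singletons",
                                       "n_profiled")]))
  list(profile = prof, hits = idf$hits, identity_threshold = idf$threshold,
       accounting = acct)
}
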