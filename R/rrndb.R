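#' Extract rrn (16S-ITS-23S) regions from annotated genomes
#'
#' Pairs 16S and 23S rRNA gene annotations lying on the same contig and strand
#' in transcriptional order 16S -> ITS -> 23S, with an inter-gene gap (the ITS)
#' of at most `max_its_len` bases, and extracts one rrn record per pair. Every
#' operon copy of a genome is emitted. Minus-strand regions are
#' reverse-complemented so the stored sequence always reads 16S -> ITS -> 23S.
#' Each 16S gene is paired with the nearest qualifying 23S gene downstream in
#' transcriptional direction, and each 23S gene is used at most once.
#' Overlapping 16S/23S pairs are skipped with a warning.
#'
#' @param genomes Data frame of contigs with columns `id`, `seq` and optional
#'   `assembly_id` (defaults to the contig id), e.g. from [read_seqs()].
#' @param features Feature data frame from [read_gff_features()] (1-based
#'   inclusive coordinates).
#' @param taxonomy Optional data frame mapping `assembly_id` to `species`.
#'   Assemblies without an entry are labeled `"unclassified <assembly_id>"`
#'   and kept.
#' @param max_its_len Maximum ITS (inter-gene gap) length in bases. The
#'   default 1500 is generous against the ~490 +/- 190 nt ITS lengths seen in
#'   bacterial genomes while still excluding spurious cross-operon pairs.
#' @return Data frame of rrn records: `record_id`, `species`, `assembly_id`,
#'   `contig`, `start`, `end` (0-based half-open on the contig), `strand`,
#'   `length`, `len_16s`, `len_its`, `len_23s`, `seq`. The three sub-region
#'   lengths partition the sequence in order 16S, ITS, 23S.
#' @export
extract_rrn_regions <- function(genomes, features, taxonomy = NULL,
                                max_its_len = 1500) {
  if (!all(c("id", "seq") %in% names(genomes))) {
    stop("genomes must have columns id, seq")
  }
  if (is.null(genomes$assembly_id)) genomes$assembly_id <- genomes$id
  missing_contigs <- setdiff(unique(features$contig[features$type != "other"]),
                             genomes$id)
  if (length(missing_contigs)) {
    stop("features reference contigs absent from genomes: ",
         paste(missing_contigs, collapse = ", "))
  }
  rows <- list()
  for (ci in seq_len(nrow(genomes))) {
    contig <- genomes$id[ci]
    cseq <- toupper(genomes$seq[ci])
    clen <- nchar(cseq)
    fs <- features[features$contig == contig & features$type != "other", , drop = FALSE]
    if (nrow(fs) == 0) next
    if (any(fs$end > clen)) {
      stop("feature beyond contig end on ", contig)
    }
    for (st in c("+", "-")) {
      f16 <- fs[fs$type == "rRNA_16S" & fs$strand == st, , drop = FALSE]
      f23 <- fs[fs$type == "rRNA_23S" & fs$strand == st, , drop = FALSE]
      if (nrow(f16) == 0 || nrow(f23) == 0) next
      used23 <- logical(nrow(f23))
      # transcription runs left-to-right on + and right-to-left on -
      ord16 <- if (st == "+") order(f16$start) else order(-f16$start)
      for (i in ord16) {
        if (st == "+") {
          gap <- f23$start - f16$end[i] - 1L
          cand <- which(!used23 & f23$start > f16$start[i] & gap <= max_its_len)
          if (length(cand) == 0) next
          j <- cand[which.min(f23$start[cand])]
        } else {
          gap <- f16$start[i] - f23$end - 1L
          cand <- which(!used23 & f23$end < f16$end[i] & gap <= max_its_len)
          if (length(cand) == 0) next
          j <- cand[which.max(f23$end[cand])]
        }
        if (gap[j] < 0) {
          warning("overlapping 16S/23S pair on ", contig, " (", st,
                  " strand), record skipped")
          used23[j] <- TRUE
          next
        }
        used23[j] <- TRUE
        if (st == "+") {
          g_start <- f16$start[i]; g_end <- f23$end[j]
        } else {
          g_start <- f23$start[j]; g_end <- f16$end[i]
        }
        seq <- substr(cseq, g_start, g_end)
        if (st == "-") seq <- revcomp(seq)
        len16 <- f16$end[i] - f16$start[i] + 1L
        len23 <- f23$end[j] - f23$start[j] + 1L
        start0 <- g_start - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = sprintf("%s:%d-%d:%s", contig, start0, g_end, st),
          assembly_id = genomes$assembly_id[ci],
          contig = contig, start = start0, end = g_end, strand = st,
          length = nchar(seq), len_16s = len16, len_its = gap[j],
          len_23s = len23, seq = seq)
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(record_id = character(), assembly_id = character(),
                      contig = character(), start = integer(), end = integer(),
                      strand = character(), length = integer(),
                      len_16s = integer(), len_its = integer(),
                      len_23s = integer(), seq = character())
  } else {
    out <- do.call(rbind, rows)
  }
  out$species <- assign_species(out$assembly_id, taxonomy)
  rrn_cols <- c("record_id", "species", "assembly_id", "contig", "start",
                "end", "strand", "length", "len_16s", "len_its", "len_23s",
                "seq")
  rrn_log("extract_rrn_regions: ", nrow(out), " records from ",
          nrow(genomes), " contigs")
  out[rrn_cols]
}

assign_species <- function(assembly_id, taxonomy) {
  if (length(assembly_id) == 0) return(character(0))
  if (is.null(taxonomy)) return(paste("unclassified", assembly_id))
  i <- match(assembly_id, taxonomy$assembly_id)
  sp <- taxonomy$species[i]
  ifelse(is.na(sp), paste("unclassified", assembly_id), sp)
}

#' Two-sided percentile length filter for rrn records
#'
#' Discards records whose length falls outside the nearest-rank percentile
#' bounds of the length distribution, removing incompletely or aberrantly
#' annotated regions. The default (0.5, 99.5) keeps the central 99 percent of
#' the distribution; `(0, 100)` keeps everything.
#'
#' @param records rrn record data frame from [extract_rrn_regions()].
#' @param low_pct,high_pct Percentile bounds (defaults 0.5 and 99.5).
#' @return List with `records` (rows with
#'   `low_bound <= length <= high_bound`) and `bounds = c(low, high)`.
#' @export
length_filter <- function(records, low_pct = 0.5, high_pct = 99.5) {
  if (nrow(records) == 0) stop("no records to filter")
  if (low_pct < 0 || high_pct > 100 || low_pct >= high_pct) {
    stop("require 0 <= low_pct < high_pct <= 100")
  }
  lens <- records$length
  lo <- percentile_threshold(lens, low_pct)$threshold
  hi <- percentile_threshold(lens, high_pct)$threshold
  keep <- lens >= lo & lens <= hi
  rrn_log("length_filter: kept ", sum(keep), "/", length(keep),
          " records in [", lo, ", ", hi, "]")
  list(records = records[keep, , drop = FALSE], bounds = c(low = lo, high = hi))
}

#' Greedy centroid clustering at an identity radius
#'
#' Clusters sequences at an identity threshold of `100 - radius_pct` percent,
#' USEARCH-style: records are processed in decreasing length order (ties
#' broken by input order); each record joins the first existing centroid whose
#' end-to-end edit-distance identity (see [segment_identity()]) is at least
#' the threshold, otherwise it founds a new centroid. The taxonomy label of a
#' cluster is inherited from its centroid. Deterministic for a fixed input.
#'
#' @param records rrn record data frame (needs `record_id`, `seq`; `species`
#'   optional), or any data frame with those columns.
#' @param radius_pct Identity radius 0-3 (threshold `100 - radius_pct` %).
#' @return An `rrn_clusters` list: `membership` (data frame `record_id`,
#'   `centroid_id`, `identity`), `clusters` (data frame `centroid_id`,
#'   `n_members`, `species`), `radius_pct`, `n_clusters`.
#' @export
greedy_cluster <- function(records, radius_pct = 0) {
  if (nrow(records) == 0) stop("no records to cluster")
  if (!radius_pct %in% 0:3) stop("radius_pct must be an integer in 0..3")
  thr <- (100 - radius_pct) / 100
  ord <- order(-nchar(records$seq))  # stable: ties keep input order
  seqs <- toupper(records$seq[ord])
  ids <- records$record_id[ord]
  species <- if (!is.null(records$species)) records$species[ord] else
    rep(NA_character_, length(ord))
  centroid_idx <- integer(0)
  assigned <- integer(length(ids))
  identity <- numeric(length(ids))
  for (i in seq_along(ids)) {
    hit <- 0L
    for (ci in seq_along(centroid_idx)) {
      idn <- segment_identity(seqs[i], seqs[centroid_idx[ci]])
      if (idn >= thr) { hit <- ci; identity[i] <- idn; break }
    }
    if (hit == 0L) {
      centroid_idx <- c(centroid_idx, i)
      assigned[i] <- length(centroid_idx)
      identity[i] <- 1
    } else {
      assigned[i] <- hit
    }
  }
  centroid_ids <- ids[centroid_idx]
  membership <- data.frame(record_id = ids,
                           centroid_id = centroid_ids[assigned],
                           identity = identity)
  clusters <- data.frame(centroid_id = centroid_ids,
                         n_members = as.integer(table(assigned)[as.character(seq_along(centroid_idx))]),
                         species = species[centroid_idx])
  rrn_log("greedy_cluster: ", nrow(clusters), " clusters from ",
          length(ids), " records at radius ", radius_pct)
  structure(list(membership = membership, clusters = clusters,
                 radius_pct = radius_pct, n_clusters = nrow(clusters)),
            class = "rrn_clusters")
}

#' Normalized diversity of rrn sub-regions across cluster radii
#'
#' For each (region, radius) cell, diversity is the cluster count divided by
#' the median region length in kb, referenced against the 16S region clustered
#' at 97% identity (radius 3), the canonical species-assignment threshold:
#' `D = (N(region, radius) / median_kb(region)) / (N(16S, 3) / median_kb(16S))`.
#' The reference cell therefore has normalized diversity exactly 1.
#'
#' @param cluster_counts Data frame with columns `region`, `radius_pct`,
#'   `n_clusters`.
#' @param median_lengths_kb Named numeric vector of median region lengths in
#'   kb, one entry per region.
#' @return The input data frame with `median_kb` and `normalized_diversity`
#'   columns added.
#' @export
normalized_diversity <- function(cluster_counts, median_lengths_kb) {
  need <- c("region", "radius_pct", "n_clusters")
  if (!all(need %in% names(cluster_counts))) {
    stop("cluster_counts must have columns ", paste(need, collapse = ", "))
  }
  ref <- cluster_counts$region == "16S" & cluster_counts$radius_pct == 3
  if (!any(ref)) stop("reference cell (16S at radius 3) missing")
  if (!"16S" %in% names(median_lengths_kb)) stop("median length for 16S missing")
  ref_n <- cluster_counts$n_clusters[ref][1]
  ref_kb <- median_lengths_kb[["16S"]]
  if (ref_n == 0 || ref_kb == 0) stop("reference cell count/median must be positive")
  md <- median_lengths_kb[cluster_counts$region]
  if (any(is.na(md))) {
    stop("missing median length for region(s): ",
         paste(unique(cluster_counts$region[is.na(md)]), collapse = ", "))
  }
  out <- cluster_counts
  out$median_kb <- as.numeric(md)
  out$normalized_diversity <- (out$n_clusters / out$median_kb) / (ref_n / ref_kb)
  out
}

#' Diversity table over rrn sub-regions and cluster radii
#'
#' Convenience wrapper: splits each rrn record into its 16S, ITS and 23S
#' sub-sequences, clusters each region (and the full rrn) at radii 0-3, and
#' tabulates normalized diversity via [normalized_diversity()].
#'
#' @param records rrn record data frame from [extract_rrn_regions()].
#' @param radii Integer radii to evaluate (default 0:3).
#' @return Normalized diversity data frame, one row per (region, radius).
#' @export
rrn_diversity <- function(records, radii = 0:3) {
  subs <- list(
    rrn = records$seq,
    `16S` = substr(records$seq, 1, records$len_16s),
    ITS = substr(records$seq, records$len_16s + 1,
                 records$len_16s + records$len_its),
    `23S` = substr(records$seq, records$len_16s + records$len_its + 1,
                   nchar(records$seq)))
  subs$ITS <- subs$ITS[nzchar(subs$ITS)]
  rows <- list()
  med <- vapply(subs, function(s) median(nchar(s)) / 1000, numeric(1))
  for (region in names(subs)) {
    df <- data.frame(record_id = sprintf("%s_%d", region, seq_along(subs[[region]])),
                     seq = subs[[region]])
    for (r in radii) {
      cl <- greedy_cluster(df, radius_pct = r)
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, radius_pct = r, n_clusters = cl$n_clusters)
    }
  }
  counts <- do.call(rbind, rows)
  if (!3 %in% radii) {
    # reference cell always evaluated so the table is well-defined
    cl <- greedy_cluster(data.frame(record_id = seq_along(subs$`16S`),
                                    seq = subs$`16S`), radius_pct = 3)
    counts <- rbind(counts, data.frame(region = "16S", radius_pct = 3,
                                       n_clusters = cl$n_clusters))
  }
  normalized_diversity(counts, med)
}

#' Write / read the rrn reference database
#'
#' The database is serialized as a FASTA with structured headers
#' `record_id|species|assembly_id` plus a sidecar taxonomy/coordinate TSV, so
#' it stays greppable and diffable.
#'
#' @param records rrn record data frame.
#' @param prefix Path prefix; writes `<prefix>.fasta` and `<prefix>.tsv`.
#' @return The two paths, invisibly.
#' @export
write_rrn_db <- function(records, prefix) {
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".tsv")
  hdr <- paste(records$record_id, records$species, records$assembly_id, sep = "|")
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, fa)
  meta <- records[setdiff(names(records), "seq")]
  write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, tsv = tsv))
}

#' @rdname write_rrn_db
#' @export
read_rrn_db <- function(prefix) {
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".tsv")
  x <- Biostrings::readDNAStringSet(fa)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  meta <- read.delim(tsv, colClasses = NA)
  out <- data.frame(record_id = vapply(parts, `[`, character(1), 1),
                    seq = as.character(x), row.names = NULL)
  m <- merge(meta, out, by = "record_id", sort = FALSE)
  m[match(out$record_id, m$record_id), , drop = FALSE]
}

#' Build an rrn reference database from annotated genomes
#'
#' Chains extraction, two-sided length filtering and greedy clustering; the
#' returned database holds one centroid record per cluster.
#'
#' @inheritParams extract_rrn_regions
#' @inheritParams length_filter
#' @inheritParams greedy_cluster
#' @return List with `db` (centroid records), `clusters`, `bounds`, and
#'   `n_extracted`.
#' @export
build_rrn_db <- function(genomes, features, taxonomy = NULL,
                         max_its_len = 1500, low_pct = 0.5, high_pct = 99.5,
                         radius_pct = 0) {
  recs <- extract_rrn_regions(genomes, features, taxonomy, max_its_len)
  if (nrow(recs) == 0) stop("no rrn regions extracted")
  lf <- length_filter(recs, low_pct, high_pct)
  cl <- greedy_cluster(lf$records, radius_pct)
  db <- lf$records[match(cl$clusters$centroid_id, lf$records$record_id), ,
                   drop = FALSE]
  rownames(db) <- NULL
  list(db = db, clusters = cl, bounds = lf$bounds, n_extracted = nrow(recs))
}
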