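#' Build extended barcode probes
#'
#' The search probes for demultiplexing are the extended barcodes: the sample
#' barcode concatenated with the forward (`probe_F = barcode + fwd_primer`) or
#' reverse (`probe_R = barcode + rev_primer`) PCR primer. Searching the
#' extended barcode rather than the 38-nt barcode alone is what makes score
#' thresholds discriminative on error-prone long reads. Four search sequences
#' are produced per sample: both probes plus their reverse complements.
#'
#' @param specs Barcode spec data frame (see [read_barcode_specs()]).
#' @return Data frame with one row per sample: `sample_id`, `probe_F`,
#'   `probe_R`, `probe_F_rc`, `probe_R_rc`.
#' @export
build_probes <- function(specs) {
  need <- c("sample_id", "barcode", "fwd_primer", "rev_primer")
  if (!all(need %in% names(specs))) {
    stop("specs must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(specs$sample_id)) stop("duplicate sample_id")
  if (any(!nzchar(specs$fwd_primer)) || any(!nzchar(specs$rev_primer))) {
    stop("primers must be non-empty")
  }
  pf <- toupper(paste0(specs$barcode, specs$fwd_primer))
  pr <- toupper(paste0(specs$barcode, specs$rev_primer))
  data.frame(sample_id = specs$sample_id,
             probe_F = pf, probe_R = pr,
             probe_F_rc = revcomp(pf), probe_R_rc = revcomp(pr))
}

# Probe variant geometry for a dual-barcoded amplicon
# (amplicon = probe_F + insert + revcomp(probe_R)):
#   probe_F    at the 5' end  -> read is the + strand
#   probe_R_rc at the 3' end  -> read is the + strand
#   probe_R    at the 5' end  -> read is the - strand
#   probe_F_rc at the 3' end  -> read is the - strand
probe_variant_table <- function() {
  data.frame(
    variant = c("probe_F", "probe_R_rc", "probe_R", "probe_F_rc",
                "probe_F", "probe_R_rc", "probe_R", "probe_F_rc"),
    end = c("5p", "3p", "5p", "3p", "3p", "5p", "3p", "5p"),
    strand = c("+", "+", "-", "-", NA, NA, NA, NA),
    probe_kind = c("F", "R", "R", "F", "F", "R", "R", "F"))
}

#' Assign one read to a sample by extended-barcode alignment
#'
#' Each probe variant is locally aligned, IUPAC-aware (degenerate primer
#' positions score as matches against any compatible base), within a window at
#' each read end. The best-scoring sample wins if its score reaches the
#' stringency threshold. Two safety rules produce a `conflict` instead of an
#' assignment: two different samples above stringency with best evidence at
#' opposite read ends, or two samples tied at the same best score at the same
#' end.
#'
#' @param seq Read sequence (a single string).
#' @param probes Probe table from [build_probes()].
#' @param stringency Minimum alignment score for assignment (default 25; the
#'   permissive default of barcode splitters, 14, is too lax for extended
#'   probes on noisy reads).
#' @param window Bases scanned at each read end (default 150; truncated to the
#'   read length for short reads).
#' @param scoring A [scoring_scheme()].
#' @return One-row data frame: `assignment` (sample id, `"unassigned"` or
#'   `"conflict"`), `best_score`, `second_score`, `matched_end`
#'   (`"5p"`/`"3p"`), `strand`, `probe_kind` (`"F"`/`"R"`).
#' @export
assign_read <- function(seq, probes, stringency = 25, window = 150,
                        scoring = scoring_scheme()) {
  seq <- toupper(seq)
  len <- nchar(seq)
  w <- min(window, len)
  w5 <- substr(seq, 1, w)
  w3 <- substr(seq, len - w + 1, len)
  vt <- probe_variant_table()  # canonical geometry rows first: ties prefer them
  best <- data.frame(sample_id = probes$sample_id, score = -Inf,
                     end = NA_character_, strand = NA_character_,
                     probe_kind = NA_character_)
  for (si in seq_len(nrow(probes))) {
    for (vi in seq_len(nrow(vt))) {
      probe <- probes[[vt$variant[vi]]][si]
      win_seq <- if (vt$end[vi] == "5p") w5 else w3
      aln <- local_align(probe, win_seq, scoring, method = "full", iupac = TRUE)
      if (aln$score > best$score[si]) {
        best$score[si] <- aln$score
        best$end[si] <- vt$end[vi]
        best$strand[si] <- vt$strand[vi]
        best$probe_kind[si] <- vt$probe_kind[vi]
      }
    }
  }
  ord <- order(-best$score, best$sample_id)
  top <- best[ord[1], ]
  second <- if (nrow(best) > 1) best[ord[2], ] else
    data.frame(score = -Inf, end = NA_character_)
  res <- data.frame(assignment = "unassigned",
                    best_score = ifelse(is.finite(top$score), top$score, 0),
                    second_score = ifelse(is.finite(second$score), second$score, 0),
                    matched_end = top$end, strand = top$strand,
                    probe_kind = top$probe_kind)
  if (is.finite(top$score) && top$score >= stringency) {
    conflict <- is.finite(second$score) && second$score >= stringency &&
      (!identical(second$end, top$end) || second$score == top$score)
    res$assignment <- if (conflict) "conflict" else top$sample_id
  }
  res
}

#' Demultiplex a read set
#'
#' Runs [assign_read()] over all reads and bins them per sample. Bins are
#' disjoint: every read lands in exactly one of the sample bins, `unassigned`,
#' or `conflict`. The per-sample report splits assignments by probe
#' orientation (forward extended barcode vs reverse), mirroring the read
#' accounting used when pooling forward- and reverse-barcode matches.
#'
#' @param reads Data frame with columns `id`, `seq` (e.g. [read_seqs()]).
#' @param probes Probe table from [build_probes()].
#' @inheritParams assign_read
#' @return List: `assignments` (one row per read), `bins` (named list of read
#'   data frames, including `unassigned`/`conflict`), `report` (per-sample
#'   counts with forward/reverse probe split).
#' @export
demux_run <- function(reads, probes, stringency = 25, window = 150,
                      scoring = scoring_scheme()) {
  if (nrow(reads) == 0) {
    empty <- reads[0, , drop = FALSE]
    bins <- c(stats::setNames(rep(list(empty), nrow(probes)), probes$sample_id),
              list(unassigned = empty, conflict = empty))
    return(list(assignments = data.frame(), bins = bins,
                report = data.frame(sample_id = character(), n = integer(),
                                    n_forward = integer(), n_reverse = integer())))
  }
  res <- do.call(rbind, lapply(reads$seq, assign_read, probes = probes,
                               stringency = stringency, window = window,
                               scoring = scoring))
  res <- cbind(read_id = reads$id, res)
  groups <- c(probes$sample_id, "unassigned", "conflict")
  bins <- lapply(groups, function(g) reads[res$assignment == g, , drop = FALSE])
  names(bins) <- groups
  report <- do.call(rbind, lapply(probes$sample_id, function(s) {
    sel <- res$assignment == s
    data.frame(sample_id = s, n = sum(sel),
               n_forward = sum(sel & res$probe_kind == "F"),
               n_reverse = sum(sel & res$probe_kind == "R"))
  }))
  rrn_log("demux: ", sum(res$assignment %in% probes$sample_id), "/",
          nrow(reads), " reads assigned (",
          sum(res$assignment == "conflict"), " conflicts)")
  list(assignments = res, bins = bins, report = report)
}
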