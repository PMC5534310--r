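#' Alignment scoring scheme
#'
#' The defaults mirror the LAST-style parameterisation used throughout the
#' pipeline: match +1, mismatch -1, and a gap of length k costing
#' `gap_open + k * gap_extend` (so 1 + k by default).
#'
#' @param match Match reward (default 1).
#' @param mismatch Mismatch penalty, subtracted (default 1).
#' @param gap_open Cost of opening a gap (default 1).
#' @param gap_extend Cost per gap column (default 1).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1, mismatch = 1, gap_open = 1, gap_extend = 1) {
  vals <- c(match, mismatch, gap_open, gap_extend)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("scoring parameters must be non-negative")
  }
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Local alignment of two nucleotide sequences
#'
#' Smith-Waterman local alignment with affine gaps (Gotoh), either as full
#' dynamic programming (`method = "full"`) or as an exact-k-mer seeded, banded
#' variant (`method = "heuristic"`) for long sequences. The heuristic finds the
#' densest diagonal window of exact k-mer seeds and runs the same DP restricted
#' to a band around it; with no usable seed it reports an empty alignment.
#'
#' `N` scores as a mismatch against everything (including `N`). With
#' `iupac = TRUE` degenerate IUPAC codes score as matches against any
#' compatible base; this mode is meant for barcode/primer probes, not read
#' mapping.
#'
#' @param query,target Nucleotide strings (non-empty; case-insensitive).
#' @param scoring A [scoring_scheme()].
#' @param method `"full"` or `"heuristic"`.
#' @param k Seed length for the heuristic (default 11).
#' @param band Diagonal band width for the heuristic (default 151): seeds are
#'   clustered into a diagonal window at most `band` wide and the DP band pads
#'   that window by `band %/% 2` on each side.
#' @param iupac Treat IUPAC-compatible bases as matches (default `FALSE`).
#' @return A `local_alignment` list: `score`, `query_span` and `target_span`
#'   (0-based half-open), `n_match`, `n_mismatch`, `n_gap`, `n_gap_cols`.
#'   Score 0 with empty spans when no positive-scoring alignment exists.
#' @export
local_align <- function(query, target, scoring = scoring_scheme(),
                        method = c("full", "heuristic"), k = 11, band = 151,
                        iupac = FALSE) {
  method <- match.arg(method)
  if (!nzchar(query) || !nzchar(target)) stop("sequences must be non-empty")
  query <- toupper(query)
  target <- toupper(target)
  if (method == "full") {
    raw <- cpp_local_align(query, target, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend, iupac)
  } else {
    sb <- cpp_seed_band(query, target, as.integer(k), as.integer(band))
    if (sb[1] == 0) {
      raw <- list(score = 0L, qstart = 0L, qend = 0L, tstart = 0L, tend = 0L,
                  n_match = 0L, n_mismatch = 0L, n_gap = 0L, n_gap_cols = 0L)
    } else {
      pad <- band %/% 2
      raw <- cpp_banded_local_align(query, target, sb[2] - pad, sb[3] + pad,
                                    scoring$match, scoring$mismatch,
                                    scoring$gap_open, scoring$gap_extend, iupac)
    }
  }
  structure(list(score = raw$score,
                 query_span = c(raw$qstart, raw$qend),
                 target_span = c(raw$tstart, raw$tend),
                 n_match = raw$n_match, n_mismatch = raw$n_mismatch,
                 n_gap = raw$n_gap, n_gap_cols = raw$n_gap_cols),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local alignment: score %d, query [%d,%d), target [%d,%d)\n",
              x$score, x$query_span[1], x$query_span[2],
              x$target_span[1], x$target_span[2]))
  cat(sprintf("  %d match / %d mismatch / %d gap columns in %d gaps\n",
              x$n_match, x$n_mismatch, x$n_gap_cols, x$n_gap))
  invisible(x)
}

#' Edit-distance identity between two matched segments
#'
#' Identity is `1 - editdistance(a, b) / max(nchar(a), nchar(b))` by default.
#' The alternative `"ratio"` normalization,
#' `(nchar(a) + nchar(b) - editdistance) / (nchar(a) + nchar(b))`, is available
#' but the max-length denominator is the package default and what every
#' identity threshold in the pipeline refers to.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param mode `"max"` (default) or `"ratio"`.
#' @return Identity fraction in `[0, 1]`.
#' @export
segment_identity <- function(a, b, mode = c("max", "ratio")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("segments must be non-empty")
  a <- toupper(a)
  b <- toupper(b)
  d <- cpp_edit_distance(a, b)
  if (mode == "max") 1 - d / max(nchar(a), nchar(b))
  else (nchar(a) + nchar(b) - d) / (nchar(a) + nchar(b))
}

#' Nearest-rank percentile threshold
#'
#' The nearest-rank percentile of a sample: the `ceiling(n * pct / 100)`-th
#' smallest value (the minimum for `pct = 0`). No interpolation is performed,
#' so the threshold is always an observed value. The count of values that
#' would survive filtering at strictly greater than the threshold is reported
#' alongside.
#'
#' @param values Non-empty numeric vector.
#' @param pct Percentile in `[0, 100]`.
#' @return List with `threshold` and `n_above` (count of `values > threshold`).
#' @export
percentile_threshold <- function(values, pct) {
  if (length(values) == 0) stop("empty value list")
  if (pct < 0 || pct > 100) stop("pct must be in [0, 100]")
  srt <- sort(values)
  idx <- max(1L, ceiling(length(values) * pct / 100))
  thr <- srt[idx]
  list(threshold = thr, n_above = sum(values > thr))
}

#' Reverse complement of nucleotide strings
#'
#' IUPAC-aware, vectorised over a character vector.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}
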