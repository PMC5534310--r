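#' Read sequences from FASTA or FASTQ
#'
#' Loads a sequence file into a plain data frame, one row per record, with the
#' alphabet validated and lowercase normalized to uppercase. FASTQ per-base
#' qualities are retained (the profiling pipeline itself filters on length and
#' alignment identity only).
#'
#' @param path Path to a FASTA or FASTQ file (plain or gzip).
#' @param format `"auto"` (by extension, falling back to content sniffing),
#'   `"fasta"` or `"fastq"`.
#' @return A data frame with columns `id`, `desc`, `seq` and `qual`
#'   (`NA` for FASTA input). Record order is preserved.
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- sniff_seq_format(path)
  if (format == "fasta") {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(x))
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
    bad <- nchar(qual) != Biostrings::width(x)
    if (any(bad)) stop("quality string length mismatch at record ", which(bad)[1])
  }
  nm <- names(x)
  if (is.null(nm) || any(!nzchar(nm))) stop("record with empty id in ", path)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(Biostrings::width(x) < 1)) stop("zero-length sequence in ", path)
  data.frame(id = id, desc = desc, seq = as.character(x), qual = qual,
             row.names = NULL)
}

sniff_seq_format <- function(path) {
  ext <- tolower(sub("\\.gz$", "", basename(path)))
  if (grepl("\\.(fq|fastq)$", ext)) return("fastq")
  if (grepl("\\.(fa|fasta|fna|ffn)$", ext)) return("fasta")
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0) stop("empty file: ", path)
  if (startsWith(first, "@")) "fastq" else "fasta"
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs Data frame with columns `id`, `seq`, and optionally `desc` and
#'   `qual` (as returned by [read_seqs()]).
#' @param path Output path.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`. FASTQ output
#'   fills missing qualities with a constant placeholder.
#' @return `path`, invisibly.
#' @export
write_seqs <- function(seqs, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", tolower(path))) "fastq" else "fasta"
  }
  x <- Biostrings::DNAStringSet(seqs$seq)
  desc <- if ("desc" %in% names(seqs)) seqs$desc else character(nrow(seqs))
  desc <- rep_len(ifelse(is.na(desc), "", desc), nrow(seqs))
  names(x) <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  } else {
    qual <- if ("qual" %in% names(seqs)) seqs$qual else NA_character_
    qual <- ifelse(is.na(qual), strrep("I", nchar(seqs$seq)), qual)
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual))
  }
  invisible(path)
}

#' Read rRNA features from a GFF3 annotation
#'
#' Imports a GFF3 file and classifies features as 16S rRNA, 23S rRNA or other.
#' rRNA genes are recognized by feature type `rRNA` (any case) together with a
#' `product`, `Name` or `gene` attribute matching `16S` or `23S`
#' case-insensitively, since GFF dialects vary in where they put the molecule
#' name. Coordinates are returned 1-based inclusive exactly as in the file;
#' [extract_rrn_regions()] converts to the internal 0-based convention.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `contig`, `type` (one of `rRNA_16S`,
#'   `rRNA_23S`, `other`), `start`, `end`, `strand`, `attr` (the matched
#'   product/name text, `NA` for `other`).
#' @export
read_gff_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  get_attr <- function(col) {
    if (col %in% names(md)) {
      v <- md[[col]]
      if (methods::is(v, "List") || is.list(v)) {
        v <- vapply(v, function(e) if (length(e)) paste(e, collapse = ";") else NA_character_,
                    character(1))
      }
      as.character(v)
    } else rep(NA_character_, length(gr))
  }
  type_raw <- get_attr("type")
  label <- get_attr("product")
  for (alt in c("Name", "gene")) {
    miss <- is.na(label) | !grepl("16S|23S", label, ignore.case = TRUE)
    alt_v <- get_attr(alt)
    label[miss & !is.na(alt_v)] <- alt_v[miss & !is.na(alt_v)]
  }
  is_rrna <- !is.na(type_raw) & tolower(type_raw) == "rrna"
  type <- rep("other", length(gr))
  type[is_rrna & grepl("16S", label, ignore.case = TRUE)] <- "rRNA_16S"
  type[is_rrna & grepl("23S", label, ignore.case = TRUE)] <- "rRNA_23S"
  strand <- as.character(BiocGenerics::strand(gr))
  ribo <- type != "other"
  if (any(ribo & !strand %in% c("+", "-"))) {
    stop("rRNA feature without a +/- strand in ", path)
  }
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    type = type,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    attr = ifelse(type == "other", NA_character_, label),
    row.names = NULL)
  if (any(out$end < out$start)) stop("feature with end < start in ", path)
  out
}

# GFF3 1-based inclusive <-> internal 0-based half-open
gff_to_zero <- function(start, end) cbind(start = start - 1L, end = end)
zero_to_gff <- function(start, end) cbind(start = start + 1L, end = end)

#' Write profile and coverage-bias tables as TSV
#'
#' Emits a single deterministic table with fixed column order
#' (`taxon`, `count`, `proportion`, `predominant`, `bias`). Undetected taxa
#' (observed proportion zero) have their bias printed as `"ND"`.
#'
#' @param profile An abundance profile from [build_profile()].
#' @param bias Optional coverage-bias table from [coverage_bias()].
#' @param path Output TSV path.
#' @param decimals Printed precision for proportions (default 3).
#' @return `path`, invisibly.
#' @export
write_profile_tables <- function(profile, bias = NULL, path, decimals = 3) {
  tab <- profile$taxa
  if (nrow(tab) == 0) stop("empty profile")
  out <- data.frame(
    taxon = tab$taxon,
    count = tab$count,
    proportion = formatC(tab$proportion, digits = decimals, format = "f"),
    predominant = tab$predominant)
  if (!is.null(bias)) {
    i <- match(out$taxon, bias$taxon)
    b <- bias$bias[i]
    out$bias <- ifelse(is.na(b), "ND", formatC(b, digits = 2, format = "f"))
    missing_rows <- bias[!bias$taxon %in% out$taxon, , drop = FALSE]
    if (nrow(missing_rows) > 0) {
      extra <- data.frame(
        taxon = missing_rows$taxon, count = 0L,
        proportion = formatC(0, digits = decimals, format = "f"),
        predominant = FALSE,
        bias = ifelse(is.na(missing_rows$bias), "ND",
                      formatC(missing_rows$bias, digits = 2, format = "f")))
      out <- rbind(out, extra)
    }
  } else {
    out$bias <- "ND"
  }
  out <- out[order(-out$count, out$taxon), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode specification table
#'
#' Expects a TSV with columns `sample_id`, `barcode`, `fwd_primer`,
#' `rev_primer`. Sequences must be IUPAC nucleotide codes; sample ids must be
#' unique. The barcode/primer pairs used for the two mock communities ship with
#' the package: `system.file("extdata", "barcodes_minion.tsv", package =
#' "rrnprofile")`.
#'
#' @param path TSV path.
#' @return Data frame with the four columns, sequences uppercased.
#' @export
read_barcode_specs <- function(path) {
  sp <- read.delim(path, colClasses = "character")
  need <- c("sample_id", "barcode", "fwd_primer", "rev_primer")
  if (!all(need %in% names(sp))) {
    stop("barcode spec must have columns: ", paste(need, collapse = ", "))
  }
  sp <- sp[need]
  for (col in c("barcode", "fwd_primer", "rev_primer")) {
    sp[[col]] <- toupper(sp[[col]])
    bad <- grepl("[^ACGTURYSWKMBDHVN]", sp[[col]])
    if (any(bad)) stop("non-IUPAC characters in ", col, " for sample ",
                       sp$sample_id[bad][1])
  }
  if (any(!nzchar(sp$fwd_primer)) || any(!nzchar(sp$rev_primer))) {
    stop("primers must be non-empty")
  }
  if (anyDuplicated(sp$sample_id)) stop("duplicate sample_id in barcode spec")
  sp
}

#' Read a mock-community design table
#'
#' A design lists the taxa of a defined community and their expected relative
#' proportions (summing to 1). Designs for the HM782D (20 species, equimolar
#' rrn operon counts) and D6305 (8 species) mock communities ship under
#' `system.file("extdata", package = "rrnprofile")`.
#'
#' @param path TSV with columns `taxon` and `proportion`.
#' @param tol Tolerance on the proportion sum (default 1e-6).
#' @return Data frame with columns `taxon`, `proportion`.
#' @export
read_community_design <- function(path, tol = 1e-6) {
  d <- read.delim(path)
  if (!all(c("taxon", "proportion") %in% names(d))) {
    stop("design must have columns taxon, proportion")
  }
  d$proportion <- as.numeric(d$proportion)
  if (abs(sum(d$proportion) - 1) > tol) {
    stop("design proportions sum to ", sum(d$proportion), ", expected 1")
  }
  if (anyDuplicated(d$taxon)) stop("duplicate taxon in design")
  d[c("taxon", "proportion")]
}

#' Pipeline run configuration
#'
#' A flat key-value configuration covering every tunable stage threshold, with
#' unknown keys rejected and ranges checked. `run_config()` returns the
#' defaults, overridden by any named arguments; `read_run_config()` reads
#' overrides from a plain-text `key: value` (YAML subset) file.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of settings, class `rrn_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    # rrndb
    max_its_len = 1500, length_low_pct = 0.5, length_high_pct = 99.5,
    otu_radius_pct = 0,
    # demux
    stringency = 25, demux_window = 150,
    # profile
    min_read_len = 1500, max_read_len = 7000, identity_percentile = 50,
    min_abundance = 0.01, remove_singletons = TRUE,
    # align
    match = 1, mismatch = 1, gap_open = 1, gap_extend = 1,
    map_method = "heuristic", seed_k = 11, band = 151,
    identity_mode = "max",
    # simulate
    error_preset = "R9.4", strand_flip_prob = 0.5, trunc_prob = 0.2,
    trunc_min_frac = 0.3,
    seed = NA_integer_, verbosity = 1)
  ov <- list(...)
  cfg <- apply_config_overrides(cfg, ov)
  structure(cfg, class = "rrn_config")
}

apply_config_overrides <- function(cfg, ov) {
  if (length(ov) == 0) return(cfg)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (k in names(ov)) cfg[[k]] <- ov[[k]]
  stopifnot(
    cfg$otu_radius_pct >= 0, cfg$otu_radius_pct <= 3,
    cfg$length_low_pct >= 0, cfg$length_low_pct < cfg$length_high_pct,
    cfg$length_high_pct <= 100,
    cfg$stringency >= 1, cfg$min_read_len > 0,
    cfg$min_read_len < cfg$max_read_len,
    cfg$identity_percentile >= 0, cfg$identity_percentile <= 100,
    cfg$min_abundance >= 0, cfg$min_abundance < 1,
    cfg$identity_mode %in% c("max", "ratio"),
    cfg$map_method %in% c("heuristic", "full"))
  cfg
}

#' @rdname run_config
#' @param path Plain-text configuration file of `key: value` lines.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.+)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- lapply(kv, function(m) utils::type.convert(m[3], as.is = TRUE))
  names(vals) <- vapply(kv, `[`, character(1), 2)
  do.call(run_config, vals)
}

#' Log a pipeline message to standard error
#'
#' Every stage logs its input/output record counts at verbosity 1; per-record
#' detail appears at verbosity 2.
#'
#' @param ... Message parts, pasted together.
#' @param level Message level (1 = stage summary, 2 = detail).
#' @param verbosity Current verbosity (0 silences everything).
#' @export
rrn_log <- function(..., level = 1, verbosity = getOption("rrnprofile.verbosity", 1)) {
  if (verbosity >= level) message("[rrnprofile] ", ...)
  invisible(NULL)
}
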