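#' Read pre-processing configuration
#'
#' Settings for the footprint read clean-up pipeline: per-base accuracy
#' filtering, UMI-aware duplicate collapsing, 3' adapter trimming, dual UMI
#' removal and footprint size selection.
#'
#' @param min_base_accuracy_frac Minimum fraction of bases that must reach
#'   `min_base_phred` for a read to be kept (default 0.70). Reads where
#'   *less* than this fraction of bases is accurate are removed; a read at
#'   exactly the threshold is kept.
#' @param min_base_phred Phred score corresponding to the required per-base
#'   accuracy (default 20, i.e. 99% accuracy under Phred+33).
#' @param adapter 3' adapter sequence to trim. The default is a 21-nt
#'   TruSeq-style small-RNA adapter; supply the one used for your library.
#' @param umi_len_each_end Length of the unique molecular identifier at each
#'   read end (default 4 nt, giving an 8-nt combined UMI).
#' @param min_len,max_len Inclusive footprint length bounds applied after UMI
#'   removal (defaults 26 and 34 nt, the monosome-protected size range).
#' @param adapter_min_overlap Minimum suffix/prefix overlap for an adapter
#'   match (default 3).
#' @param adapter_max_error_rate Maximum mismatch rate in an adapter match
#'   (default 0.1).
#'
#' @return An object of class `prep_config`.
#' @export
#' @examples
#' cfg <- prep_config(adapter = "AGATCGGAAGAGCACACGTCT")
prep_config <- function(min_base_accuracy_frac = 0.70,
                        min_base_phred = 20L,
                        adapter = "AGATCGGAAGAGCACACGTCT",
                        umi_len_each_end = 4L,
                        min_len = 26L,
                        max_len = 34L,
                        adapter_min_overlap = 3L,
                        adapter_max_error_rate = 0.1) {
  if (min_base_accuracy_frac < 0 || min_base_accuracy_frac > 1)
    stopf("min_base_accuracy_frac must be in [0, 1]")
  if (min_len > max_len) stopf("min_len must not exceed max_len")
  if (umi_len_each_end < 0) stopf("umi_len_each_end must be >= 0")
  if (nchar(adapter) > 0 && nchar(adapter) < adapter_min_overlap)
    stopf("adapter (%d nt) is shorter than adapter_min_overlap (%d)",
          nchar(adapter), adapter_min_overlap)
  structure(list(min_base_accuracy_frac = min_base_accuracy_frac,
                 min_base_phred = as.integer(min_base_phred),
                 adapter = toupper(adapter),
                 umi_len_each_end = as.integer(umi_len_each_end),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 adapter_max_error_rate = adapter_max_error_rate),
            class = "prep_config")
}

#' Construct a set of sequencing reads
#'
#' Reads are held in a plain data frame with one row per read: identifier,
#' nucleotide sequence, Phred+33 quality string, a multiplicity counter
#' (number of collapsed originals) and the extracted UMI (empty until
#' [extract_umi()] runs).
#'
#' @param read_id Character vector of read identifiers.
#' @param sequence Character vector of sequences over `A,C,G,T,N`.
#' @param quality Character vector of Phred+33 quality strings, same
#'   lengths as `sequence`.
#' @param multiplicity Integer vector of collapsed-read counts (default 1).
#' @param umi Character vector of extracted UMIs (default empty).
#'
#' @return A `read_set` data frame.
#' @export
read_set <- function(read_id, sequence, quality,
                     multiplicity = 1L, umi = "") {
  sequence <- toupper(sequence)
  if (any(nchar(sequence) != nchar(quality)))
    stopf("sequence and quality lengths differ for some reads")
  if (any(multiplicity < 1)) stopf("multiplicity must be >= 1")
  df <- data.frame(read_id = as.character(read_id),
                   sequence = sequence,
                   quality = as.character(quality),
                   multiplicity = as.integer(multiplicity),
                   umi = as.character(umi),
                   stringsAsFactors = FALSE)
  class(df) <- c("read_set", "data.frame")
  df
}

phred_scores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

#' Filter reads by per-base accuracy
#'
#' Keeps reads where the fraction of bases at or above the Phred threshold
#' is at least `min_base_accuracy_frac`; a read exactly at the threshold is
#' retained. Order is preserved and the decision depends only on the read
#' itself.
#'
#' @param reads A [read_set()].
#' @param cfg A [prep_config()].
#' @return The filtered `read_set`.
#' @export
quality_filter <- function(reads, cfg = prep_config()) {
  if (nrow(reads) == 0) return(reads)
  len <- nchar(reads$sequence)
  if (any(len == 0)) {
    bad <- reads$read_id[len == 0]
    warning(sprintf("rejecting %d empty read(s): %s", length(bad),
                    paste(head(bad, 5), collapse = ", ")))
  }
  frac <- vapply(phred_scores(reads$quality), function(s) {
    if (length(s) == 0) return(-1)  # empty reads always rejected
    mean(s >= cfg$min_base_phred)
  }, numeric(1))
  reads[frac >= cfg$min_base_accuracy_frac, , drop = FALSE]
}

#' Collapse duplicate reads
#'
#' Groups reads by their full raw sequence (UMIs still embedded, so two
#' molecules with identical inserts but different UMIs stay distinct) and
#' keeps the first-seen read of each group, accumulating multiplicity.
#' Total multiplicity is conserved.
#'
#' @inheritParams quality_filter
#' @return The collapsed `read_set`.
#' @export
collapse_duplicates <- function(reads) {
  if (nrow(reads) == 0) return(reads)
  first <- !duplicated(reads$sequence)
  mult <- tapply(reads$multiplicity, factor(reads$sequence,
                                            levels = reads$sequence[first]),
                 sum)
  out <- reads[first, , drop = FALSE]
  out$multiplicity <- as.integer(mult[out$sequence])
  rownames(out) <- NULL
  out
}

# Leftmost start (1-based) of a 3' adapter occurrence in `seq`, or NA.
# Semi-global: the read suffix from the start must match an adapter prefix
# with mismatch rate <= max_err over the overlap; `N` matches nothing.
adapter_start <- function(seq, adapter, min_overlap, max_err) {
  n <- nchar(seq)
  la <- nchar(adapter)
  if (n == 0) return(NA_integer_)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  a <- strsplit(adapter, "", fixed = TRUE)[[1]]
  for (i in seq_len(n)) {
    k <- min(n - i + 1L, la)
    if (k < min_overlap) break
    sub <- s[i:(i + k - 1L)]
    mism <- sum(sub != a[seq_len(k)] | sub == "N")
    if (mism <= floor(max_err * k)) return(i)
  }
  NA_integer_
}

#' Trim the 3' adapter from reads
#'
#' Removes, per read, the leftmost suffix matching a prefix of the adapter
#' with mismatch rate at most `adapter_max_error_rate` and overlap at least
#' `adapter_min_overlap`. Qualities are trimmed in lockstep; reads without
#' a match are untouched.
#'
#' @inheritParams quality_filter
#' @return The trimmed `read_set`.
#' @export
trim_adapter <- function(reads, cfg = prep_config()) {
  if (nchar(cfg$adapter) == 0) stopf("adapter must be non-empty")
  if (nchar(cfg$adapter) < cfg$adapter_min_overlap)
    stopf("adapter shorter than adapter_min_overlap")
  if (nrow(reads) == 0) return(reads)
  pos <- vapply(reads$sequence, adapter_start, integer(1),
                adapter = cfg$adapter,
                min_overlap = cfg$adapter_min_overlap,
                max_err = cfg$adapter_max_error_rate,
                USE.NAMES = FALSE)
  hit <- !is.na(pos)
  keep_to <- ifelse(hit, pos - 1L, nchar(reads$sequence))
  reads$sequence <- substr(reads$sequence, 1L, keep_to)
  reads$quality <- substr(reads$quality, 1L, keep_to)
  reads
}

#' Extract the dual-end UMI
#'
#' Removes `umi_len_each_end` bases from each end of every read and stores
#' their concatenation (5' block first) in the `umi` field. Reads too short
#' to contain an interior are discarded; their count is available as
#' attribute `n_discarded`.
#'
#' @inheritParams quality_filter
#' @return The `read_set` with interior sequences and populated `umi`.
#' @export
extract_umi <- function(reads, cfg = prep_config()) {
  u <- cfg$umi_len_each_end
  if (u == 0 || nrow(reads) == 0) return(reads)
  if (any(done <- reads$umi != "")) {
    # UMIs already extracted for these reads; leave them untouched
    rest <- extract_umi(reads[!done, , drop = FALSE], cfg)
    out <- rbind(reads[done, , drop = FALSE], rest)
    attr(out, "n_discarded") <- attr(rest, "n_discarded")
    return(out)
  }
  len <- nchar(reads$sequence)
  ok <- len > 2L * u
  n_disc <- sum(!ok)
  if (n_disc > 0)
    message(sprintf("extract_umi: discarded %d read(s) with no interior",
                    n_disc))
  out <- reads[ok, , drop = FALSE]
  len <- len[ok]
  out$umi <- paste0(substr(out$sequence, 1L, u),
                    substr(out$sequence, len - u + 1L, len))
  out$sequence <- substr(out$sequence, u + 1L, len - u)
  out$quality <- substr(out$quality, u + 1L, len - u)
  rownames(out) <- NULL
  attr(out, "n_discarded") <- n_disc
  out
}

#' Select reads by footprint length
#'
#' Keeps reads whose (UMI-free) length lies in `[min_len, max_len]`
#' inclusive. In the original protocol this range corresponds to the
#' gel-extracted 26-34-nt monosome footprints; disable for RNA libraries by
#' widening the bounds.
#'
#' @inheritParams quality_filter
#' @return The filtered `read_set`.
#' @export
length_filter <- function(reads, cfg = prep_config()) {
  len <- nchar(reads$sequence)
  reads[len >= cfg$min_len & len <= cfg$max_len, , drop = FALSE]
}

#' Run the full read pre-processing pipeline
#'
#' Applies, in order: [quality_filter()], [collapse_duplicates()],
#' [trim_adapter()], [extract_umi()] and (optionally) [length_filter()].
#'
#' @inheritParams quality_filter
#' @param apply_length_filter Apply the footprint size selection (default
#'   `TRUE`, appropriate for RPF libraries; set `FALSE` for RNA).
#' @return A list with elements `reads` (the processed `read_set`) and
#'   `stats` (named read counts after each stage).
#' @export
run_prep <- function(reads, cfg = prep_config(), apply_length_filter = TRUE) {
  stats <- c(input = nrow(reads))
  reads <- quality_filter(reads, cfg)
  stats["quality_filter"] <- nrow(reads)
  reads <- collapse_duplicates(reads)
  stats["collapse_duplicates"] <- nrow(reads)
  reads <- trim_adapter(reads, cfg)
  stats["trim_adapter"] <- nrow(reads)
  reads <- extract_umi(reads, cfg)
  stats["extract_umi"] <- nrow(reads)
  if (apply_length_filter) {
    reads <- length_filter(reads, cfg)
    stats["length_filter"] <- nrow(reads)
  }
  list(reads = reads, stats = stats)
}

#' Read a FASTQ file into a read set
#'
#' @param path Path to a (optionally gzipped) FASTQ file, Phred+33.
#' @return A [read_set()].
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  read_set(read_id = names(x),
           sequence = as.character(x),
           quality = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a read set to a FASTQ file
#'
#' @param reads A [read_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}
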