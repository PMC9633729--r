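#' Construct a transcript-space read position table
#'
#' Holds footprint alignments as half-open transcript intervals
#' (`start` 0-based inclusive, `end` exclusive) with a read id, an integer
#' weight (collapsed-duplicate multiplicity) and a sample id, plus
#' per-sample library sizes (total mapped reads) used for per-million
#' normalization and optional per-transcript lengths.
#'
#' @param positions Data frame with columns `transcript_id`, `start`,
#'   `end`, `read_id`, `weight` (default 1 when absent), `sample_id`.
#' @param library_sizes Named numeric vector of total mapped reads per
#'   sample; defaults to the number of reads observed per sample.
#' @param transcript_lengths Optional named integer vector of transcript
#'   lengths (nt).
#' @return A `read_position_table` object.
#' @export
read_position_table <- function(positions, library_sizes = NULL,
                                transcript_lengths = NULL) {
  req <- c("transcript_id", "start", "end", "read_id", "sample_id")
  if (!all(req %in% names(positions)))
    stopf("positions needs columns: %s", paste(req, collapse = ", "))
  if (is.null(positions$weight)) positions$weight <- 1L
  if (any(positions$start < 0) || any(positions$end <= positions$start))
    stopf("require 0 <= start < end for every read")
  if (is.null(library_sizes)) {
    library_sizes <- tapply(rep(1L, nrow(positions)), positions$sample_id,
                            sum)
    library_sizes <- setNames(as.numeric(library_sizes),
                              names(library_sizes))
  }
  if (any(library_sizes <= 0)) stopf("library sizes must be positive")
  structure(list(positions = positions,
                 library_sizes = library_sizes,
                 transcript_lengths = transcript_lengths),
            class = "read_position_table")
}

#' Assign each footprint a single transcript position
#'
#' `five_prime` uses the 5' end (the interval start, matching plain
#' interval-intersection counting); `p_site` shifts the 5' end downstream
#' by a fixed offset, clipped to stay inside the read.
#'
#' @param start,end Integer vectors, 0-based half-open intervals.
#' @param offset_mode `"five_prime"` (default) or `"p_site"`.
#' @param p_site_offset Offset in nt for `p_site` mode (default 12).
#' @return Integer vector of 0-based assigned positions.
#' @export
assign_position <- function(start, end,
                            offset_mode = c("five_prime", "p_site"),
                            p_site_offset = 12L) {
  offset_mode <- match.arg(offset_mode)
  if (any(start >= end)) stopf("require start < end")
  if (offset_mode == "five_prime") as.integer(start)
  else as.integer(pmin(start + p_site_offset, end - 1L))
}

sample_rows <- function(tab, transcript_id, sample_id) {
  p <- tab$positions
  p[p$transcript_id == transcript_id & p$sample_id == sample_id, ,
    drop = FALSE]
}

transcript_len <- function(tab, transcript_id, length = NULL) {
  length %||% tab$transcript_lengths[[transcript_id]] %||%
    max(tab$positions$end[tab$positions$transcript_id == transcript_id], 0)
}

#' Per-nucleotide footprint coverage profile
#'
#' Reads-per-nucleotide-per-million profile over a transcript: each read
#' contributes its weight at its assigned position, scaled by the sample's
#' library size to reads per million.
#'
#' @param tab A [read_position_table()].
#' @param transcript_id Transcript to profile.
#' @param sample_id Sample to profile.
#' @param length Transcript length; taken from the table when omitted.
#' @param offset_mode,p_site_offset Passed to [assign_position()].
#' @return A `coverage_profile` list with `transcript_id`, `sample_id`,
#'   `length`, `values` (rpm per nucleotide, position 1 first) and
#'   `library_size`.
#' @export
coverage_profile <- function(tab, transcript_id, sample_id, length = NULL,
                             offset_mode = "five_prime",
                             p_site_offset = 12L) {
  L <- transcript_len(tab, transcript_id, length)
  lib <- tab$library_sizes[[sample_id]]
  if (is.null(lib) || lib <= 0) stopf("library size missing for sample %s",
                                      sample_id)
  rows <- sample_rows(tab, transcript_id, sample_id)
  if (nrow(rows) == 0)
    warning(sprintf("no reads for transcript %s in sample %s; zero profile",
                    transcript_id, sample_id))
  values <- numeric(L)
  if (nrow(rows) > 0) {
    pos <- assign_position(rows$start, rows$end, offset_mode,
                           p_site_offset) + 1L
    keep <- pos >= 1 & pos <= L
    agg <- tapply(rows$weight[keep], pos[keep], sum)
    values[as.integer(names(agg))] <- as.numeric(agg)
  }
  structure(list(transcript_id = transcript_id, sample_id = sample_id,
                 length = L, values = values / lib * 1e6,
                 library_size = lib, offset_mode = offset_mode),
            class = "coverage_profile")
}

#' Raw footprint count in a window around a focal nucleotide
#'
#' Number of distinct read ids whose assigned position falls in the
#' 1-based inclusive window `[center - halfwidth, center + halfwidth]`
#' (25 nt at the default halfwidth of 12). Windows reaching past the
#' transcript ends are truncated with a warning.
#'
#' @inheritParams coverage_profile
#' @param center_1based Focal nucleotide, 1-based.
#' @param halfwidth Window half-width in nt (default 12).
#' @return Integer count of distinct reads in the window.
#' @export
window_count <- function(tab, transcript_id, sample_id, center_1based,
                         halfwidth = 12L, length = NULL,
                         offset_mode = "five_prime", p_site_offset = 12L) {
  if (center_1based < 1) stopf("center must be >= 1")
  L <- transcript_len(tab, transcript_id, length)
  lo <- center_1based - halfwidth
  hi <- center_1based + halfwidth
  if (lo < 1 || (L > 0 && hi > L)) {
    warning("window truncated at transcript bounds")
    lo <- max(lo, 1)
    if (L > 0) hi <- min(hi, L)
  }
  rows <- sample_rows(tab, transcript_id, sample_id)
  if (nrow(rows) == 0) return(0L)
  pos <- assign_position(rows$start, rows$end, offset_mode,
                         p_site_offset) + 1L
  length(unique(rows$read_id[pos >= lo & pos <= hi]))
}

#' Two-sample Student's t test on library-normalized window counts
#'
#' Each raw window count is normalized to reads per million of its library
#' and the two conditions are compared with a pooled-variance two-sided
#' Student's t test (`df = nA + nB - 2`); Welch's unpooled variant is
#' available behind a flag. Degenerate inputs: zero variance in both
#' groups with equal means gives `t = 0, p = 1`; zero variance with
#' unequal means is reported with `p = 0` and `degenerate = TRUE`.
#'
#' @param counts_a,counts_b Raw window counts per replicate.
#' @param lib_a,lib_b Library sizes per replicate (recycled if scalar).
#' @param welch Use Welch's unequal-variance t test instead of the pooled
#'   Student form (default `FALSE`).
#' @return A `pause_test` list with `t`, `df`, `p`, `norm_a`, `norm_b`,
#'   `mean_a`, `mean_b`, `degenerate`.
#' @export
#' @examples
#' pause_test(c(10, 12), c(30, 28))  # |t| ~ 12.73, df 2, p ~ 0.0061
pause_test <- function(counts_a, counts_b, lib_a = 1e6, lib_b = 1e6,
                       welch = FALSE) {
  na <- length(counts_a); nb <- length(counts_b)
  if (na < 2 || nb < 2) stopf("need >= 2 replicates per condition")
  a <- counts_a / rep_len(lib_a, na) * 1e6
  b <- counts_b / rep_len(lib_b, nb) * 1e6
  va <- var(a); vb <- var(b)
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      t <- 0; df <- na + nb - 2; p <- 1
    } else {
      t <- sign(mean(b) - mean(a)) * Inf; df <- na + nb - 2; p <- 0
      degenerate <- TRUE
      warning("zero variance with unequal means; p below machine precision")
    }
  } else if (welch) {
    se2 <- va / na + vb / nb
    t <- (mean(b) - mean(a)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(-abs(t), df)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p = p, norm_a = a, norm_b = b,
                 mean_a = mean(a), mean_b = mean(b),
                 degenerate = degenerate),
            class = "pause_test")
}

#' Windowed pause test at a transcript position
#'
#' Convenience wrapper: computes raw window counts for each sample of the
#' two condition groups and runs [pause_test()].
#'
#' @inheritParams window_count
#' @param samples_a,samples_b Sample ids of the two condition groups.
#' @param ... Passed to [pause_test()].
#' @return A `pause_test` result with added fields `transcript_id`,
#'   `center`, `halfwidth`, `counts_a`, `counts_b`.
#' @export
pause_test_window <- function(tab, transcript_id, center_1based,
                              samples_a, samples_b, halfwidth = 12L,
                              length = NULL, offset_mode = "five_prime",
                              p_site_offset = 12L, ...) {
  wc <- function(s) window_count(tab, transcript_id, s, center_1based,
                                 halfwidth, length, offset_mode,
                                 p_site_offset)
  ca <- vapply(samples_a, wc, integer(1))
  cb <- vapply(samples_b, wc, integer(1))
  res <- pause_test(ca, cb,
                    lib_a = tab$library_sizes[samples_a],
                    lib_b = tab$library_sizes[samples_b], ...)
  res$transcript_id <- transcript_id
  res$center <- center_1based
  res$halfwidth <- halfwidth
  res$counts_a <- ca
  res$counts_b <- cb
  res
}

# Centered rolling window sum with zero padding (truncated at the ends).
window_sum <- function(x, halfwidth) {
  w <- 2L * halfwidth + 1L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - halfwidth, 1L)
  hi <- pmin(seq_len(n) + halfwidth, n)
  cs[hi + 1L] - cs[lo]
}

#' Scan a transcript for candidate ribosome-accumulation sites
#'
#' Computes the windowed, library-normalized coverage for every position,
#' averages replicates per condition, and reports positions where the
#' ratio (condition B over condition A, with a pseudocount) reaches
#' `min_ratio` and is a local maximum. Each candidate carries its
#' [pause_test()] result on the raw window counts.
#'
#' @inheritParams pause_test_window
#' @param min_ratio Minimum B/A windowed coverage ratio (default 2).
#' @param pseudocount Added to both windowed rpm means (default 0.1 rpm).
#' @return Data frame of candidates: `center`, `ratio`, `mean_a`,
#'   `mean_b` (windowed rpm), `t`, `df`, `p`; zero rows when nothing
#'   passes.
#' @export
scan_pauses <- function(tab, transcript_id, samples_a, samples_b,
                        min_ratio = 2.0, halfwidth = 12L, length = NULL,
                        pseudocount = 0.1, offset_mode = "five_prime",
                        p_site_offset = 12L) {
  L <- transcript_len(tab, transcript_id, length)
  prof <- function(s) coverage_profile(tab, transcript_id, s, L,
                                       offset_mode, p_site_offset)$values
  wa <- vapply(samples_a, function(s) window_sum(prof(s), halfwidth),
               numeric(L))
  wb <- vapply(samples_b, function(s) window_sum(prof(s), halfwidth),
               numeric(L))
  ma <- rowMeans(wa)
  mb <- rowMeans(wb)
  ratio <- (mb + pseudocount) / (ma + pseudocount)
  if (!is.finite(min_ratio)) return(empty_scan_result())
  above <- ratio >= min_ratio
  # local maximum: strictly above the left neighbour, at least the right
  left <- c(-Inf, ratio[-L])
  right <- c(ratio[-1], -Inf)
  cand <- which(above & ratio > left & ratio >= right)
  if (length(cand) == 0) return(empty_scan_result())
  rows <- lapply(cand, function(ct) {
    pt <- suppressWarnings(
      pause_test_window(tab, transcript_id, ct, samples_a, samples_b,
                        halfwidth, L, offset_mode, p_site_offset))
    data.frame(center = ct, ratio = ratio[ct],
               mean_a = ma[ct], mean_b = mb[ct],
               t = pt$t, df = pt$df, p = pt$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_scan_result <- function() {
  data.frame(center = integer(0), ratio = numeric(0), mean_a = numeric(0),
             mean_b = numeric(0), t = numeric(0), df = numeric(0),
             p = numeric(0))
}

#' Read a BED-like footprint position TSV
#'
#' Six columns, tab-separated, with header or not:
#' `transcript_id, start, end, read_id, weight, sample_id`.
#'
#' @param path TSV path.
#' @param library_sizes,transcript_lengths Passed to
#'   [read_position_table()].
#' @return A [read_position_table()].
#' @export
read_positions_bed <- function(path, library_sizes = NULL,
                               transcript_lengths = NULL) {
  cols <- c("transcript_id", "start", "end", "read_id", "weight",
            "sample_id")
  first <- readLines(path, n = 1)
  header <- grepl("transcript_id", first, fixed = TRUE)
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (!header) names(df) <- cols[seq_len(ncol(df))]
  read_position_table(df, library_sizes, transcript_lengths)
}
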