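#' Default gene-class table for count simulation
#'
#' Five planted classes define how each gene responds across the four
#' conditions, per assay layer (log2 fold changes are knock-out vs wild
#' type; the knock-out + knock-down condition attenuates the knock-out
#' effect by `rescue_frac`; `lfc_wtkd` applies to both knock-down
#' conditions):
#' \describe{
#'   \item{null}{no effect anywhere.}
#'   \item{rescued}{two-fold response on both layers, 60% rescued, no
#'     knock-down-only effect - the true screen targets.}
#'   \item{nonrescued_responder}{two-fold response that the knock-down
#'     does not revert.}
#'   \item{wtkd_only}{responds to the knock-down alone.}
#'   \item{rpf_only_shift}{footprint-only (translational) response at
#'     constant mRNA.}
#' }
#' The default mixture (92% null, 4% rescued, 4% non-rescued responders)
#' mirrors a screen where a few hundred genes out of ~5,000 respond.
#' Effect signs are drawn per gene (up or down, equiprobable).
#'
#' @param p_rescued,p_nonrescued,p_wtkd,p_rpf_only Class proportions; the
#'   null class takes the remainder.
#' @param lfc Planted absolute log2 fold change of responder classes
#'   (default 2).
#' @param rescue_frac True rescue fraction of the rescued class
#'   (default 0.6).
#' @return A data frame with one row per class.
#' @export
default_class_table <- function(p_rescued = 0.04, p_nonrescued = 0.04,
                                p_wtkd = 0, p_rpf_only = 0,
                                lfc = 2, rescue_frac = 0.6) {
  p_null <- 1 - p_rescued - p_nonrescued - p_wtkd - p_rpf_only
  if (p_null < 0) stopf("class proportions exceed 1")
  data.frame(
    class = c("null", "rescued", "nonrescued_responder", "wtkd_only",
              "rpf_only_shift"),
    proportion = c(p_null, p_rescued, p_nonrescued, p_wtkd, p_rpf_only),
    lfc_ko_rna = c(0, lfc, lfc, 0, 0),
    lfc_ko_rpf = c(0, lfc, lfc, 0, lfc),
    rescue_frac = c(0, rescue_frac, 0, 0, 0),
    lfc_wtkd_rna = c(0, 0, 0, lfc, 0),
    lfc_wtkd_rpf = c(0, 0, 0, lfc, 0),
    stringsAsFactors = FALSE)
}

#' Simulation specification
#'
#' Bundles every parameter of the seeded generators. Identical specs
#' (including the seed) produce identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes (default 5000).
#' @param replicates Replicates per (condition, assay) (default 2,
#'   biological duplicates).
#' @param library_size Reads per sample (default 5e6).
#' @param dispersion NB overdispersion alpha (default 0.05).
#' @param class_table See [default_class_table()].
#' @param base_mean_range Log-uniform range of baseline mean expression
#'   (default `c(20, 2000)`, on the per-million scale).
#' @param pause_spec List: `transcript_length` (1500 nt),
#'   `n_reads` (20000 per sample), `replicates` (2), `peak_centers` (442),
#'   `peak_fold` (3), `peak_halfwidth` (12), `conditions`
#'   (`c("WT","KO_KD")`), `peak_conditions` (`"KO_KD"`), `footprint_len`
#'   (`c(26, 34)`).
#' @param fastq_spec List: `n_reads` (2000), `insert_len` (`c(26, 34)`),
#'   `adapter` (21-nt), `umi_len` (4), `duplicate_rate` (0.2),
#'   `low_quality_rate` (0, fraction of reads with half their bases at
#'   Phred 10), `base_error_rate` (0, per-base substitution rate).
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(seed = 1L, n_genes = 5000L, replicates = 2L,
                     library_size = 5e6, dispersion = 0.05,
                     class_table = default_class_table(),
                     base_mean_range = c(20, 2000),
                     pause_spec = list(), fastq_spec = list()) {
  if (abs(sum(class_table$proportion) - 1) > 1e-9)
    stopf("class proportions must sum to 1")
  if (any(class_table$proportion < 0)) stopf("negative class proportion")
  pause_default <- list(transcript_length = 1500L, n_reads = 20000L,
                        replicates = 2L, peak_centers = 442L,
                        peak_fold = 3, peak_halfwidth = 12L,
                        conditions = c("WT", "KO_KD"),
                        peak_conditions = "KO_KD",
                        footprint_len = c(26L, 34L))
  fastq_default <- list(n_reads = 2000L, insert_len = c(26L, 34L),
                        adapter = "AGATCGGAAGAGCACACGTCT", umi_len = 4L,
                        duplicate_rate = 0.2, low_quality_rate = 0,
                        base_error_rate = 0)
  ps <- utils::modifyList(pause_default, pause_spec)
  fs <- utils::modifyList(fastq_default, fastq_spec)
  if (any(ps$peak_centers < 1 | ps$peak_centers > ps$transcript_length))
    stopf("peak centers must lie within the transcript")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 replicates = as.integer(replicates),
                 library_size = library_size, dispersion = dispersion,
                 class_table = class_table,
                 base_mean_range = base_mean_range,
                 pause_spec = ps, fastq_spec = fs),
            class = "sim_spec")
}

rnb <- function(n, mu, alpha) {
  if (alpha < 1e-12) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate four-condition two-assay count matrices
#'
#' Draws per-gene baseline means log-uniformly over `base_mean_range`,
#' applies the class-defined condition multipliers per layer (`WT`
#' baseline; `KO` scaled by `2^lfc_ko`; `KO_KD` by
#' `2^(lfc_ko * (1 - rescue_frac) + lfc_wtkd)`; `WT_KD` by `2^lfc_wtkd`),
#' scales to the library size and draws NB counts with the spec's
#' dispersion. Output is deterministic under the spec's seed.
#'
#' @param spec A [sim_spec()].
#' @return List with `rna` and `rpf` ([count_matrix()]), `sheet`
#'   ([sample_sheet()]) and `truth` (per-gene class, sign, true log2 fold
#'   changes per layer and condition, `is_true_target`).
#' @export
generate_counts <- function(spec = sim_spec()) {
  ct <- spec$class_table
  with_seed(spec$seed, {
    n <- spec$n_genes
    cls_idx <- sample(seq_len(nrow(ct)), n, replace = TRUE,
                      prob = ct$proportion)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    base <- exp(runif(n, log(spec$base_mean_range[1]),
                      log(spec$base_mean_range[2])))
    gene_id <- sprintf("gene_%05d", seq_len(n))

    truth <- data.frame(
      gene_id = gene_id, class = ct$class[cls_idx], sign = sgn,
      base_mean = base,
      lfc_ko_rna = sgn * ct$lfc_ko_rna[cls_idx],
      lfc_ko_rpf = sgn * ct$lfc_ko_rpf[cls_idx],
      rescue_frac = ct$rescue_frac[cls_idx],
      lfc_wtkd_rna = sgn * ct$lfc_wtkd_rna[cls_idx],
      lfc_wtkd_rpf = sgn * ct$lfc_wtkd_rpf[cls_idx],
      stringsAsFactors = FALSE)
    truth$lfc_kokd_rna <- truth$lfc_ko_rna * (1 - truth$rescue_frac) +
      truth$lfc_wtkd_rna
    truth$lfc_kokd_rpf <- truth$lfc_ko_rpf * (1 - truth$rescue_frac) +
      truth$lfc_wtkd_rpf
    truth$is_true_target <- truth$class == "rescued"

    conds <- c("WT", "KO", "WT_KD", "KO_KD")
    reps <- seq_len(spec$replicates)
    lib_scale <- spec$library_size / 1e6
    mats <- list()
    sheet_rows <- list()
    for (assay in c("RNA", "RPF")) {
      lkey <- tolower(assay)
      mult <- cbind(
        WT = rep(1, n),
        KO = 2^truth[[paste0("lfc_ko_", lkey)]],
        WT_KD = 2^truth[[paste0("lfc_wtkd_", lkey)]],
        KO_KD = 2^truth[[paste0("lfc_kokd_", lkey)]])
      cols <- list()
      for (cond in conds) for (r in reps) {
        sid <- paste(assay, cond, r, sep = "_")
        mu <- base * mult[, cond] * lib_scale
        cols[[sid]] <- rnb(n, mu, spec$dispersion)
        sheet_rows[[sid]] <- data.frame(sample_id = sid, condition = cond,
                                        assay = assay, replicate = r,
                                        stringsAsFactors = FALSE)
      }
      m <- do.call(cbind, cols)
      rownames(m) <- gene_id
      mats[[assay]] <- count_matrix(m, assay)
    }
    sh <- do.call(rbind, sheet_rows)
    list(rna = mats$RNA, rpf = mats$RPF,
         sheet = sample_sheet(sh$sample_id, sh$condition, sh$assay,
                              sh$replicate),
         truth = truth)
  })
}

#' Simulate footprint position tables with planted pause peaks
#'
#' Per sample, draws `n_reads` footprint 5' positions from a mixture of a
#' uniform background and, for peak-carrying conditions, a
#' `peak_fold`-times elevated intensity within `peak_halfwidth` of each
#' planted center. Footprint lengths are uniform over `footprint_len`.
#' Read ids are unique per sample; the per-sample total equals `n_reads`.
#'
#' @param spec A [sim_spec()]; see its `pause_spec` argument.
#' @param transcript_id Transcript name used in the table.
#' @return List with `table` (a [read_position_table()]), `samples` (named
#'   list of sample ids per condition) and `truth` (planted centers, fold,
#'   peak conditions).
#' @export
generate_positions <- function(spec = sim_spec(), transcript_id = "tx1") {
  ps <- spec$pause_spec
  with_seed(spec$seed + 1L, {
    L <- ps$transcript_length
    rows <- list()
    samples <- list()
    for (cond in ps$conditions) {
      w <- rep(1, L)
      if (cond %in% ps$peak_conditions)
        for (ctr in ps$peak_centers) {
          lo <- max(1, ctr - ps$peak_halfwidth)
          hi <- min(L, ctr + ps$peak_halfwidth)
          w[lo:hi] <- w[lo:hi] * ps$peak_fold
        }
      for (r in seq_len(ps$replicates)) {
        sid <- paste(cond, r, sep = "_")
        site <- sample.int(L, ps$n_reads, replace = TRUE, prob = w)
        len <- sample(seq(ps$footprint_len[1], ps$footprint_len[2]),
                      ps$n_reads, replace = TRUE)
        rows[[sid]] <- data.frame(
          transcript_id = transcript_id,
          start = site - 1L, end = site - 1L + len,
          read_id = sprintf("%s_read_%06d", sid, seq_len(ps$n_reads)),
          weight = 1L, sample_id = sid, stringsAsFactors = FALSE)
        samples[[cond]] <- c(samples[[cond]], sid)
      }
    }
    tab <- read_position_table(
      do.call(rbind, rows),
      transcript_lengths = setNames(L, transcript_id))
    list(table = tab, samples = samples,
         truth = list(peak_centers = ps$peak_centers,
                      peak_fold = ps$peak_fold,
                      peak_conditions = ps$peak_conditions,
                      transcript_length = L))
  })
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a footprint FASTQ library with UMIs, adapters and duplicates
#'
#' Each unique molecule is built as `UMI(4) + insert + UMI(4) + adapter`;
#' PCR duplicates (exact copies) are injected at `duplicate_rate`. A
#' `low_quality_rate` fraction of reads gets half its bases at Phred 10
#' (the rest are Phred 36); `base_error_rate` substitutes bases uniformly.
#' The truth table records each read's insert, UMIs, duplicate and
#' low-quality status.
#'
#' @param spec A [sim_spec()]; see its `fastq_spec` argument.
#' @return List with `reads` (a [read_set()]) and `truth` (data frame).
#' @export
generate_fastq <- function(spec = sim_spec()) {
  fs <- spec$fastq_spec
  if (nchar(fs$adapter) == 0) stopf("adapter must be non-empty")
  with_seed(spec$seed + 2L, {
    n <- fs$n_reads
    n_unique <- max(1L, round(n * (1 - fs$duplicate_rate)))
    ins_len <- sample(seq(fs$insert_len[1], fs$insert_len[2]), n_unique,
                      replace = TRUE)
    inserts <- vapply(ins_len, random_bases, character(1))
    umi5 <- vapply(rep(fs$umi_len, n_unique), random_bases, character(1))
    umi3 <- vapply(rep(fs$umi_len, n_unique), random_bases, character(1))
    src <- c(seq_len(n_unique),
             sample.int(n_unique, n - n_unique, replace = TRUE))
    is_dup <- duplicated(src)
    seqs <- paste0(umi5[src], inserts[src], umi3[src], fs$adapter)
    if (fs$base_error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        hit <- runif(length(ch)) < fs$base_error_rate
        ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    len <- nchar(seqs)
    is_lowq <- runif(n) < fs$low_quality_rate
    qual <- vapply(seq_len(n), function(i) {
      q <- rep(36L, len[i])
      if (is_lowq[i]) {
        bad <- sample.int(len[i], ceiling(len[i] / 2))
        q[bad] <- 10L
      }
      intToUtf8(q + 33L)
    }, character(1))
    reads <- read_set(read_id = sprintf("read_%06d", seq_len(n)),
                      sequence = seqs, quality = qual)
    truth <- data.frame(read_id = reads$read_id,
                        molecule = src,
                        insert = inserts[src],
                        umi5 = umi5[src], umi3 = umi3[src],
                        is_duplicate = is_dup,
                        is_low_quality = is_lowq,
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}
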