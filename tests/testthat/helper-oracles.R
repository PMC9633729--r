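# Independent brute-force oracles used across the suite. These are written
# as naive enumerations/loops, deliberately sharing no code with the
# package implementations they check.

# Step-up FDR adjustment via the reference algorithm in stats.
oracle_bh <- function(p) stats::p.adjust(p, method = "BH")

# Upper-tail hypergeometric P(X >= k) by enumerating all C(N, n) draws.
oracle_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  ref <- seq_len(K)  # first K elements are the reference set
  hits <- apply(draws, 2, function(d) sum(d %in% ref))
  mean(hits >= k)
}

# Overlapping IUPAC motif count via a per-window regex (lookahead trick).
oracle_motif_count <- function(sequence, motif) {
  classes <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG")
  pat <- strsplit(toupper(motif), "")[[1]]
  if (any(pat == "N")) return(0L)  # N matches nothing
  rx <- paste0("(?=", paste0("[", classes[pat], "]", collapse = ""), ")")
  s <- chartr("U", "T", toupper(sequence))
  m <- gregexpr(rx, s, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

# Duplicate collapsing by explicit hash-grouping.
oracle_collapse <- function(reads) {
  groups <- split(seq_len(nrow(reads)), reads$sequence)
  rows <- lapply(groups, function(idx) {
    r <- reads[min(idx), , drop = FALSE]
    r$multiplicity <- sum(reads$multiplicity[idx])
    r
  })
  out <- do.call(rbind, rows)
  out[order(vapply(groups, min, integer(1))), , drop = FALSE]
}

# Window count by looping over reads and testing interval membership.
oracle_window_count <- function(rows, center, halfwidth) {
  ids <- character(0)
  for (i in seq_len(nrow(rows))) {
    pos1 <- rows$start[i] + 1L  # five-prime assignment, 1-based
    if (pos1 >= center - halfwidth && pos1 <= center + halfwidth)
      ids <- c(ids, rows$read_id[i])
  }
  length(unique(ids))
}

# Random read set over ACGT with uniform qualities.
random_read_set <- function(n, len_range = c(20, 40), n_distinct = NULL) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  if (!is.null(n_distinct))  # force duplicates
    seqs <- sample(seqs[seq_len(n_distinct)], n, replace = TRUE)
  read_set(read_id = sprintf("r%04d", seq_len(n)), sequence = seqs,
           quality = strrep("I", nchar(seqs)))
}

# Naive per-gene re-evaluation of the three screen criteria.
oracle_select_targets <- function(calls, cfg) {
  vapply(seq_len(nrow(calls)), function(i) {
    row <- calls[i, ]
    sig <- isTRUE(row$padj_ko_rna < cfg$alpha) ||
      isTRUE(row$padj_ko_rpf < cfg$alpha)
    pass_layer <- function(lko, lkd, lwt) {
      c1 <- abs(lko) >= cfg$fold_threshold && sig
      if (!c1) return(FALSE)
      resc <- (lko - lkd) / lko
      c2 <- resc >= cfg$rescue_min
      c3 <- sign(lwt) != sign(lko) || abs(lwt) < cfg$null_lfc
      c2 && c3
    }
    pass_layer(row$lfc_ko_rna, row$lfc_ko_kd_rna, row$lfc_wt_kd_rna) ||
      pass_layer(row$lfc_ko_rpf, row$lfc_ko_kd_rpf, row$lfc_wt_kd_rpf)
  }, logical(1))
}

# Small deterministic count fixture: two conditions, given group means.
toy_count_matrix <- function(means_ref, means_test, n_rep = 3,
                             assay = "RNA") {
  n <- length(means_ref)
  m <- cbind(matrix(rep(means_ref, n_rep), n),
             matrix(rep(means_test, n_rep), n))
  rownames(m) <- sprintf("g%03d", seq_len(n))
  colnames(m) <- c(paste0(assay, "_WT_", seq_len(n_rep)),
                   paste0(assay, "_KO_", seq_len(n_rep)))
  count_matrix(m, assay)
}

toy_sheet <- function(n_rep = 3, assay = "RNA",
                      conds = c("WT", "KO")) {
  grid <- expand.grid(replicate = seq_len(n_rep), condition = conds,
                      stringsAsFactors = FALSE)
  sample_sheet(paste(assay, grid$condition, grid$replicate, sep = "_"),
               grid$condition, assay, grid$replicate)
}
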