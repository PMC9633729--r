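#' Construct a gene set
#'
#' @param name Set name.
#' @param members Character vector of gene ids (deduplicated, non-empty).
#' @param source Free-text provenance (file, database export, ...).
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, members, source = "") {
  members <- unique(as.character(members))
  if (length(members) == 0) stopf("gene set '%s' is empty", name)
  structure(list(name = name, members = members, source = source),
            class = "gene_set")
}

as_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else unique(as.character(x))
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then member ids.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: %s", substr(l, 1, 40))
    gene_set(f[1], f[-(1:2)], source = path)
  })
  setNames(sets, vapply(sets, function(s) s$name, character(1)))
}

#' Hypergeometric overlap between two gene sets
#'
#' Counts the overlap `k` between a query and a reference set inside a
#' fixed universe and reports the upper-tail hypergeometric p-value
#' `P(X >= k)` for `X ~ Hypergeometric(N = |universe|, K = |reference|,
#' n = |query|)`, plus the fraction of the query shared and the Jaccard
#' index. Members outside the universe are dropped with a message.
#'
#' @param query,reference Gene sets ([gene_set()] or character vectors).
#' @param universe The background gene universe.
#' @return A list with `k`, `n_query`, `n_set`, `n_universe`, `pct_query`,
#'   `p_hyper`, `jaccard`.
#' @export
#' @examples
#' overlap_test(letters[1:4], letters[1:5], letters[1:10])  # p = 5/210
overlap_test <- function(query, reference, universe) {
  uni <- as_members(universe)
  if (length(uni) == 0) stopf("universe is empty")
  q <- as_members(query)
  r <- as_members(reference)
  n_out <- sum(!(q %in% uni)) + sum(!(r %in% uni))
  if (n_out > 0)
    message(sprintf("overlap_test: dropping %d member(s) outside the universe",
                    n_out))
  q <- intersect(q, uni)
  r <- intersect(r, uni)
  k <- length(intersect(q, r))
  N <- length(uni); K <- length(r); n <- length(q)
  list(k = k, n_query = n, n_set = K, n_universe = N,
       pct_query = if (n > 0) k / n else NA_real_,
       p_hyper = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       jaccard = if (length(union(q, r)) > 0)
         k / length(union(q, r)) else NA_real_)
}

# IUPAC nucleotide code -> set of concrete bases (DNA alphabet; U == T).
# N matches nothing, on either side: an N in the sequence defeats every
# window containing it, and a pattern N can never be satisfied.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = character(0))

#' Count motif instances in a nucleotide sequence
#'
#' Slides an IUPAC pattern along the sequence and counts all (possibly
#' overlapping) start positions that match. `U` and `T` are equivalent on
#' both sides; an `N` in the sequence matches nothing (so any window
#' containing `N` fails).
#'
#' @param sequence Nucleotide string over `A,C,G,T,U,N` (case-insensitive).
#' @param motif IUPAC pattern string (e.g. `"TCCCW"` for the poly-C-class
#'   KH-domain binding element).
#' @return Integer instance count.
#' @export
#' @examples
#' motif_instances("TCCCTCCCT", "TCCCT")  # 2, overlap allowed
motif_instances <- function(sequence, motif) {
  motif <- toupper(motif)
  if (nchar(motif) == 0) stopf("motif pattern is empty")
  pat <- strsplit(motif, "", fixed = TRUE)[[1]]
  bad <- setdiff(pat, names(IUPAC_SETS))
  if (length(bad) > 0)
    stopf("invalid IUPAC code(s) in motif: %s", paste(bad, collapse = ", "))
  seqc <- strsplit(chartr("Uu", "Tt", toupper(sequence)), "",
                   fixed = TRUE)[[1]]
  L <- length(seqc); m <- length(pat)
  if (m > L) return(0L)
  ok <- matrix(FALSE, nrow = m, ncol = L)
  for (j in seq_len(m)) ok[j, ] <- seqc %in% IUPAC_SETS[[pat[j]]]
  hits <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m)) hits <- hits & ok[j, j:(L - m + j)]
  sum(hits)
}

# Exact two-sided Mann-Whitney permutation p-value (enumerates label
# assignments; ties handled by the 0.5 convention in U).
exact_rank_p <- function(x, y, max_comb = 20000L) {
  nx <- length(x); ny <- length(y)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  if (choose(nx + ny, nx) > max_comb) return(NULL)
  pool <- c(x, y)
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(i) u_stat(pool[i], pool[-i]))
  eps <- 1e-9
  p_hi <- mean(us >= u_obs - eps)
  p_lo <- mean(us <= u_obs + eps)
  min(1, 2 * min(p_hi, p_lo))
}

#' Motif-density enrichment between two sequence groups
#'
#' Computes, per sequence, the motif instance density (instances per
#' kilobase) and compares the query and background groups with a two-sided
#' rank-sum test. For small groups the p-value is the exact permutation
#' tail over all label assignments; larger groups fall back to the normal
#' approximation of [stats::wilcox.test()].
#'
#' @param query_seqs,background_seqs Named character vectors of sequences,
#'   or `Biostrings::DNAStringSet`/`RNAStringSet` objects.
#' @param motif IUPAC pattern string.
#' @return A list with `median_query`, `median_background`, `u`, `p`, and
#'   the per-sequence `density_query` / `density_background`.
#' @export
motif_enrichment <- function(query_seqs, background_seqs, motif) {
  to_chr <- function(x) {
    if (methods::is(x, "XStringSet")) x <- as.character(x)
    as.character(x)
  }
  q <- to_chr(query_seqs); b <- to_chr(background_seqs)
  if (length(q) == 0 || length(b) == 0)
    stopf("both sequence groups must be non-empty")
  density <- function(seqs) vapply(seqs, function(s)
    motif_instances(s, motif) / (nchar(s) / 1000), numeric(1))
  dq <- density(q); db <- density(b)
  u <- sum(outer(dq, db, ">")) + 0.5 * sum(outer(dq, db, "=="))
  if (all(c(dq, db) == 0)) {
    warning("all motif densities are zero; p set to 1")
    p <- 1
  } else if (!is.null(p_exact <- exact_rank_p(dq, db))) {
    p <- p_exact
  } else {
    p <- suppressWarnings(stats::wilcox.test(dq, db, exact = FALSE)$p.value)
  }
  list(median_query = median(dq), median_background = median(db),
       u = u, p = p, density_query = dq, density_background = db)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}
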