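#' Construct a sample sheet
#'
#' Sample metadata for the four-condition, two-assay rescue design. The
#' conditions are named explicitly: `WT` (wild type), `KO` (knock-out),
#' `WT_KD` (wild type + knock-down) and `KO_KD` (knock-out + knock-down);
#' assays are `RNA` (total RNA-seq) and `RPF` (ribosome-protected
#' fragments).
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param condition Character vector over `WT, KO, WT_KD, KO_KD`.
#' @param assay Character vector over `RNA, RPF`.
#' @param replicate Positive integer vector.
#' @return A `sample_sheet` data frame.
#' @export
sample_sheet <- function(sample_id, condition, assay, replicate) {
  conds <- c("WT", "KO", "WT_KD", "KO_KD")
  if (!all(condition %in% conds))
    stopf("condition must be one of %s", paste(conds, collapse = ", "))
  if (!all(assay %in% c("RNA", "RPF")))
    stopf("assay must be RNA or RPF")
  if (anyDuplicated(sample_id)) stopf("sample ids must be unique")
  key <- paste(condition, assay, replicate)
  if (anyDuplicated(key))
    stopf("(condition, assay, replicate) triples must be unique")
  df <- data.frame(sample_id = as.character(sample_id),
                   condition = condition, assay = assay,
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Construct a count matrix
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns (colnames are sample ids).
#' @param assay `"RNA"` or `"RPF"`.
#' @return A `count_matrix` object: a list with elements `counts`, `assay`
#'   and `size_factors` (`NULL` until estimated).
#' @export
count_matrix <- function(counts, assay = c("RNA", "RPF")) {
  assay <- match.arg(assay)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (is.null(rownames(counts))) stopf("counts needs gene ids as rownames")
  if (is.null(colnames(counts))) stopf("counts needs sample ids as colnames")
  structure(list(counts = counts, assay = assay, size_factors = NULL),
            class = "count_matrix")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with strictly
#' positive counts in every sample) of the ratio of the gene's count to its
#' geometric mean across samples; factors are rescaled to geometric mean 1.
#'
#' @param cm A [count_matrix()].
#' @return Named numeric vector of per-sample size factors.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("A", "B")))
#' size_factors(count_matrix(m, "RNA"))  # ratio B/A = 2
size_factors <- function(cm) {
  x <- cm$counts
  pos <- rowSums(x > 0) == ncol(x)
  if (!any(pos))
    stopf(paste("no gene has positive counts in every sample;",
                "use total-count normalization instead"))
  lx <- log(x[pos, , drop = FALSE])
  lg <- rowMeans(lx)
  sf <- exp(apply(lx - lg, 2, median))
  sf <- sf / geometric_mean(sf)
  setNames(sf, colnames(x))
}

#' Attach size factors to a count matrix
#'
#' @param cm A [count_matrix()].
#' @param sf Optional numeric vector; computed by [size_factors()] when
#'   omitted.
#' @return The `count_matrix` with `size_factors` set (geometric mean 1).
#' @export
estimate_size_factors <- function(cm, sf = NULL) {
  sf <- sf %||% size_factors(cm)
  if (any(sf <= 0)) stopf("size factors must be positive")
  cm$size_factors <- sf / geometric_mean(sf)
  cm
}

normalized_counts <- function(cm) {
  if (is.null(cm$size_factors)) cm <- estimate_size_factors(cm)
  sweep(cm$counts, 2, cm$size_factors, "/")
}

# Columns of cm belonging to each (condition) group of its assay.
assay_groups <- function(cm, sheet) {
  sheet <- sheet[sheet$assay == cm$assay &
                   sheet$sample_id %in% colnames(cm$counts), , drop = FALSE]
  split(sheet$sample_id, sheet$condition, drop = TRUE)
}

#' Estimate negative-binomial dispersion
#'
#' Per-gene method-of-moments estimate of the NB overdispersion `alpha`
#' (`Var = mu + alpha * mu^2`), computed on normalized counts within each
#' condition's replicate group and combined as a group-size-weighted mean,
#' with `max(0, .)` truncation and a floor of `1e-8`. With few replicates
#' the per-gene estimate is noisy, so the default `pooled` method replaces
#' it by the mean estimate of genes with similar expression (10 bins of
#' log mean normalized count), a trended common dispersion in the spirit of
#' the standard count-model packages.
#'
#' @param cm A [count_matrix()] (size factors estimated on demand).
#' @param sheet A [sample_sheet()] with at least two replicates in some
#'   condition of `cm`'s assay.
#' @param method `"pooled"` (trended common dispersion, default) or
#'   `"moments"` (raw per-gene estimate).
#' @param n_bins Number of expression bins for the pooled trend.
#' @return A data frame with columns `gene_id` and `dispersion`, carrying
#'   attribute `method`.
#' @export
estimate_dispersion <- function(cm, sheet, method = c("pooled", "moments"),
                                n_bins = 10L) {
  method <- match.arg(method)
  nc <- normalized_counts(cm)
  groups <- assay_groups(cm, sheet)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) == 0)
    stopf("every condition group has a single replicate; cannot estimate dispersion")
  est <- matrix(0, nrow(nc), length(groups))
  w <- vapply(groups, length, integer(1))
  for (j in seq_along(groups)) {
    x <- nc[, groups[[j]], drop = FALSE]
    m <- rowMeans(x)
    v <- row_vars(x)
    a <- ifelse(m > 0, (v - m) / m^2, 0)
    est[, j] <- pmax(0, a)
  }
  disp <- as.vector(est %*% w) / sum(w)
  if (method == "pooled" && nrow(nc) > 1) {
    bm <- rowMeans(nc)
    bins <- cut(rank(bm, ties.method = "first"),
                breaks = min(n_bins, nrow(nc)), labels = FALSE)
    disp <- ave(disp, bins, FUN = mean)
  }
  out <- data.frame(gene_id = rownames(nc),
                    dispersion = pmax(disp, 1e-8),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: sort the p-values ascending, take
#' `q_(i) = min_(j >= i) p_(j) * m / j` capped at 1, and return the adjusted
#' values in the original input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same order as input.
#' @export
#' @examples
#' bh_adjust(c(0.005, 0.01, 0.03, 0.04))  # 0.02 0.02 0.04 0.04
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must be finite and in [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Negative-binomial Wald test between two conditions
#'
#' Simplified count-based differential test for one assay layer: normalized
#' group means with a pseudocount, delta-method standard error on the log2
#' fold change using the NB dispersion, a standard-normal Wald p-value and
#' Benjamini-Hochberg correction. Genes with zero counts in every sample
#' are dropped before testing (count reported as attribute `n_dropped`).
#'
#' The log2 fold change is `log2((m_test + c) / (m_ref + c))` with
#' pseudocount `c`; its squared standard error is
#' `(1/ln 2)^2 * sum_groups(1 / (n (m + c)) + alpha / n)`.
#' A gene is called `up` when `padj < alpha` and `lfc >= lfc_threshold`,
#' `down` symmetrically, otherwise `ns`.
#'
#' @param cm A [count_matrix()].
#' @param sheet A [sample_sheet()].
#' @param ref_cond,test_cond Condition labels to contrast (test vs reference).
#' @param alpha Adjusted-p significance cutoff for the direction call
#'   (default 0.05).
#' @param lfc_threshold Absolute log2-fold-change threshold for the
#'   direction call (default 1, i.e. two-fold; boundary included).
#' @param pseudocount Half-count offset keeping fold changes finite at zero
#'   (default 0.5).
#' @param dispersion Optional precomputed [estimate_dispersion()] result.
#' @param dispersion_method Passed to [estimate_dispersion()] when
#'   `dispersion` is not supplied.
#' @return A `de_table` data frame with columns `gene_id`, `base_mean`,
#'   `lfc`, `se`, `wald`, `p`, `padj`, `direction`, and attribute
#'   `contrast = c(ref, test, assay)`.
#' @export
wald_test <- function(cm, sheet, ref_cond, test_cond,
                      alpha = 0.05, lfc_threshold = 1.0,
                      pseudocount = 0.5, dispersion = NULL,
                      dispersion_method = "pooled") {
  groups <- assay_groups(cm, sheet)
  for (cond in c(ref_cond, test_cond))
    if (is.null(groups[[cond]]) || length(groups[[cond]]) == 0)
      stopf("condition '%s' has no %s samples in the sheet", cond, cm$assay)
  if (is.null(cm$size_factors)) cm <- estimate_size_factors(cm)
  nonzero <- rowSums(cm$counts) > 0
  n_dropped <- sum(!nonzero)
  if (n_dropped > 0) {
    message(sprintf("wald_test: dropping %d all-zero gene(s)", n_dropped))
    cm$counts <- cm$counts[nonzero, , drop = FALSE]
  }
  nc <- normalized_counts(cm)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(cm, sheet, method = dispersion_method)
  disp <- dispersion$dispersion[match(rownames(nc), dispersion$gene_id)]
  if (any(is.na(disp))) stopf("dispersion missing for some genes")

  ref_cols <- groups[[ref_cond]]
  test_cols <- groups[[test_cond]]
  n_ref <- length(ref_cols)
  n_test <- length(test_cols)
  m_ref <- rowMeans(nc[, ref_cols, drop = FALSE])
  m_test <- rowMeans(nc[, test_cols, drop = FALSE])
  cc <- pseudocount

  lfc <- log2((m_test + cc) / (m_ref + cc))
  se2 <- (1 / log(2))^2 * (1 / (n_ref * (m_ref + cc)) + disp / n_ref +
                             1 / (n_test * (m_test + cc)) + disp / n_test)
  se <- sqrt(se2)
  wald <- lfc / se
  p <- 2 * pnorm(-abs(wald))
  padj <- bh_adjust(p)
  direction <- ifelse(padj < alpha & lfc >= lfc_threshold, "up",
                      ifelse(padj < alpha & lfc <= -lfc_threshold, "down",
                             "ns"))
  out <- data.frame(gene_id = rownames(nc),
                    base_mean = rowMeans(nc),
                    lfc = lfc, se = se, wald = wald, p = p, padj = padj,
                    direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- c(ref = ref_cond, test = test_cond,
                             assay = cm$assay)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("de_table", "data.frame")
  out
}

#' Read a gene-by-sample count TSV
#'
#' First column is the gene id, remaining columns are samples.
#'
#' @param path TSV path.
#' @param assay `"RNA"` or `"RPF"`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, assay = c("RNA", "RPF")) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_matrix(m, match.arg(assay))
}

#' Write a differential-expression table to TSV
#'
#' @param de A `de_table` from [wald_test()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
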