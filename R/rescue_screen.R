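#' Rescue-screen configuration
#'
#' Thresholds for the three-criterion selection of knock-down-rescued
#' targets: (I) at least two-fold up- or down-regulation in the knock-out
#' with adjusted significance, (II) at least 25% rescue of that change when
#' the RBP is co-depleted in the knock-out, and (III) an opposite-direction
#' or null response to the knock-down alone.
#'
#' @param fold_threshold Criterion-I absolute log2-fold-change threshold
#'   (default 1, i.e. two-fold; boundary included).
#' @param alpha Criterion-I adjusted-p cutoff (default 0.05).
#' @param rescue_min Criterion-II minimum rescue fraction (default 0.25).
#' @param null_lfc Criterion-III "no effect" bound on the knock-down-only
#'   log2 fold change (default `log2(1.5)`, the midpoint class between a
#'   null and a two-fold response).
#' @param rescue_scale `"log2"` (default) computes the rescue fraction on
#'   log2 fold changes; `"linear"` on linear fold changes.
#' @return A `screen_config` object.
#' @export
screen_config <- function(fold_threshold = 1.0, alpha = 0.05,
                          rescue_min = 0.25, null_lfc = log2(1.5),
                          rescue_scale = c("log2", "linear")) {
  if (fold_threshold <= 0) stopf("fold_threshold must be positive")
  if (rescue_min <= 0 || rescue_min > 1)
    stopf("rescue_min must be in (0, 1]")
  structure(list(fold_threshold = fold_threshold, alpha = alpha,
                 rescue_min = rescue_min, null_lfc = null_lfc,
                 rescue_scale = match.arg(rescue_scale)),
            class = "screen_config")
}

#' Fraction of a knock-out effect reverted by the knock-down
#'
#' On the log2 scale the rescue fraction is
#' `(lfc_ko - lfc_ko_kd) / lfc_ko`, both fold changes taken against the
#' wild-type reference. A value of 1 means full reversion; values above 1
#' (over-rescue) and below 0 (aggravation) are possible.
#'
#' @param lfc_ko Log2 fold change knock-out vs wild type; must be nonzero.
#' @param lfc_ko_kd Log2 fold change knock-out + knock-down vs wild type.
#' @param scale `"log2"` or `"linear"`; the linear variant maps fold
#'   changes to `2^lfc` and measures reversion of the distance to 1.
#' @return Numeric vector of rescue fractions.
#' @export
#' @examples
#' rescue_fraction(2.0, 1.4)   # 0.30
#' rescue_fraction(2.0, -0.5)  # 1.25, over-rescue
rescue_fraction <- function(lfc_ko, lfc_ko_kd, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (any(lfc_ko == 0))
    stopf("rescue fraction undefined for lfc_ko == 0")
  if (scale == "log2") {
    (lfc_ko - lfc_ko_kd) / lfc_ko
  } else {
    (2^lfc_ko - 2^lfc_ko_kd) / (2^lfc_ko - 1)
  }
}

# Per-layer criteria evaluation on aligned vectors; returns a data.frame.
layer_criteria <- function(lfc_ko, padj_ko, lfc_ko_kd, lfc_wt_kd,
                           sig_either, cfg) {
  crit_i <- abs(lfc_ko) >= cfg$fold_threshold & sig_either
  rescue <- rep(NA_real_, length(lfc_ko))
  idx <- crit_i & lfc_ko != 0
  rescue[idx] <- rescue_fraction(lfc_ko[idx], lfc_ko_kd[idx],
                                 cfg$rescue_scale)
  crit_ii <- !is.na(rescue) & rescue >= cfg$rescue_min
  crit_iii <- sign(lfc_wt_kd) != sign(lfc_ko) |
    abs(lfc_wt_kd) < cfg$null_lfc
  data.frame(lfc_ko = lfc_ko, padj_ko = padj_ko,
             lfc_ko_kd = lfc_ko_kd, lfc_wt_kd = lfc_wt_kd,
             rescue_frac = rescue,
             crit_i = crit_i, crit_ii = crit_ii, crit_iii = crit_iii,
             pass = crit_i & crit_ii & crit_iii)
}

#' Select rescue-screen targets from the six wild-type-referenced contrasts
#'
#' Applies the three criteria per gene and per assay layer. Criterion I
#' requires the tested layer to change at least `fold_threshold` (log2) in
#' the knock-out while adjusted significance may come from either layer
#' (RNA or RPF). Criteria II (rescue fraction) and III (opposite or null
#' knock-down-only response) are evaluated on the same layer, using point
#' fold-change estimates without further p-value gating. A gene is a
#' target when any single layer passes all three.
#'
#' @param de_ko_rna,de_ko_rpf `de_table`s for knock-out vs wild type.
#' @param de_kokd_rna,de_kokd_rpf `de_table`s for knock-out + knock-down vs
#'   wild type.
#' @param de_wtkd_rna,de_wtkd_rpf `de_table`s for knock-down alone vs wild
#'   type.
#' @param cfg A [screen_config()].
#' @return A `rescue_calls` data frame, one row per gene in the shared
#'   universe, with per-layer columns (`*_rna`, `*_rpf`) for the fold
#'   changes, adjusted p, rescue fraction and criteria, plus `is_target`
#'   and `qualifying_layers`.
#' @export
select_targets <- function(de_ko_rna, de_ko_rpf, de_kokd_rna, de_kokd_rpf,
                           de_wtkd_rna, de_wtkd_rpf,
                           cfg = screen_config()) {
  tables <- list(de_ko_rna, de_ko_rpf, de_kokd_rna, de_kokd_rpf,
                 de_wtkd_rna, de_wtkd_rpf)
  if (any(vapply(tables, is.null, logical(1))))
    stopf("all six contrast tables are required")
  genes <- Reduce(intersect, lapply(tables, function(t) t$gene_id))
  n_union <- length(Reduce(union, lapply(tables, function(t) t$gene_id)))
  if (n_union > length(genes))
    message(sprintf("select_targets: restricting to %d shared gene(s), dropping %d",
                    length(genes), n_union - length(genes)))
  pick <- function(tab, col) tab[[col]][match(genes, tab$gene_id)]

  sig_either <- pick(de_ko_rna, "padj") < cfg$alpha |
    pick(de_ko_rpf, "padj") < cfg$alpha
  rna <- layer_criteria(pick(de_ko_rna, "lfc"), pick(de_ko_rna, "padj"),
                        pick(de_kokd_rna, "lfc"), pick(de_wtkd_rna, "lfc"),
                        sig_either, cfg)
  rpf <- layer_criteria(pick(de_ko_rpf, "lfc"), pick(de_ko_rpf, "padj"),
                        pick(de_kokd_rpf, "lfc"), pick(de_wtkd_rpf, "lfc"),
                        sig_either, cfg)
  qualifying <- ifelse(rna$pass & rpf$pass, "RNA,RPF",
                       ifelse(rna$pass, "RNA",
                              ifelse(rpf$pass, "RPF", "")))
  names(rna) <- paste0(names(rna), "_rna")
  names(rpf) <- paste0(names(rpf), "_rpf")
  out <- cbind(data.frame(gene_id = genes, stringsAsFactors = FALSE),
               rna, rpf,
               data.frame(is_target = qualifying != "",
                          qualifying_layers = qualifying,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("rescue_calls", "data.frame")
  out
}

#' Criteria funnel summary for a rescue screen
#'
#' @param calls A `rescue_calls` data frame from [select_targets()].
#' @return Named integer vector: genes passing criterion I on any layer,
#'   then I+II, then I+II+III (= targets).
#' @export
screen_summary <- function(calls) {
  c(crit_I = sum(calls$crit_i_rna | calls$crit_i_rpf),
    crit_I_II = sum((calls$crit_i_rna & calls$crit_ii_rna) |
                      (calls$crit_i_rpf & calls$crit_ii_rpf)),
    targets = sum(calls$is_target))
}
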