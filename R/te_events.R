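#' Apparent translation efficiency per gene
#'
#' TE is the ratio of ribosome-footprint abundance to mRNA abundance:
#' `(mean normalized RPF + c) / (mean normalized RNA + c)` within one
#' condition, each assay normalized by its own size factors. Genes present
#' in only one matrix are excluded with a message.
#'
#' @param rna_cm,rpf_cm [count_matrix()] objects for the RNA and RPF layers.
#' @param sheet A [sample_sheet()].
#' @param condition Condition label whose replicate means are used.
#' @param pseudocount Half-count offset (default 0.5).
#' @return Named numeric vector of TE values over the shared gene universe.
#' @export
translation_efficiency <- function(rna_cm, rpf_cm, sheet, condition,
                                   pseudocount = 0.5) {
  if (rna_cm$assay != "RNA" || rpf_cm$assay != "RPF")
    stopf("expected an RNA and an RPF count matrix, in that order")
  shared <- intersect(rownames(rna_cm$counts), rownames(rpf_cm$counts))
  n_only <- length(union(rownames(rna_cm$counts), rownames(rpf_cm$counts))) -
    length(shared)
  if (n_only > 0)
    message(sprintf("translation_efficiency: excluding %d gene(s) present in one assay only",
                    n_only))
  cond_mean <- function(cm) {
    cols <- assay_groups(cm, sheet)[[condition]]
    if (is.null(cols)) stopf("condition '%s' absent for assay %s",
                             condition, cm$assay)
    rowMeans(normalized_counts(cm)[shared, cols, drop = FALSE])
  }
  (cond_mean(rpf_cm) + pseudocount) / (cond_mean(rna_cm) + pseudocount)
}

#' Classify per-gene regulation events from paired RNA/RPF tests
#'
#' Combines the direction calls of the RNA-layer and RPF-layer tests for
#' one contrast into a five-class partition:
#' \describe{
#'   \item{concordant}{both layers called, same direction (buffered
#'     transcriptional change).}
#'   \item{rna_only}{mRNA level changes without a footprint change.}
#'   \item{rpf_only}{footprints change at constant mRNA - the
#'     translationally regulated class.}
#'   \item{discordant}{both layers called, opposite directions.}
#'   \item{none}{neither layer called, or the gene is missing from one
#'     table.}
#' }
#'
#' @param rna_de,rpf_de `de_table` objects from [wald_test()] on the same
#'   contrast.
#' @return Data frame with `gene_id`, `rna_direction`, `rpf_direction`,
#'   `event_class` over the union of gene universes.
#' @export
classify_events <- function(rna_de, rpf_de) {
  genes <- union(rna_de$gene_id, rpf_de$gene_id)
  missing <- sum(!(genes %in% rna_de$gene_id)) +
    sum(!(genes %in% rpf_de$gene_id))
  if (missing > 0)
    message(sprintf("classify_events: %d gene(s) missing from one table -> class 'none'",
                    missing))
  rna <- rna_de$direction[match(genes, rna_de$gene_id)]
  rpf <- rpf_de$direction[match(genes, rpf_de$gene_id)]
  cls <- rep("none", length(genes))
  known <- !is.na(rna) & !is.na(rpf)
  rna_hit <- known & rna != "ns"
  rpf_hit <- known & rpf != "ns"
  cls[rna_hit & rpf_hit & rna == rpf] <- "concordant"
  cls[rna_hit & rpf_hit & rna != rpf] <- "discordant"
  cls[rna_hit & !rpf_hit] <- "rna_only"
  cls[!rna_hit & rpf_hit] <- "rpf_only"
  data.frame(gene_id = genes,
             rna_direction = ifelse(is.na(rna), "ns", rna),
             rpf_direction = ifelse(is.na(rpf), "ns", rpf),
             event_class = cls,
             stringsAsFactors = FALSE)
}

#' Count events per class
#'
#' @param classes Output of [classify_events()] (or a character vector of
#'   classes).
#' @return Named integer vector over all five classes; counts sum to the
#'   number of classified genes.
#' @export
event_summary <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$event_class
  lv <- c("concordant", "rna_only", "rpf_only", "discordant", "none")
  table(factor(classes, levels = lv))
}

#' Full TE comparison between two conditions
#'
#' Convenience wrapper producing one row per shared gene: TE in each
#' condition, the log2 TE shift, per-layer direction calls and the event
#' class.
#'
#' @inheritParams translation_efficiency
#' @param ref_cond,test_cond Conditions to compare.
#' @param rna_de,rpf_de `de_table`s for this contrast (computed on the fly
#'   when omitted).
#' @param ... Passed to [wald_test()].
#' @return Data frame with columns `gene_id`, `te_ref`, `te_test`,
#'   `delta_te`, `rna_direction`, `rpf_direction`, `event_class`.
#' @export
te_compare <- function(rna_cm, rpf_cm, sheet, ref_cond, test_cond,
                       rna_de = NULL, rpf_de = NULL, pseudocount = 0.5, ...) {
  rna_de <- rna_de %||% wald_test(rna_cm, sheet, ref_cond, test_cond, ...)
  rpf_de <- rpf_de %||% wald_test(rpf_cm, sheet, ref_cond, test_cond, ...)
  ev <- classify_events(rna_de, rpf_de)
  te_ref <- translation_efficiency(rna_cm, rpf_cm, sheet, ref_cond,
                                   pseudocount)
  te_test <- translation_efficiency(rna_cm, rpf_cm, sheet, test_cond,
                                    pseudocount)
  genes <- intersect(ev$gene_id, names(te_ref))
  ev <- ev[match(genes, ev$gene_id), , drop = FALSE]
  data.frame(gene_id = genes,
             te_ref = unname(te_ref[genes]),
             te_test = unname(te_test[genes]),
             delta_te = unname(log2(te_test[genes] / te_ref[genes])),
             rna_direction = ev$rna_direction,
             rpf_direction = ev$rpf_direction,
             event_class = ev$event_class,
             stringsAsFactors = FALSE, row.names = NULL)
}
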