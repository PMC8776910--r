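#' Relative expression by the 2^-deltaCt method
#'
#' For each sample and target gene, deltaCt is the target's mean Ct minus
#' the sample's reference-gene mean Ct (technical replicate Cts are averaged
#' first), and relative expression is `2^-deltaCt`. Samples missing the
#' reference gene, or with non-finite Ct values, are dropped with a warning.
#'
#' @param ct_table `data.frame` with columns `sample_id`, `gene`, `ct` and
#'   optionally `condition`; multiple rows per sample/gene are treated as
#'   technical replicates.
#' @param reference_gene name of the reference (normalizer) gene, e.g.
#'   `"RPLP0"`.
#' @return `data.frame` with one row per sample x target gene: `sample_id`,
#'   `condition` (if present), `gene`, `mean_ct`, `ref_ct`, `delta_ct`,
#'   `rel_expr`.
#' @export
relative_expression <- function(ct_table, reference_gene) {
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(ct_table)))
    stopf("'ct_table' must have columns %s", paste(need, collapse = ", "))
  bad <- !is.finite(ct_table$ct) | ct_table$ct <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d row(s) with non-finite or non-positive Ct", sum(bad)))
    ct_table <- ct_table[!bad, , drop = FALSE]
  }
  if (!reference_gene %in% ct_table$gene)
    stopf("reference gene '%s' not present in the table", reference_gene)
  agg <- stats::aggregate(ct ~ sample_id + gene, data = ct_table, FUN = mean)
  ref <- agg[agg$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ref_ct"
  targets <- agg[agg$gene != reference_gene, ]
  names(targets)[names(targets) == "ct"] <- "mean_ct"
  missing_ref <- setdiff(unique(targets$sample_id), ref$sample_id)
  if (length(missing_ref)) {
    warning(sprintf("excluding sample(s) without reference gene: %s",
                    paste(missing_ref, collapse = ", ")))
    targets <- targets[!targets$sample_id %in% missing_ref, , drop = FALSE]
  }
  out <- merge(targets, ref, by = "sample_id", sort = FALSE)
  if ("condition" %in% names(ct_table)) {
    cond <- unique(ct_table[, c("sample_id", "condition")])
    out <- merge(out, cond, by = "sample_id", sort = FALSE)
  }
  out$delta_ct <- out$mean_ct - out$ref_ct
  out$rel_expr <- 2^(-out$delta_ct)
  out <- out[order(out$gene, out$sample_id), ]
  rownames(out) <- NULL
  out
}

#' Fold change versus a basal condition
#'
#' Divides each sample's relative expression by the mean relative expression
#' of the basal group (per gene), so the basal group's mean fold is 1 by
#' construction; values are "fold increases as compared with basal".
#'
#' @param rel output of [relative_expression()] with a `condition` column.
#' @param basal_condition name of the basal (reference) condition.
#' @return list with `per_sample` (rel table plus `fold_change`) and
#'   `summary` (`data.frame` of per-condition/gene mean fold, SE, n).
#' @export
fold_change <- function(rel, basal_condition) {
  if (!"condition" %in% names(rel))
    stopf("'rel' must carry a 'condition' column")
  if (!basal_condition %in% rel$condition)
    stopf("basal condition '%s' not present", basal_condition)
  rel$fold_change <- NA_real_
  for (g in unique(rel$gene)) {
    sel <- rel$gene == g
    basal_mean <- mean(rel$rel_expr[sel & rel$condition == basal_condition])
    if (!is.finite(basal_mean) || basal_mean <= 0)
      stopf("basal group mean relative expression is zero for gene '%s'", g)
    rel$fold_change[sel] <- rel$rel_expr[sel] / basal_mean
  }
  summ <- do.call(rbind, lapply(split(rel, list(rel$condition, rel$gene), drop = TRUE),
    function(g) data.frame(condition = g$condition[1], gene = g$gene[1],
                           mean_fold = mean(g$fold_change),
                           se_fold = standard_error(g$fold_change),
                           n = nrow(g))))
  rownames(summ) <- NULL
  list(per_sample = rel, summary = summ)
}
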