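#' Median-of-ratios size factors
#'
#' For every gene with a nonzero count in all samples, the ratio of its count
#' to its across-sample geometric mean is formed; the per-sample factor is the
#' median of these ratios, then the factors are rescaled to geometric mean 1.
#'
#' @param counts genes x samples non-negative matrix.
#' @return Named numeric vector of positive size factors (one per sample).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative.")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) abort("no gene has nonzero counts in all samples.")
  ref <- apply(counts[all_pos, , drop = FALSE], 1, geomean)
  ratios <- counts[all_pos, , drop = FALSE] / ref
  sf <- apply(ratios, 2, median)
  sf <- sf / geomean(sf)
  setNames(sf, colnames(counts))
}

#' Moderated differential expression on log counts
#'
#' A moderated-t surrogate for negative-binomial testing: counts are divided
#' by median-of-ratios size factors, shifted-log transformed
#' (`log2(normalized + offset)`), and run through the same per-gene linear
#' model + empirical-Bayes moderation used for methylation
#' ([fit_probe_models()], [moderate_variances()]), with the donor as a
#' covariate. The coefficient of the condition column is the log2 fold
#' change. All-zero genes are dropped with a message.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @param sheet sample sheet tibble (`sample`, `condition`, donor column).
#' @param contrast `c(treated, reference)` condition labels.
#' @param donor_col donor column name or `NULL`.
#' @param biotype optional named character vector (gene -> biotype); genes
#'   named `"protein_coding"` are flagged `coding` for [call_degs()].
#' @param offset pseudo-count added before the log (default 0.5).
#' @return Tibble of class `endotol_de` with columns `gene`, `logFC`,
#'   `mean_expr` (mean of the transformed values), `t`, `p`, `q`, `coding`.
#' @export
diff_expression <- function(counts, sheet, contrast, donor_col = "donor",
                            biotype = NULL, offset = 0.5) {
  check_number(offset, "offset", lower = 1e-9)
  design <- build_design(sheet, contrast, donor_col)
  counts <- as.matrix(counts)[, design$samples, drop = FALSE]
  if (is.null(rownames(counts))) rownames(counts) <- as.character(seq_len(nrow(counts)))
  if (anyDuplicated(rownames(counts))) abort("duplicate gene ids in `counts`.")
  nonzero <- rowSums(counts) > 0
  if (!all(nonzero)) {
    inform(sprintf("dropping %d all-zero gene(s).", sum(!nonzero)))
    counts <- counts[nonzero, , drop = FALSE]
  }
  sf <- size_factors(counts)
  y <- log2(sweep(counts, 2, sf, "/") + offset)
  fit <- fit_probe_models(y, design)
  mod <- moderate_variances(fit$s2, fit$df)
  t_mod <- fit$coef / (sqrt(mod$s2_tilde) * fit$stdev_unscaled)
  p <- 2 * pt(-abs(t_mod), df = mod$df_total)
  genes <- rownames(counts)
  coding <- if (is.null(biotype)) rep(TRUE, length(genes)) else {
    unname(biotype[genes] == "protein_coding" & !is.na(biotype[genes]))
  }
  out <- tibble(
    gene = genes,
    logFC = unname(fit$coef),
    mean_expr = unname(rowMeans(y)),
    t = unname(t_mod),
    p = unname(p),
    q = bh_fdr(unname(p)),
    coding = coding
  )
  new_tbl_subclass(out, "endotol_de",
                   d0 = mod$d0, s0_2 = mod$s0_2, df = fit$df,
                   contrast = contrast, size_factors = sf,
                   n_samples = length(design$samples))
}

#' Call differentially expressed genes
#'
#' Strict thresholds: `|logFC| > lfc` and `q < fdr`; optionally restricted to
#' protein-coding genes. Up/down counts are attached as attribute `counts`.
#'
#' @param de output of [diff_expression()].
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @param fdr FDR threshold (default 0.05).
#' @param coding_only keep only genes flagged `coding` (default TRUE).
#' @return Filtered tibble with a `direction` column (`up`/`down`).
#' @export
call_degs <- function(de, lfc = 1, fdr = 0.05, coding_only = TRUE) {
  check_number(lfc, "lfc", lower = 1e-12)
  check_number(fdr, "fdr", lower = 1e-12, upper = 1)
  check_flag(coding_only, "coding_only")
  keep <- abs(de$logFC) > lfc & de$q < fdr
  if (coding_only && "coding" %in% names(de)) keep <- keep & de$coding
  out <- as_tibble(de)[keep, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  attr(out, "counts") <- c(up = sum(out$direction == "up"),
                           down = sum(out$direction == "down"))
  out
}

#' Rank genes for preranked GSEA
#'
#' Scores each gene `-log10(q) * sign(logFC)` and sorts descending. Zero (or
#' sub-representable) q values are floored at one tenth of the smallest
#' positive q so the score stays finite while the ordering is preserved. Ties
#' are broken deterministically by larger `|logFC|`, then lexicographic gene
#' id, so the ranking is reproducible.
#'
#' @param de tibble with `gene`, `logFC` and `q` columns (e.g. from
#'   [diff_expression()]).
#' @return Tibble `(gene, score)` in descending score order.
#' @export
build_ranked_list <- function(de) {
  need <- c("gene", "logFC", "q")
  miss <- setdiff(need, names(de))
  if (length(miss)) abort(sprintf("`de` is missing column(s): %s.", paste(miss, collapse = ", ")))
  if (anyDuplicated(de$gene)) abort("duplicate gene ids in `de`.")
  q <- de$q
  if (any(q < 0 | q > 1)) abort("q values must lie in [0, 1].")
  tiny <- q < 1e-300
  if (any(tiny)) {
    flr <- min(q[!tiny & q > 0], 1e-300) / 10
    q[tiny] <- flr
  }
  score <- -log10(q) * sign(de$logFC)
  ord <- order(-score, -abs(de$logFC), de$gene)
  tibble(gene = de$gene[ord], score = score[ord])
}
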