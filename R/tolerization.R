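#' Collapse replicate expression columns to per-condition means
#'
#' Helper for time-course / re-stimulation tables: averages log-scale
#' expression over replicate samples of each condition.
#'
#' @param expr genes x samples numeric matrix (log2 scale).
#' @param sheet sample sheet tibble (`sample`, `condition`).
#' @return Tibble with a `gene` column and one numeric column per condition.
#' @export
condition_means <- function(expr, sheet) {
  sheet <- validate_sample_sheet(sheet)
  expr <- as.matrix(expr)[, sheet$sample, drop = FALSE]
  conds <- unique(sheet$condition)
  out <- tibble(gene = rownames(expr) %||% as.character(seq_len(nrow(expr))))
  for (cc in conds) {
    out[[cc]] <- rowMeans(expr[, sheet$condition == cc, drop = FALSE])
  }
  out
}

#' Tolerization score of a re-stimulation time course
#'
#' For each gene with log2 expression in four conditions (naive cells before
#' and after LPS re-exposure, and LPS-pre-exposed cells before and after
#' re-exposure) the score is
#' `(untreated_re - untreated) - (lps_re - lps)`:
#' the part of the naive re-stimulation response that pre-exposed cells fail
#' to mount. Positive scores mean the gene is tolerized (blunted induction in
#' pre-exposed cells); negative scores mean a stronger response after
#' pre-exposure. Absolute expression cancels, so gene-specific offsets
#' (length, mappability) do not affect the score.
#'
#' @param expr data frame with a `gene` column and the four condition columns.
#' @param untreated,untreated_re,lps,lps_re names of the condition columns
#'   (defaults `"untreated"`, `"untreated_re"`, `"LPS"`, `"LPS_re"`).
#' @return Tibble `(gene, untreated, untreated_re, lps, lps_re, score)`.
#' @export
#' @examples
#' tolerization_scores(tibble::tibble(
#'   gene = "g1", untreated = 2, untreated_re = 10, LPS = 3, LPS_re = 4
#' )) # score 7
tolerization_scores <- function(expr, untreated = "untreated",
                                untreated_re = "untreated_re",
                                lps = "LPS", lps_re = "LPS_re") {
  expr <- as_tibble(expr)
  cols <- c(untreated = untreated, untreated_re = untreated_re,
            lps = lps, lps_re = lps_re)
  for (nm in names(cols)) {
    if (!cols[[nm]] %in% names(expr)) {
      abort(sprintf("missing condition column '%s' (%s).", cols[[nm]], nm))
    }
  }
  if (!"gene" %in% names(expr)) abort("`expr` needs a `gene` column.")
  if (anyDuplicated(expr$gene)) abort("duplicate gene ids in `expr`.")
  vals <- map(cols, function(cc) {
    v <- expr[[cc]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      abort(sprintf("column '%s' must be finite numeric (log2 scale).", cc))
    }
    v
  })
  tibble(
    gene = expr$gene,
    untreated = vals$untreated,
    untreated_re = vals$untreated_re,
    lps = vals$lps,
    lps_re = vals$lps_re,
    score = (vals$untreated_re - vals$untreated) - (vals$lps_re - vals$lps)
  )
}

#' Top-N tolerized and non-tolerized gene sets
#'
#' The `n` genes with the highest scores form the tolerized set and the `n`
#' with the lowest form the non-tolerized set. Boundary ties are broken by
#' lexicographic gene id so the sets are deterministic. The two sets are
#' disjoint by construction; `2n` may not exceed the number of genes.
#'
#' @param scores tibble from [tolerization_scores()] (needs `gene`, `score`).
#' @param n set size (default 100).
#' @return Named list of two character vectors, `top<n>_tolerized` and
#'   `top<n>_non_tolerized`, ready for [write_gmt()] or [gsea_preranked()].
#' @export
top_n_sets <- function(scores, n = 100) {
  check_number(n, "n", lower = 1)
  n <- as.integer(n)
  n_genes <- nrow(scores)
  if (n > n_genes) abort("`n` exceeds the number of genes.")
  if (2L * n > n_genes) abort("2n exceeds the number of genes; sets would overlap.")
  top <- scores[order(-scores$score, scores$gene), ]$gene[seq_len(n)]
  bottom <- scores[order(scores$score, scores$gene), ]$gene[seq_len(n)]
  out <- list(top, bottom)
  names(out) <- paste0("top", n, c("_tolerized", "_non_tolerized"))
  attr(out, "descriptions") <- setNames(
    c("highest tolerization scores", "lowest tolerization scores"), names(out))
  out
}
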