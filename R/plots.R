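#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_hline geom_vline
#'   geom_rug labs theme_minimal scale_color_manual autoplot geom_segment
NULL

#' Volcano plot of a differential table
#'
#' Works for both differential methylation (effect = `delta_beta`) and
#' differential expression (effect = `logFC`) tibbles.
#'
#' @param stats tibble with an effect column and a `q` column.
#' @param effect_col name of the effect-size column (default guesses
#'   `delta_beta` then `logFC`).
#' @param fdr,effect thresholds drawn as guide lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(stats, effect_col = NULL, fdr = 0.05, effect = NULL) {
  effect_col <- effect_col %||%
    intersect(c("delta_beta", "logFC"), names(stats))[1]
  if (is.na(effect_col) || is.null(effect_col)) abort("no effect column found.")
  effect <- effect %||% if (effect_col == "delta_beta") 0.2 else 1
  df <- as_tibble(stats)
  df$significant <- df$q < fdr & abs(df[[effect_col]]) > effect
  ggplot(df, aes(x = .data[[effect_col]], y = -log10(.data$q),
                 color = .data$significant)) +
    geom_point(size = 0.6, alpha = 0.7) +
    geom_hline(yintercept = -log10(fdr), linetype = 2) +
    geom_vline(xintercept = c(-effect, effect), linetype = 2) +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = effect_col, y = "-log10(q)", color = "called") +
    theme_minimal()
}

#' Running enrichment-score (mountain) plot
#'
#' @param ranked ranked list tibble `(gene, score)`.
#' @param set gene set (character vector).
#' @param weight hit-increment exponent (default 1).
#' @return A ggplot object with the running sum and a hit rug.
#' @export
plot_running_score <- function(ranked, set, weight = 1) {
  es <- enrichment_score(ranked, set, weight)
  r <- es$running
  ggplot(r, aes(x = .data$rank, y = .data$running)) +
    geom_line(color = "forestgreen") +
    geom_hline(yintercept = 0, color = "grey50") +
    geom_rug(data = r[r$hit, ], sides = "b", length = grid::unit(0.03, "npc")) +
    labs(x = "rank", y = "running enrichment score",
         title = sprintf("ES = %.3f", es$es)) +
    theme_minimal()
}

#' Odds-ratio profile around CpGs
#'
#' @param object a `tile_profile` from [tile_peak_enrichment()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot tile_profile
#' @export
autoplot.tile_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$offset, y = .data$odds_ratio)) +
    geom_line(color = "steelblue") +
    geom_hline(yintercept = 1, linetype = 2, color = "grey50") +
    labs(x = "offset from CpG (bp)", y = "odds ratio") +
    theme_minimal()
}

#' Scatter of methylation change vs expression change
#'
#' @param object a `meth_expr_cor` object ([meth_expr_correlation()]).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot meth_expr_cor
#' @export
autoplot.meth_expr_cor <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$delta_beta, y = .data$logFC)) +
    geom_point(alpha = 0.7, color = "steelblue") +
    geom_hline(yintercept = 0, color = "grey70") +
    geom_vline(xintercept = 0, color = "grey70") +
    labs(x = "delta beta", y = "log2 fold change",
         title = sprintf("Pearson r = %.2f, p = %.2g (n = %d)",
                         object$r, object$p, object$n)) +
    theme_minimal()
}
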