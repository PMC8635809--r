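#' Assign CpGs to the nearest transcription start site
#'
#' Each CpG is assigned the gene whose TSS has the smallest absolute distance
#' on the same chromosome; ties are broken by the lexicographically smaller
#' gene id. The reported distance is signed and strand-aware: positive when
#' the CpG lies downstream of the TSS in the direction of transcription,
#' negative upstream. CpGs on chromosomes with no TSS are left unassigned
#' (dropped with a message). With `dedup_genes = TRUE`, genes hit by several
#' CpGs keep only their closest CpG (ties by probe id), the distance-
#' principled reading of "removing duplicate genes".
#'
#' @param cpgs tibble with `chrom`, `pos` (0-based) and `name` columns.
#' @param tss tibble with `chrom`, `pos` (0-based TSS coordinate), `strand`
#'   (`+`/`-`) and `gene` columns (an interval tibble from [read_bed()] can
#'   be converted with `pos = start`, `gene = name`).
#' @param dedup_genes keep one (closest) CpG per gene (default FALSE).
#' @return Tibble `(probe, gene, tss_pos, strand, distance)`.
#' @export
nearest_tss <- function(cpgs, tss, dedup_genes = FALSE) {
  check_flag(dedup_genes, "dedup_genes")
  for (col in c("chrom", "pos")) {
    if (!col %in% names(cpgs)) abort(sprintf("`cpgs` is missing column '%s'.", col))
    if (!col %in% names(tss)) abort(sprintf("`tss` is missing column '%s'.", col))
  }
  if (!"gene" %in% names(tss)) abort("`tss` is missing column 'gene'.")
  if (!nrow(tss)) abort("`tss` is empty.")
  strand <- tss$strand %||% rep("+", nrow(tss))
  probe <- cpgs$name %||% as.character(seq_len(nrow(cpgs)))
  rows <- vector("list", length(unique(cpgs$chrom)))
  ri <- 0L
  for (chrom in unique(cpgs$chrom)) {
    ci <- which(cpgs$chrom == chrom)
    ti <- which(tss$chrom == chrom)
    if (!length(ti)) next
    ord <- ti[order(tss$pos[ti])]
    sorted <- tss$pos[ord]
    upos <- unique(sorted)
    for (i in ci) {
      p <- cpgs$pos[i]
      k <- findInterval(p, upos)
      cand <- unique(c(max(k, 1L), min(k + 1L, length(upos))))
      d <- min(abs(upos[cand] - p))
      at <- upos[cand][abs(upos[cand] - p) == d]
      hit_rows <- ord[sorted %in% at]
      best <- hit_rows[order(tss$gene[hit_rows])][1]
      best_strand <- strand[best]
      ri <- ri + 1L
      rows[[ri]] <- tibble(
        probe = probe[i],
        gene = tss$gene[best],
        tss_pos = tss$pos[best],
        strand = best_strand,
        distance = if (best_strand == "-") tss$pos[best] - p else p - tss$pos[best]
      )
    }
  }
  n_unassigned <- nrow(cpgs) - ri
  if (n_unassigned > 0) {
    inform(sprintf("%d CpG(s) on chromosomes with no TSS left unassigned.", n_unassigned))
  }
  out <- bind_rows(rows[seq_len(ri)])
  if (dedup_genes && nrow(out)) {
    probe_order <- probe
    out <- out |>
      arrange(.data$gene, abs(.data$distance), .data$probe) |>
      distinct(.data$gene, .keep_all = TRUE) |>
      arrange(match(.data$probe, probe_order))
  }
  out
}

#' Correlate methylation change with expression change
#'
#' Pairs differentially methylated CpGs with differentially expressed genes
#' through a nearest-TSS assignment and computes the Pearson correlation of
#' `(delta_beta, logFC)` with its two-sided t-based p value. By default one
#' pair per gene is used (the assignment's closest CpG); `one_per_gene =
#' FALSE` keeps every CpG-gene pair.
#'
#' @param dmps tibble with `probe` and `delta_beta` ([call_dmps()]).
#' @param de tibble with `gene` and `logFC` ([diff_expression()] or
#'   [call_degs()]).
#' @param assign nearest-TSS tibble ([nearest_tss()]).
#' @param one_per_gene keep only the closest CpG per gene (default TRUE).
#' @return Object of class `meth_expr_cor`: list with `r`, `p`, `n` and the
#'   paired tibble `pairs`. `tidy()` returns the pairs, `glance()` the
#'   summary row.
#' @export
meth_expr_correlation <- function(dmps, de, assign, one_per_gene = TRUE) {
  check_flag(one_per_gene, "one_per_gene")
  pairs <- assign |>
    inner_join(as_tibble(dmps)[, c("probe", "delta_beta")], by = "probe") |>
    inner_join(as_tibble(de)[, c("gene", "logFC")], by = "gene")
  if (one_per_gene && nrow(pairs)) {
    pairs <- pairs |>
      arrange(.data$gene, abs(.data$distance), .data$probe) |>
      distinct(.data$gene, .keep_all = TRUE)
  }
  if (nrow(pairs) < 3L) abort("need at least 3 CpG-gene pairs.")
  if (var(pairs$delta_beta) == 0 || var(pairs$logFC) == 0) {
    abort("zero variance in delta_beta or logFC; correlation undefined.")
  }
  ct <- cor.test(pairs$delta_beta, pairs$logFC, method = "pearson")
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs),
         pairs = pairs),
    class = "meth_expr_cor"
  )
}

#' @export
print.meth_expr_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation of delta-beta vs logFC: r = %.3f, p = %.3g (n = %d pairs)\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' @method tidy meth_expr_cor
#' @export
tidy.meth_expr_cor <- function(x, ...) x$pairs

#' @method glance meth_expr_cor
#' @export
glance.meth_expr_cor <- function(x, ...) {
  tibble(r = x$r, p = x$p, n = x$n)
}

#' Hierarchical clustering of expression time courses
#'
#' Standardizes each gene's trajectory (mean 0, sd 1), clusters with
#' Euclidean distance and complete linkage, and cuts the tree into `k`
#' clusters. Cluster labels `C1..Ck` are ordered by descending cluster-mean
#' value at the final column so the labelling is deterministic. Constant rows
#' cannot be standardized and are dropped with a warning.
#'
#' @param expr genes x timepoint numeric matrix (rownames = genes), or a data
#'   frame whose first column is `gene`.
#' @param k number of clusters (default 3).
#' @return Object of class `timecourse_clusters`: list with `assignments`
#'   (tibble `gene`, `cluster`), `tree` (hclust) and `k`. `tidy()` returns
#'   the assignments.
#' @export
hier_cluster_timecourse <- function(expr, k = 3) {
  check_number(k, "k", lower = 1)
  k <- as.integer(k)
  if (is.data.frame(expr)) {
    genes <- as.character(expr[[1]])
    expr <- as.matrix(expr[, -1, drop = FALSE])
    rownames(expr) <- genes
  }
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) rownames(expr) <- as.character(seq_len(nrow(expr)))
  if (ncol(expr) < 2L) abort("need at least 2 timepoints.")
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant row(s); standardization undefined.", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (nrow(expr) < k) abort("fewer usable genes than clusters.")
  z <- t(scale(t(expr)))
  tree <- hclust(dist(z), method = "complete")
  raw <- cutree(tree, k = k)
  final <- map_dbl(seq_len(k), function(cl) mean(z[raw == cl, ncol(z)]))
  relabel <- match(raw, order(final, decreasing = TRUE))
  structure(
    list(
      assignments = tibble(gene = rownames(expr),
                           cluster = paste0("C", relabel)),
      tree = tree,
      k = k
    ),
    class = "timecourse_clusters"
  )
}

#' @method tidy timecourse_clusters
#' @export
tidy.timecourse_clusters <- function(x, ...) x$assignments

#' @method glance timecourse_clusters
#' @export
glance.timecourse_clusters <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$assignments))
}

#' @export
print.timecourse_clusters <- function(x, ...) {
  cat(sprintf("Time-course clustering: %d genes in %d clusters (complete linkage)\n",
              nrow(x$assignments), x$k))
  print(table(x$assignments$cluster))
  invisible(x)
}
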