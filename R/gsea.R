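#' Weighted running-sum enrichment score
#'
#' Walks down a ranked gene list; at each gene in the set the running sum
#' increases by `|score|^weight / sum(|score in set|^weight)`, at each gene
#' outside it decreases by `1 / (N - set size)`. The enrichment score (ES) is
#' the running-sum value of largest magnitude; the leading edge comprises the
#' set members at or before the extremum (positive ES) or after it (negative
#' ES). With `weight = 0` this is the classical Kolmogorov-Smirnov statistic
#' on the hit positions.
#'
#' @param ranked tibble `(gene, score)`; re-sorted to descending score (ties
#'   by larger `|score|` are already resolved upstream, see
#'   [build_ranked_list()]).
#' @param set character vector of gene ids; must intersect the list but not
#'   cover it.
#' @param weight exponent on `|score|` for hit increments (default 1).
#' @return List with `es`, `running` (tibble `rank`, `gene`, `score`, `hit`,
#'   `running`) and `leading_edge`.
#' @export
#' @examples
#' rl <- tibble::tibble(gene = paste0("g", 1:4), score = 4:1)
#' enrichment_score(rl, "g1")$es # 1
enrichment_score <- function(ranked, set, weight = 1) {
  ranked <- validate_ranked(ranked)
  hit <- ranked$gene %in% set
  k <- sum(hit)
  n <- nrow(ranked)
  if (k == 0L) abort("set not represented in the ranked list.")
  if (k == n) abort("set covers the whole ranked list; misses are undefined.")
  w <- abs(ranked$score[hit])^weight
  hit_inc <- if (sum(w) > 0) w / sum(w) else rep(1 / k, k)
  inc <- numeric(n)
  inc[hit] <- hit_inc
  inc[!hit] <- -1 / (n - k)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  es <- running[peak]
  leading <- if (es >= 0) {
    ranked$gene[hit & seq_len(n) <= peak]
  } else {
    ranked$gene[hit & seq_len(n) > peak]
  }
  list(
    es = es,
    running = tibble(rank = seq_len(n), gene = ranked$gene,
                     score = ranked$score, hit = hit, running = running),
    leading_edge = leading
  )
}

validate_ranked <- function(ranked) {
  need <- c("gene", "score")
  miss <- setdiff(need, names(ranked))
  if (length(miss)) abort(sprintf("ranked list is missing column(s): %s.", paste(miss, collapse = ", ")))
  if (anyDuplicated(ranked$gene)) abort("duplicate genes in ranked list.")
  if (any(!is.finite(ranked$score))) abort("ranked scores must be finite.")
  ranked <- as_tibble(ranked)
  if (is.unsorted(rev(ranked$score))) {
    ranked <- ranked[order(-ranked$score), ]
  }
  ranked
}

# ES from sorted hit positions; same statistic (and first-extremum tie rule)
# as enrichment_score() but O(k) given positions, used for the permutation
# null. Local maxima of the running sum sit at hit positions, local minima
# just before hits; the trailing decay to 0 never exceeds either.
es_from_positions <- function(pos, w, n) {
  k <- length(pos)
  sw <- sum(w)
  cw <- if (sw > 0) cumsum(w) / sw else seq_len(k) / k
  miss <- 1 / (n - k)
  drop <- (pos - seq_len(k)) * miss
  after <- cw - drop            # running value at index pos
  before <- c(0, cw[-k]) - drop # running value at index pos - 1
  vals <- c(after, before)
  idx <- c(pos, pos - 1L)
  keep <- idx >= 1L
  vals <- c(vals[keep], 0)
  idx <- c(idx[keep], n)
  best <- order(-abs(vals), idx)[1]
  vals[best]
}

#' Preranked GSEA with a gene-label permutation null
#'
#' For each gene set the observed ES ([enrichment_score()]) is compared with
#' the ES of random gene sets of identical size drawn without replacement
#' from the ranked list (gene-label permutation; the natural null for a
#' preranked list, which carries no phenotype labels). The nominal p uses the
#' add-one convention over the same-sign null, the normalized enrichment
#' score (NES) divides the ES by the mean `|ES|` of the same-sign null, and
#' the collection-level FDR q is the standard ratio-of-tails estimate on
#' pooled normalized null scores, clamped to `[0, 1]`. One RNG stream is
#' seeded once and consumed in set order, so results are bit-reproducible
#' for a given `seed` and `n_perm`.
#'
#' @param ranked tibble `(gene, score)` (e.g. [build_ranked_list()]).
#' @param sets named list of gene-id vectors ([read_gmt()], [top_n_sets()]).
#'   Sets with no gene in the list (or covering the whole list) are dropped
#'   with a warning.
#' @param n_perm permutations per set (default 1000; >= 100 required).
#' @param seed RNG seed for the permutation stream.
#' @param weight hit-increment exponent (default 1).
#' @param exhaustive enumerate all placements instead of sampling (only
#'   feasible for small `choose(N, k)`; capped at `1e5` placements).
#' @return Tibble of class `endotol_gsea`: `set`, `size`, `es`, `nes`, `p`,
#'   `q`, `leading_edge` (list column), `n_perm`.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, seed = 1, weight = 1,
                           exhaustive = FALSE) {
  ranked <- validate_ranked(ranked)
  if (!exhaustive) check_number(n_perm, "n_perm", lower = 100)
  check_flag(exhaustive, "exhaustive")
  if (!length(sets)) abort("`sets` is empty.")
  if (is.null(names(sets))) abort("`sets` must be named.")
  n <- nrow(ranked)
  sizes <- map_int(sets, function(s) sum(ranked$gene %in% s))
  usable <- sizes > 0L & sizes < n
  if (!any(usable)) abort("no set is represented in the ranked list.")
  if (!all(usable)) {
    warn(sprintf("dropping %d set(s) not usable with this ranked list: %s",
                 sum(!usable), paste(names(sets)[!usable], collapse = ", ")))
    sets <- sets[usable]
    sizes <- sizes[usable]
  }
  absw <- abs(ranked$score)^weight

  obs <- map(sets, function(s) enrichment_score(ranked, s, weight))
  es <- map_dbl(obs, "es")

  null_es <- withr::with_seed(seed, {
    map(seq_along(sets), function(i) {
      k <- sizes[[i]]
      if (exhaustive) {
        if (choose(n, k) > 1e5) {
          abort(sprintf("exhaustive enumeration infeasible for set '%s' (choose(%d, %d) placements).",
                        names(sets)[i], n, k))
        }
        placements <- utils::combn(n, k, simplify = FALSE)
      } else {
        placements <- map(seq_len(n_perm), function(j) sort(sample.int(n, k)))
      }
      map_dbl(placements, function(pos) es_from_positions(pos, absw[pos], n))
    })
  })

  p <- map_dbl(seq_along(sets), function(i) {
    e <- es[i]
    if (e == 0) return(1)
    same <- null_es[[i]][sign(null_es[[i]]) == sign(e)]
    (1 + sum(abs(same) >= abs(e))) / (1 + length(same))
  })
  nes <- map_dbl(seq_along(sets), function(i) {
    e <- es[i]
    same <- null_es[[i]][sign(null_es[[i]]) == sign(e)]
    if (!length(same)) return(NA_real_)
    e / mean(abs(same))
  })

  # pooled normalized null for the ratio-of-tails FDR
  null_nes <- unlist(map(null_es, function(ne) {
    pos <- ne[ne > 0]
    neg <- ne[ne < 0]
    out <- numeric(0)
    if (length(pos)) out <- c(out, pos / mean(pos))
    if (length(neg)) out <- c(out, neg / mean(abs(neg)))
    out
  }))
  q <- map_dbl(seq_along(sets), function(i) {
    s <- nes[i]
    if (is.na(s)) return(NA_real_)
    if (s >= 0) {
      null_tail <- sum(null_nes >= s) / max(1, sum(null_nes >= 0))
      obs_tail <- sum(nes >= s, na.rm = TRUE) / max(1, sum(nes >= 0, na.rm = TRUE))
    } else {
      null_tail <- sum(null_nes <= s) / max(1, sum(null_nes < 0))
      obs_tail <- sum(nes <= s, na.rm = TRUE) / max(1, sum(nes < 0, na.rm = TRUE))
    }
    min(1, max(0, null_tail / max(obs_tail, .Machine$double.eps)))
  })

  out <- tibble(
    set = names(sets),
    size = as.integer(sizes),
    es = unname(es),
    nes = nes,
    p = p,
    q = q,
    leading_edge = unname(map(obs, "leading_edge")),
    n_perm = map_int(null_es, length)
  )
  new_tbl_subclass(out, "endotol_gsea", seed = seed, weight = weight)
}

#' @method tidy endotol_gsea
#' @export
tidy.endotol_gsea <- function(x, ...) {
  out <- as_tibble(x)
  out$leading_edge <- map_chr(out$leading_edge, paste, collapse = ",")
  class(out) <- setdiff(class(out), "endotol_gsea")
  out
}

#' @method glance endotol_gsea
#' @export
glance.endotol_gsea <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_perm = max(x$n_perm),
    seed = attr(x, "seed"),
    weight = attr(x, "weight"),
    n_significant = sum(x$q < 0.05, na.rm = TRUE)
  )
}
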