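#' Exact two-sided Fisher test and odds ratio for 2x2 tables
#'
#' Vectorized over tables `(a, b, c, d)` = (target hit, target miss,
#' background hit, background miss). The p value is the exact conditional
#' (hypergeometric) two-sided probability: the sum of all table probabilities
#' not exceeding the observed one (with the conventional `1 + 1e-7` relative
#' tolerance for floating-point ties). The odds ratio is the cross-product
#' `ad/bc`, with the Haldane-Anscombe 0.5 correction applied to all four
#' cells whenever any cell is zero.
#'
#' @param a,b,c,d non-negative integer vectors (recycled to common length).
#' @return Tibble `(a, b, c, d, odds_ratio, p)`.
#' @export
#' @examples
#' fisher_2x2(8, 2, 20, 80)$odds_ratio # 16
fisher_2x2 <- function(a, b, c, d) {
  tab <- tibble(a = a, b = b, c = c, d = d)
  if (any(unlist(tab) < 0) || any(unlist(tab) != round(unlist(tab)))) {
    abort("cells must be non-negative integers.")
  }
  p <- pmap(tab, function(a, b, c, d) {
    m <- a + c # hits
    n_ <- b + d # misses
    k <- a + b # target size
    support <- max(0, k - n_):min(k, m)
    dens <- dhyper(support, m, n_, k)
    obs <- dhyper(a, m, n_, k)
    min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  })
  orr <- pmap_dbl_local(tab, function(a, b, c, d) {
    if (any(c(a, b, c, d) == 0)) {
      (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5))
    } else {
      a * d / (b * c)
    }
  })
  tab$odds_ratio <- orr
  tab$p <- map_dbl(p, identity)
  tab
}

pmap_dbl_local <- function(tab, f) {
  vapply(seq_len(nrow(tab)), function(i) {
    f(tab$a[i], tab$b[i], tab$c[i], tab$d[i])
  }, numeric(1))
}

#' Symmetric windows around CpG positions
#'
#' For a CpG at 0-based position `p`, the window is
#' `[max(0, p - flank), p + flank + 1)`: `flank` bp on each side plus the CpG
#' base itself (length `2 * flank + 1` away from the contig start).
#'
#' @param cpgs tibble with `chrom`, `pos` (0-based) and `name` columns.
#' @param flank flank size in bp (default 250).
#' @return Interval tibble, one window per CpG, input order preserved.
#' @export
windows_around <- function(cpgs, flank = 250) {
  check_number(flank, "flank", lower = 1)
  need <- c("chrom", "pos")
  miss <- setdiff(need, names(cpgs))
  if (length(miss)) abort(sprintf("`cpgs` is missing column(s): %s.", paste(miss, collapse = ", ")))
  genomic_intervals(
    chrom = cpgs$chrom,
    start = pmax(0L, as.integer(cpgs$pos) - as.integer(flank)),
    end = as.integer(cpgs$pos) + as.integer(flank) + 1L,
    name = cpgs$name %||% as.character(seq_len(nrow(cpgs)))
  )
}

# log-odds matrix of a pwm: log2((count + pc) / (colsum + 4 pc)) - log2(bg)
pwm_logodds <- function(pwm) {
  counts <- pwm$counts
  pc <- pwm$pseudocount
  freq <- sweep(counts + pc, 2, colSums(counts) + 4 * pc, "/")
  log2(freq) - log2(pwm$background)
}

#' Maximum achievable log-odds score of a PWM
#'
#' @param pwm a `pwm` object.
#' @return Sum of the column-wise maxima of the log-odds matrix.
#' @export
pwm_max_score <- function(pwm) {
  sum(apply(pwm_logodds(pwm), 2, max))
}

encode_seq <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
}

# max-score / scores over all starts for an encoded sequence; NA where the
# L-mer contains a non-ACGT base
scan_scores <- function(enc, lo) {
  L <- ncol(lo)
  n <- length(enc) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    sc <- sc + lo[enc[j:(j + n - 1L)], j]
  }
  unname(sc)
}

#' Scan a sequence with a PWM on both strands
#'
#' Log-odds scoring: at start `i`, the score is the sum over motif columns of
#' `log2((count + pseudocount) / (column total + 4 * pseudocount)) -
#' log2(background)`. The minus strand is scanned by scoring the
#' reverse-complemented matrix at the same forward coordinates, so a minus
#' hit at position `i` means the reverse complement of the L-mer starting at
#' `i` matches. L-mers containing `N` are skipped; a sequence shorter than
#' the motif yields an empty result.
#'
#' @param seq a single nucleotide string over A, C, G, T, N.
#' @param pwm a `pwm` object.
#' @param threshold minimum log-odds score to report.
#' @return Tibble `(pos, strand, score)`, `pos` 0-based start on the forward
#'   strand, sorted by position.
#' @export
pwm_scan <- function(seq, pwm, threshold) {
  if (!inherits(pwm, "pwm")) abort("`pwm` must be a pwm object.")
  check_number(threshold, "threshold")
  enc <- encode_seq(seq)
  lo <- pwm_logodds(pwm)
  lo_rc <- lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
  fwd <- scan_scores(enc, lo)
  rev_ <- scan_scores(enc, lo_rc)
  keep_f <- which(!is.na(fwd) & fwd >= threshold)
  keep_r <- which(!is.na(rev_) & rev_ >= threshold)
  out <- tibble(
    pos = c(keep_f, keep_r) - 1L,
    strand = rep(c("+", "-"), c(length(keep_f), length(keep_r))),
    score = c(fwd[keep_f], rev_[keep_r])
  )
  out[order(out$pos, out$strand), ]
}

#' Motif enrichment in target vs background windows
#'
#' HOMER-style known-motif enrichment: each window is a hit for a motif if it
#' contains at least one position (either strand) scoring at or above the
#' threshold; hits are compared between target and background windows with a
#' two-sided exact Fisher test per motif and BH correction across motifs.
#' Background windows sharing a name with a target window are removed first
#' so the two groups are disjoint, mirroring the "all array CpGs minus
#' targets" background convention.
#'
#' @param targets,background window tibbles (see [windows_around()]).
#' @param seqs named character vector of contig sequences (see
#'   [read_fasta()]).
#' @param pwms list of `pwm` objects (a single `pwm` is accepted).
#' @param threshold absolute log-odds threshold, or `NULL` to use
#'   `threshold_frac * pwm_max_score(pwm)` per motif.
#' @param threshold_frac fraction of the maximum achievable score (default
#'   0.8) used when `threshold` is `NULL`.
#' @return Tibble `(motif, target_hit, target_miss, bg_hit, bg_miss,
#'   odds_ratio, p, q)`.
#' @export
motif_enrichment <- function(targets, background, seqs, pwms,
                             threshold = NULL, threshold_frac = 0.8) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (!nrow(targets)) abort("`targets` is empty.")
  if (!nrow(background)) abort("`background` is empty.")
  shared <- intersect(targets$name, background$name)
  if (length(shared)) {
    inform(sprintf("removing %d background window(s) that are targets.", length(shared)))
    background <- background[!background$name %in% shared, , drop = FALSE]
    if (!nrow(background)) abort("`background` is empty after removing targets.")
  }
  window_seq <- function(win) {
    miss <- setdiff(unique(win$chrom), names(seqs))
    if (length(miss)) abort(sprintf("contig(s) missing from `seqs`: %s.", paste(miss, collapse = ", ")))
    substr_vec <- function(chrom, start, end) {
      substring(seqs[chrom], start + 1L, end)
    }
    map_chr(seq_len(nrow(win)), function(i) substr_vec(win$chrom[i], win$start[i], win$end[i]))
  }
  enc_t <- map(window_seq(targets), encode_seq)
  enc_b <- map(window_seq(background), encode_seq)
  rows <- map(pwms, function(pwm) {
    thr <- threshold %||% (threshold_frac * pwm_max_score(pwm))
    lo <- pwm_logodds(pwm)
    lo_rc <- lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
    has_hit <- function(enc) {
      sc <- c(scan_scores(enc, lo), scan_scores(enc, lo_rc))
      any(!is.na(sc) & sc >= thr)
    }
    th <- sum(map_lgl(enc_t, has_hit))
    bh <- sum(map_lgl(enc_b, has_hit))
    f <- fisher_2x2(th, length(enc_t) - th, bh, length(enc_b) - bh)
    tibble(motif = pwm$name, target_hit = th, target_miss = length(enc_t) - th,
           bg_hit = bh, bg_miss = length(enc_b) - bh,
           odds_ratio = f$odds_ratio, p = f$p)
  })
  out <- bind_rows(rows)
  out$q <- bh_fdr(out$p)
  out
}

# logical n_cpg x n_offsets hit matrix: TRUE when the tile at that offset
# overlaps >= 1 bp of any peak
tile_hits <- function(cpgs, peaks, flank, tile) {
  offsets <- seq(-flank, flank - tile, by = tile)
  hits <- matrix(FALSE, nrow(cpgs), length(offsets))
  if (!nrow(peaks)) return(hits)
  for (chrom in unique(cpgs$chrom)) {
    ci <- which(cpgs$chrom == chrom)
    pos <- cpgs$pos[ci]
    ord <- order(pos)
    sorted <- pos[ord]
    pk <- peaks[peaks$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(pk))) {
      s <- pk$start[i]
      e <- pk$end[i]
      lo_idx <- findInterval(s - flank + 1 - 1e-9, sorted) + 1L
      hi_idx <- findInterval(e + flank - 1 + 1e-9, sorted)
      if (hi_idx < lo_idx) next
      for (j in lo_idx:hi_idx) {
        p <- sorted[j]
        o_lo <- max(s - p - tile + 1, -flank)
        o_hi <- min(e - p - 1, flank - tile)
        if (o_lo > o_hi) next
        t_lo <- ceiling((o_lo + flank) / tile) + 1L
        t_hi <- floor((o_hi + flank) / tile) + 1L
        if (t_lo > t_hi) next
        hits[ci[ord[j]], t_lo:t_hi] <- TRUE
      }
    }
  }
  hits
}

#' Tile-wise peak enrichment around CpGs
#'
#' Divides the `[-flank, +flank)` region around each CpG into `tile`-bp
#' tiles; at each offset a CpG is a hit if its tile overlaps at least 1 bp of
#' any peak. Per offset, target hits/misses vs background hits/misses give a
#' 2x2 table tested with the exact Fisher test; odds ratios use the
#' Haldane-Anscombe correction when needed, so the degenerate no-peak case
#' yields OR = 1 everywhere (with a warning).
#'
#' @param targets,background CpG tibbles with `chrom`, `pos` (0-based) and
#'   `name` columns.
#' @param peaks interval tibble ([read_bed()]).
#' @param flank half-width of the profiled region in bp (default 3000); must
#'   be divisible by `tile`.
#' @param tile tile width in bp (default 10).
#' @return Tibble of class `tile_profile` with `offset` (bp of the tile start
#'   relative to the CpG), the 2x2 counts, `odds_ratio`, `p` and BH `q`
#'   across tiles; `2 * flank / tile` rows with strictly increasing offsets.
#' @export
tile_peak_enrichment <- function(targets, background, peaks, flank = 3000,
                                 tile = 10) {
  check_number(flank, "flank", lower = 1)
  check_number(tile, "tile", lower = 1)
  if (flank %% tile != 0) abort("`flank` must be divisible by `tile`.")
  if (!nrow(targets) || !nrow(background)) abort("empty target or background CpGs.")
  if (!nrow(peaks)) warn("empty peak list: all odds ratios are 1 under correction.")
  offsets <- seq(-flank, flank - tile, by = tile)
  th <- colSums(tile_hits(targets, peaks, flank, tile))
  bh <- colSums(tile_hits(background, peaks, flank, tile))
  f <- fisher_2x2(th, nrow(targets) - th, bh, nrow(background) - bh)
  out <- tibble(
    offset = as.integer(offsets),
    target_hit = as.integer(th), target_miss = nrow(targets) - as.integer(th),
    bg_hit = as.integer(bh), bg_miss = nrow(background) - as.integer(bh),
    odds_ratio = f$odds_ratio, p = f$p, q = bh_fdr(f$p)
  )
  new_tbl_subclass(out, "tile_profile", flank = flank, tile = tile)
}

#' Genomic-category enrichment of target CpGs
#'
#' For each level of a single-label annotation (genomic feature or CpG-island
#' context), tests in-label vs not-in-label counts of target CpGs against
#' background CpGs with the two-sided exact Fisher test, BH-corrected across
#' labels. A label present in targets but absent from the background is
#' counted with zero background hits (corrected odds ratio) and flagged with
#' a warning.
#'
#' @param targets,background tibbles carrying `label_col`.
#' @param label_col name of the annotation column (default
#'   `"genomic_feature"`).
#' @return Tibble `(label, target_hit, target_miss, bg_hit, bg_miss,
#'   odds_ratio, p, q, direction)` with `direction` in
#'   `enriched`/`depleted`/`none` relative to OR = 1.
#' @export
category_enrichment <- function(targets, background,
                                label_col = "genomic_feature") {
  for (nm in c("targets", "background")) {
    tbl <- get(nm)
    if (!label_col %in% names(tbl)) {
      abort(sprintf("`%s` is missing column '%s'.", nm, label_col))
    }
    if (anyNA(tbl[[label_col]])) abort(sprintf("`%s`: missing labels.", nm))
  }
  if (!nrow(targets) || !nrow(background)) abort("empty target or background CpGs.")
  labels <- sort(unique(c(targets[[label_col]], background[[label_col]])))
  orphan <- setdiff(unique(targets[[label_col]]), unique(background[[label_col]]))
  if (length(orphan)) {
    warn(sprintf("label(s) absent from background: %s (corrected odds ratio used).",
                 paste(orphan, collapse = ", ")))
  }
  th <- map_int(labels, function(l) sum(targets[[label_col]] == l))
  bh <- map_int(labels, function(l) sum(background[[label_col]] == l))
  f <- fisher_2x2(th, nrow(targets) - th, bh, nrow(background) - bh)
  tibble(
    label = labels,
    target_hit = th, target_miss = nrow(targets) - th,
    bg_hit = bh, bg_miss = nrow(background) - bh,
    odds_ratio = f$odds_ratio, p = f$p, q = bh_fdr(f$p),
    direction = case_when(
      f$odds_ratio > 1 ~ "enriched",
      f$odds_ratio < 1 ~ "depleted",
      TRUE ~ "none"
    )
  )
}
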