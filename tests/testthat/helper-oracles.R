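# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition, by a different route than the
# package implementation.

# BH step-up from the literal definition: q_i = min over p_(j) >= p_i of
# min(1, p_(j) * m / j)
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, numeric(1))
  q_sorted[order(o)]
}

# two-sided Fisher p by literal enumeration of the conditional distribution
fisher_bruteforce <- function(a, b, c, d) {
  k <- a + b
  hits <- a + c
  total <- a + b + c + d
  support <- max(0, k - (total - hits)):min(k, hits)
  dens <- vapply(support, function(x) {
    choose(hits, x) * choose(total - hits, k - x) / choose(total, k)
  }, numeric(1))
  obs <- dens[support == a]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# running-sum ES from first principles (independent loop implementation)
es_bruteforce <- function(scores, hit, weight = 1) {
  n <- length(scores)
  k <- sum(hit)
  w <- abs(scores[hit])^weight
  denom <- if (sum(w) > 0) sum(w) else NA
  running <- numeric(n)
  cur <- 0
  wi <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      wi <- wi + 1
      cur <- cur + if (is.na(denom)) 1 / k else w[wi] / denom
    } else {
      cur <- cur - 1 / (n - k)
    }
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# all-pairs nearest TSS with lexicographic tie-break
nearest_tss_bruteforce <- function(cpgs, tss) {
  do.call(rbind, lapply(seq_len(nrow(cpgs)), function(i) {
    same <- tss[tss$chrom == cpgs$chrom[i], , drop = FALSE]
    if (!nrow(same)) return(NULL)
    d <- abs(same$pos - cpgs$pos[i])
    cand <- same[d == min(d), , drop = FALSE]
    best <- cand[order(cand$gene)[1], , drop = FALSE]
    data.frame(probe = cpgs$name[i], gene = best$gene,
               stringsAsFactors = FALSE)
  }))
}

# per-tile hit counts by an explicit double loop over CpGs and peaks
tile_counts_bruteforce <- function(cpgs, peaks, flank, tile) {
  offsets <- seq(-flank, flank - tile, by = tile)
  vapply(offsets, function(o) {
    sum(vapply(seq_len(nrow(cpgs)), function(i) {
      s <- cpgs$pos[i] + o
      e <- s + tile
      any(peaks$chrom == cpgs$chrom[i] & peaks$start < e & peaks$end > s)
    }, logical(1)))
  }, numeric(1))
}

random_intervals <- function(n, chroms = c("chr1", "chr2")) {
  start <- sample.int(1e6, n)
  genomic_intervals(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(5000, n),
    name = paste0("iv", seq_len(n)),
    strand = sample(c("+", "-", "."), n, replace = TRUE)
  )
}

# minimal paired two-condition sheet
toy_sheet <- function(n_donors = 3, conditions = c("untreated", "LPS")) {
  tibble::tibble(
    sample = as.vector(outer(seq_len(n_donors), conditions,
                             function(d, cc) paste0("D", d, "_", cc))),
    condition = rep(conditions, each = n_donors),
    donor = rep(paste0("D", seq_len(n_donors)), 2)
  )
}
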