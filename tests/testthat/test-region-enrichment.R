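test_that("Fisher 2x2 matches the cross-product OR and exact reference p", {
  f <- fisher_2x2(8, 2, 20, 80)
  expect_equal(f$odds_ratio, 16)
  expect_equal(f$p, fisher.test(matrix(c(8, 2, 20, 80), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  # Haldane-Anscombe correction engages on zero cells
  fz <- fisher_2x2(5, 0, 3, 7)
  expect_equal(fz$odds_ratio, (5.5 * 7.5) / (0.5 * 3.5))
  # swap of target and background inverts the (uncorrected) OR
  f1 <- fisher_2x2(6, 4, 10, 30)
  f2 <- fisher_2x2(10, 30, 6, 4)
  expect_equal(f1$odds_ratio, 1 / f2$odds_ratio, tolerance = 1e-12)
  expect_equal(f1$p, f2$p, tolerance = 1e-12)
  expect_error(fisher_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p equals brute-force hypergeometric enumeration on small tables", {
  withr::local_seed(61)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, size = sample(5:30, 1), prob = rep(0.25, 4)))
    ours <- fisher_2x2(cells[1], cells[2], cells[3], cells[4])$p
    expect_equal(ours, fisher_bruteforce(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("windows_around applies the flank definition with left clamping", {
  cpgs <- tibble::tibble(chrom = "chr1", pos = c(1000L, 100L),
                         name = c("a", "b"))
  w <- windows_around(cpgs, 250)
  expect_equal(w$start, c(750L, 0L))
  expect_equal(w$end, c(1251L, 351L))
  expect_equal(w$name, c("a", "b"))
  expect_equal(nrow(windows_around(cpgs[0, ], 250)), 0)
})

test_that("PWM log-odds scanning matches direct evaluation", {
  # uniform 1-column PWM scores 0 at every position
  uni <- new_pwm("uni", matrix(1, 4, 1))
  sc <- pwm_scan("ACGTAC", uni, threshold = -1)
  expect_equal(nrow(sc), 12) # 6 positions x 2 strands
  expect_true(all(abs(sc$score) < 1e-9))

  # consensus scores the column-max sum; one mismatch scores strictly less
  pwm <- stat_like_pwm()
  consensus <- "TTCCGGGAA"
  hits <- pwm_scan(consensus, pwm, threshold = 0)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$score, pwm_max_score(pwm), tolerance = 1e-12)
  for (j in c(1, 5, 9)) {
    mm <- consensus
    substr(mm, j, j) <- "C"
    mm_hits <- pwm_scan(mm, pwm, threshold = -100)
    expect_lt(max(mm_hits$score[mm_hits$strand == "+"]), pwm_max_score(pwm))
  }

  # reverse-complement symmetry: strands swap, scores preserved
  withr::local_seed(67)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  h_f <- pwm_scan(seq, pwm, threshold = 5)
  h_r <- pwm_scan(rc, pwm, threshold = 5)
  expect_equal(nrow(h_f), nrow(h_r))
  expect_equal(sort(h_f$score), sort(h_r$score), tolerance = 1e-9)

  # sequence shorter than the motif yields an empty result, not an error
  expect_equal(nrow(pwm_scan("ACG", pwm, threshold = 0)), 0)
  # N-containing L-mers are skipped
  expect_equal(nrow(pwm_scan("TTCCNGGAA", pwm, threshold = -100)), 0)
})

test_that("motif enrichment builds the 2x2 from window hits", {
  pwm <- stat_like_pwm()
  withr::local_seed(71)
  mer <- "TTCCGGGAA"
  # A/C-only background cannot contain the consensus (or its reverse
  # complement) by chance, so the hit counts are exactly the planted ones
  rand_seq <- function() paste(sample(c("A", "C"), 61, TRUE), collapse = "")
  with_motif <- function() {
    s <- rand_seq()
    substr(s, 20, 28) <- mer
    s
  }
  # one contig per window keeps the fixture explicit
  n_t <- 12; n_b <- 40
  t_seqs <- c(replicate(9, with_motif()), replicate(3, rand_seq()))
  b_seqs <- c(replicate(2, with_motif()), replicate(38, rand_seq()))
  seqs <- setNames(c(t_seqs, b_seqs), paste0("w", seq_len(n_t + n_b)))
  win <- function(idx, prefix) {
    genomic_intervals(paste0("w", idx), 0, 61, name = paste0(prefix, idx))
  }
  res <- motif_enrichment(win(1:n_t, "t"), win(n_t + 1:n_b, "b"), seqs, pwm)
  expect_equal(res$target_hit, 9)
  expect_equal(res$bg_hit, 2)
  expect_lt(res$q, 0.01)
  expect_equal(res$odds_ratio, (9 * 38) / (3 * 2))
  expect_error(motif_enrichment(win(1:2, "t")[0, ], win(3:4, "b"), seqs, pwm),
               "empty")
})

test_that("tile profile counts equal the brute-force interval-overlap loop", {
  withr::local_seed(73)
  flank <- 300; tile <- 10
  targets <- tibble::tibble(chrom = "chr1",
                            pos = sample(2000:8000, 20),
                            name = paste0("t", 1:20))
  background <- tibble::tibble(chrom = "chr1",
                               pos = sample(2000:8000, 60),
                               name = paste0("b", 1:60))
  peaks <- genomic_intervals("chr1",
                             start = targets$pos[1:10] - sample(0:150, 10, TRUE),
                             end = targets$pos[1:10] + sample(10:200, 10, TRUE))
  prof <- tile_peak_enrichment(targets, background, peaks, flank, tile)
  expect_equal(nrow(prof), 2 * flank / tile)
  expect_true(all(diff(prof$offset) == tile))
  expect_equal(prof$target_hit,
               as.integer(tile_counts_bruteforce(targets, peaks, flank, tile)))
  expect_equal(prof$bg_hit,
               as.integer(tile_counts_bruteforce(background, peaks, flank, tile)))
})

test_that("tile profile handles saturating and empty peak sets", {
  targets <- tibble::tibble(chrom = "chr1", pos = c(5000L, 6000L), name = c("t1", "t2"))
  background <- tibble::tibble(chrom = "chr1", pos = c(7000L, 8000L), name = c("b1", "b2"))
  everything <- genomic_intervals("chr1", 0, 1e6)
  sat <- tile_peak_enrichment(targets, background, everything, 3000, 10)
  expect_equal(nrow(sat), 600)
  expect_true(all(sat$odds_ratio == 1)) # saturated cells, corrected OR
  expect_warning(
    none <- tile_peak_enrichment(targets, background, everything[0, ], 3000, 10),
    "empty peak"
  )
  expect_true(all(none$odds_ratio == 1))
  # splitting a peak into abutting pieces leaves the counts unchanged
  peak <- genomic_intervals("chr1", 4900, 5300)
  split <- genomic_intervals("chr1", c(4900, 5100), c(5100, 5300))
  p1 <- tile_peak_enrichment(targets, background, peak, 300, 10)
  p2 <- tile_peak_enrichment(targets, background, split, 300, 10)
  expect_equal(p1$target_hit, p2$target_hit)
  expect_equal(p1$bg_hit, p2$bg_hit)
})

test_that("category enrichment reports complementary directions", {
  targets <- tibble::tibble(genomic_feature = rep("intergenic", 20))
  background <- tibble::tibble(genomic_feature = rep(c("intergenic", "promoter"), 50))
  res <- category_enrichment(targets, background)
  expect_gt(res$odds_ratio[res$label == "intergenic"], 1)
  expect_lt(res$odds_ratio[res$label == "promoter"], 1)
  expect_equal(res$direction, c("enriched", "depleted"))
  # identical label distributions: OR 1, p 1
  same <- tibble::tibble(genomic_feature = rep(c("a", "b"), 25))
  null <- category_enrichment(same, same)
  expect_true(all(null$odds_ratio == 1))
  expect_equal(null$p, rep(1, 2), tolerance = 1e-12)
  # label absent from background is corrected, with a warning
  orphan <- tibble::tibble(genomic_feature = c(rep("a", 5), "weird"))
  expect_warning(res2 <- category_enrichment(orphan, same), "absent")
  expect_true(is.finite(res2$odds_ratio[res2$label == "weird"]))
})
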