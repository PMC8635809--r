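test_that("size factors follow the median-of-ratios definition", {
  withr::local_seed(12)
  counts <- matrix(rnbinom(50 * 4, mu = 100, size = 5) + 1, 50, 4,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  # identical columns -> all factors 1
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(size_factors(same)), rep(1, 3))
  # doubling one column doubles its factor relative to the others
  doubled <- counts
  doubled[, 2] <- doubled[, 2] * 2L
  sf <- size_factors(doubled)
  sf_base <- size_factors(counts)
  expect_equal(unname(sf[2] / sf[1]), unname(2 * sf_base[2] / sf_base[1]),
               tolerance = 1e-12)
  # direct re-computation of the definition
  ref <- apply(counts, 1, function(x) exp(mean(log(x))))
  manual <- apply(counts / ref, 2, median)
  manual <- manual / exp(mean(log(manual)))
  expect_equal(size_factors(counts), manual, tolerance = 1e-12)
  # gene-order invariance
  expect_equal(size_factors(counts[sample.int(50), ]), size_factors(counts))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "nonzero")
})

test_that("size factors are proportional to the reference median-of-ratios fit", {
  withr::local_seed(13)
  counts <- matrix(rnbinom(200 * 6, mu = 80, size = 3) + 1, 200, 6)
  ours <- unname(size_factors(counts))
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  # the reference takes the median on the log scale, which interpolates
  # even-length medians geometrically rather than arithmetically
  expect_equal(ours / ours[1], unname(ref / ref[1]), tolerance = 1e-3)
})

test_that("moderated DE recovers the shifted-log fold change exactly", {
  sheet <- toy_sheet(2)
  # a majority of constant filler genes pins every size factor at exactly 1
  # (their count ratios dominate the medians); a few noisy genes keep the
  # residual variances non-degenerate, and the tested gene moves
  withr::local_seed(1)
  filler <- matrix(rep(c(50L, 100L, 200L, 80L, 60L, 120L, 90L), 4), 7, 4,
                   dimnames = list(paste0("g", 1:7), sheet$sample))
  noisy <- matrix(rnbinom(4 * 4, mu = 100, size = 10), 4, 4,
                  dimnames = list(paste0("n", 1:4), sheet$sample))
  counts <- rbind(filler, noisy, gX = c(10L, 10L, 40L, 40L))
  de <- suppressMessages(diff_expression(counts, sheet, c("LPS", "untreated"),
                                         donor_col = NULL))
  expect_equal(de$logFC[de$gene == "gX"], log2(40.5) - log2(10.5),
               tolerance = 5e-4)
})

test_that("DE results are invariant to sample column permutation", {
  sim <- simulate_counts(n_genes = 400, n_de = 30, seed = 17)
  de1 <- diff_expression(sim$counts, sim$sheet, c("LPS", "untreated"))
  withr::local_seed(4)
  perm <- sample.int(ncol(sim$counts))
  de2 <- diff_expression(sim$counts[, perm], sim$sheet[perm, ],
                         c("LPS", "untreated"))
  expect_equal(de1$logFC, de2$logFC, tolerance = 1e-10)
  expect_equal(de1$q, de2$q, tolerance = 1e-10)
})

test_that("DEG calling applies strict thresholds and the biotype filter", {
  de <- tibble::tibble(
    gene = c("up", "weak", "noncoding"),
    logFC = c(1.2, -0.9, 3),
    q = c(0.01, 0.001, 1e-8),
    coding = c(TRUE, TRUE, FALSE)
  )
  degs <- call_degs(de)
  expect_equal(degs$gene, "up")
  expect_equal(degs$direction, "up")
  expect_equal(nrow(call_degs(de, coding_only = FALSE)), 2)
  # monotone non-increasing in both thresholds
  sim <- simulate_counts(n_genes = 500, n_de = 50, seed = 19)
  full <- diff_expression(sim$counts, sim$sheet, c("LPS", "untreated"))
  n_loose <- nrow(call_degs(full, lfc = 0.5, fdr = 0.1))
  n_mid <- nrow(call_degs(full, lfc = 1, fdr = 0.05))
  n_tight <- nrow(call_degs(full, lfc = 1.5, fdr = 0.01))
  expect_true(n_loose >= n_mid && n_mid >= n_tight)
})

test_that("planted fold changes are recovered at the DEG thresholds", {
  sim <- simulate_counts(n_genes = 5000, n_de = 200, lfc = 2, seed = 1)
  de <- diff_expression(sim$counts, sim$sheet, c("LPS", "untreated"))
  degs <- call_degs(de, lfc = 1, fdr = 0.05)
  expect_gte(mean(sim$truth$gene %in% degs$gene), 0.80)
  expect_lte(mean(!degs$gene %in% sim$truth$gene), 0.10)
  # recovered directions match the planted signs
  hit <- degs[degs$gene %in% sim$truth$gene, ]
  truth_sign <- sign(sim$truth$true_lfc[match(hit$gene, sim$truth$gene)])
  expect_true(all(sign(hit$logFC) == truth_sign))
})

test_that("ranking metric is signed -log10(q) with deterministic tie-breaks", {
  de <- tibble::tibble(
    gene = c("a", "b", "c", "d", "e"),
    logFC = c(2, -0.5, 1, 3, -1),
    q = c(0.01, 0.001, 1, 1, 1)
  )
  rl <- build_ranked_list(de)
  expect_equal(rl$score[rl$gene == "a"], 2)
  expect_equal(rl$score[rl$gene == "b"], -3)
  expect_true(all(rl$score[rl$gene %in% c("c", "d", "e")] == 0))
  # zero-score ties: larger |logFC| first, then gene id (|1| ties c before e)
  zeros <- rl$gene[rl$score == 0]
  expect_equal(zeros, c("d", "c", "e"))
  expect_error(build_ranked_list(de[c(1, 1, 2), ]), "duplicate")
})

test_that("ranking is antisymmetric under flipping the contrast", {
  sim <- simulate_counts(n_genes = 300, n_de = 30, seed = 23)
  de_fwd <- diff_expression(sim$counts, sim$sheet, c("LPS", "untreated"))
  de_rev <- diff_expression(sim$counts, sim$sheet, c("untreated", "LPS"))
  expect_equal(de_fwd$logFC, -de_rev$logFC, tolerance = 1e-10)
  rl_fwd <- build_ranked_list(de_fwd)
  rl_rev <- build_ranked_list(de_rev)
  scores_rev <- setNames(rl_rev$score, rl_rev$gene)
  expect_equal(unname(scores_rev[rl_fwd$gene]), -rl_fwd$score, tolerance = 1e-10)
})

test_that("q floor keeps vanishing FDRs finite and ordered", {
  de <- tibble::tibble(gene = c("a", "b", "c"),
                       logFC = c(2, 2, 2),
                       q = c(0, 1e-10, 0.5))
  rl <- build_ranked_list(de)
  expect_true(all(is.finite(rl$score)))
  expect_equal(rl$gene[1], "a") # floored below the smallest positive q
})
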