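test_that("beta/M conversion is the logit2, antisymmetric and invertible", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(beta_to_m(b), -beta_to_m(1 - b))
  expect_true(all(diff(beta_to_m(b)) > 0))
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  expect_error(beta_to_m(1.2), "\\[0, 1\\]")
  # boundary values stay finite through the clip
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))
})

test_that("per-probe OLS reproduces closed forms and lm() on a paired design", {
  withr::local_seed(21)
  # two groups, no donor column: coefficient is the group-mean difference
  sheet <- toy_sheet(3)
  m <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, sheet$sample))
  des <- build_design(sheet, c("LPS", "untreated"), donor_col = NULL)
  fit <- fit_probe_models(m, des)
  lps <- sheet$condition == "LPS"
  expect_equal(unname(fit$coef),
               rowMeans(m[, lps]) - rowMeans(m[, !lps]))
  expect_equal(fit$fitted + (m - fit$fitted), m)

  # paired design: agree with lm() per probe (independent solver)
  des2 <- build_design(sheet, c("LPS", "untreated"), donor_col = "donor")
  fit2 <- fit_probe_models(m, des2)
  cond <- as.integer(lps)
  donor <- factor(sheet$donor)
  for (i in c(1, 7, 20)) {
    ref <- lm(m[i, ] ~ cond + donor)
    expect_equal(unname(fit2$coef[i]), unname(coef(ref)["cond"]), tolerance = 1e-10)
    expect_equal(fit2$s2[i], sum(resid(ref)^2) / ref$df.residual, tolerance = 1e-10)
  }
  expect_equal(fit2$df, 6 - 4)
  # paired contrast equals the mean of within-donor differences
  expect_equal(unname(fit2$coef),
               rowMeans(m[, lps][, order(sheet$donor[lps])] -
                          m[, !lps][, order(sheet$donor[!lps])]))
})

test_that("variance moderation recovers a known scaled-chisquare prior", {
  withr::local_seed(42)
  d <- 4
  s2 <- 1 * rchisq(10000, d) / d # true s0^2 = 1, infinite prior df
  mod <- moderate_variances(s2, d)
  expect_gt(mod$s0_2, 0.9)
  expect_lt(mod$s0_2, 1.1)
  expect_gt(mod$d0, 50)
  expect_true(all(mod$s2_tilde > 0))
  expect_error(moderate_variances(rep(0, 100), 4), "degenerate")
})

test_that("variance moderation agrees with the reference empirical-Bayes fit", {
  withr::local_seed(7)
  d <- 3
  true_s0 <- 2
  true_d0 <- 8
  s2 <- true_s0 * true_d0 / rchisq(5000, true_d0) * rchisq(5000, d) / d
  mod <- moderate_variances(s2, d)
  ref <- limma::squeezeVar(s2, df = d)
  expect_equal(mod$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_2, ref$var.prior, tolerance = 1e-6)
  expect_equal(mod$s2_tilde, ref$var.post, tolerance = 1e-6)
})

test_that("BH step-up matches its definition, p.adjust, and hand examples", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_error(bh_fdr(c(0.1, NaN)), "NA")
  grid <- c(0.001, 0.02, 0.2, 0.5, 1)
  withr::local_seed(9)
  for (len in 2:6) {
    for (rep_i in 1:40) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(bh_fdr(p), bh_bruteforce(p))
      expect_equal(bh_fdr(p), p.adjust(p, "BH"))
    }
  }
  # order preserving and q >= p
  p <- runif(200)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("DMP calling applies strict thresholds and labels direction", {
  stats <- tibble::tibble(
    probe = c("a", "b", "c", "d"),
    q = c(0.01, 0.01, 0.2, 0.01),
    delta_beta = c(-0.25, -0.10, -0.5, 0.30)
  )
  dmps <- call_dmps(stats)
  expect_equal(dmps$probe, c("a", "d"))
  expect_equal(dmps$direction, c("hypo", "hyper"))
  expect_equal(attr(dmps, "counts"), c(hypo = 1L, hyper = 1L))
  # ties at the threshold are excluded (strict inequalities)
  edge <- tibble::tibble(probe = "e", q = 0.05, delta_beta = -0.2)
  expect_equal(nrow(call_dmps(edge)), 0)
  expect_error(call_dmps(stats, fdr = 2), "fdr")
})

test_that("differential methylation is invariant to probe and sample order", {
  sim <- simulate_methylome(n_probes = 300, n_dmp = 20, n_donors = 3, seed = 14)
  dm1 <- diff_methylation(sim$beta, sim$sheet, c("LPS", "untreated"))
  withr::local_seed(2)
  perm_p <- sample.int(nrow(sim$beta))
  perm_s <- sample.int(ncol(sim$beta))
  dm2 <- diff_methylation(sim$beta[perm_p, perm_s], sim$sheet[perm_s, ],
                          c("LPS", "untreated"))
  dm2 <- dm2[match(dm1$probe, dm2$probe), ]
  expect_equal(dm1$t, dm2$t, tolerance = 1e-9)
  expect_equal(dm1$q, dm2$q, tolerance = 1e-9)
  expect_equal(dm1$delta_beta, dm2$delta_beta, tolerance = 1e-12)
})

test_that("covariate correction removes donor offsets and nothing else", {
  withr::local_seed(31)
  sheet <- toy_sheet(3)
  base <- matrix(rnorm(50 * 6, sd = 0.5), 50, 6,
                 dimnames = list(paste0("cg", 1:50), sheet$sample))
  # no donor columns: correction is the beta -> M -> beta round trip
  beta0 <- m_to_beta(base)
  out0 <- remove_covariate_effects(beta0, sheet, c("LPS", "untreated"),
                                   donor_col = NULL)
  expect_equal(out0, beta0, tolerance = 1e-12)

  # noise-free fixture: per-probe value + condition effect + 1 M-unit offset
  # on donor D2; the correction removes the donor offset exactly
  probe_m <- rnorm(50)
  cond_eff <- rnorm(50, sd = 0.3)
  m <- sapply(seq_len(nrow(sheet)), function(j) {
    probe_m + cond_eff * (sheet$condition[j] == "LPS") +
      1 * (sheet$donor[j] == "D2")
  })
  dimnames(m) <- list(paste0("cg", 1:50), sheet$sample)
  corrected <- remove_covariate_effects(m_to_beta(m), sheet, c("LPS", "untreated"))
  mc <- beta_to_m(corrected)
  for (cc in unique(sheet$condition)) {
    cols <- which(sheet$condition == cc)
    expect_equal(mc[, cols[1]], mc[, cols[2]], tolerance = 1e-9)
    expect_equal(mc[, cols[1]], mc[, cols[3]], tolerance = 1e-9)
  }
  # condition difference untouched
  expect_equal(unname(mc[, sheet$condition == "LPS"][, 1] -
                        mc[, sheet$condition == "untreated"][, 1]),
               cond_eff, tolerance = 1e-9)

  # balanced design: corrected group means equal uncorrected group means
  # (M scale), because removed donor effects are coded sum-to-zero
  beta <- m_to_beta(base)
  corr <- remove_covariate_effects(beta, sheet, c("LPS", "untreated"))
  for (cc in unique(sheet$condition)) {
    cols <- sheet$condition == cc
    expect_equal(rowMeans(beta_to_m(corr)[, cols]),
                 rowMeans(beta_to_m(beta, clip = 1e-6)[, cols]),
                 tolerance = 1e-9)
  }
  # agrees with the reference batch-effect removal on the M scale
  ref <- limma::removeBatchEffect(
    beta_to_m(beta), batch = sheet$donor,
    design = stats::model.matrix(~sheet$condition)
  )
  expect_equal(beta_to_m(corr), ref, ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(
    remove_covariate_effects(beta, sheet, c("LPS", "untreated"), keep = character()),
    "keep"
  )
})

test_that("glance and tidy expose the moderation prior and plain stats", {
  sim <- simulate_methylome(n_probes = 200, n_dmp = 0, n_donors = 2, seed = 8)
  dm <- diff_methylation(sim$beta, sim$sheet, c("LPS", "untreated"))
  g <- glance(dm)
  expect_equal(g$n_probes, 200)
  expect_true(g$prior_var > 0)
  expect_false(inherits(tidy(dm), "endotol_dm"))
})
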