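#' Convert between beta and M values
#'
#' Methylation beta values (fraction methylated signal, in `[0, 1]`) are
#' mapped to M values `M = log2(beta / (1 - beta))` for linear modelling,
#' where their variance is closer to constant across the range. Betas are
#' clipped to `[clip, 1 - clip]` first so boundary values stay finite.
#'
#' @param beta numeric vector or matrix of beta values in `[0, 1]`.
#' @param clip small positive clip applied before the logit (default 1e-6).
#' @return M values with the same shape as the input.
#' @export
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8)) # -2, 0, 2
beta_to_m <- function(beta, clip = 1e-6) {
  check_number(clip, "clip", lower = .Machine$double.xmin, upper = 0.5)
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    abort("beta values must lie in [0, 1].")
  }
  b <- pmin(pmax(beta, clip), 1 - clip)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @param m numeric vector or matrix of M values.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Build a two-condition design with donor covariates
#'
#' Encodes intercept + condition indicator (+ donor indicator columns when
#' `donor_col` is given) for the samples belonging to the two contrasted
#' conditions. The tested coefficient is the condition indicator, so the
#' fitted contrast is treated minus reference on whatever scale is modelled.
#'
#' @param sheet sample sheet tibble with `sample`, `condition` and, for a
#'   paired design, a donor column.
#' @param contrast length-2 character vector `c(treated, reference)`.
#' @param donor_col name of the donor column, or `NULL` for an unpaired model.
#' @return A list of class `endotol_design` with elements `X` (samples x p
#'   design matrix), `coef` (tested column name), `donor_cols`, `samples`
#'   and `contrast`.
#' @export
build_design <- function(sheet, contrast, donor_col = "donor") {
  sheet <- validate_sample_sheet(sheet)
  if (length(contrast) != 2L) abort("`contrast` must be c(treated, reference).")
  miss <- setdiff(contrast, unique(sheet$condition))
  if (length(miss)) {
    abort(sprintf("condition(s) not in sheet: %s.", paste(miss, collapse = ", ")))
  }
  sheet <- sheet[sheet$condition %in% contrast, , drop = FALSE]
  cond_counts <- table(sheet$condition)
  if (any(cond_counts < 2L)) {
    abort("each contrasted condition needs at least 2 samples.")
  }
  treated <- as.integer(sheet$condition == contrast[1])
  X <- cbind(intercept = 1, condition = treated)
  donor_cols <- character()
  if (!is.null(donor_col)) {
    if (!donor_col %in% names(sheet)) {
      abort(sprintf("donor column '%s' not in sheet.", donor_col))
    }
    donors <- factor(sheet[[donor_col]])
    if (nlevels(donors) > 1L) {
      D <- model.matrix(~donors)[, -1, drop = FALSE]
      colnames(D) <- paste0("donor_", levels(donors)[-1])
      donor_cols <- colnames(D)
      X <- cbind(X, D)
    }
  }
  rownames(X) <- sheet$sample
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank-deficient.")
  if (nrow(X) <= ncol(X)) abort("no residual degrees of freedom (n <= rank).")
  structure(
    list(X = X, coef = "condition", donor_cols = donor_cols,
         samples = sheet$sample, contrast = contrast, sheet = sheet),
    class = "endotol_design"
  )
}

#' Per-probe ordinary least squares
#'
#' Fits the same design to every row of an M-value matrix in one QR pass and
#' returns the tested contrast coefficient, the residual mean square and the
#' residual degrees of freedom, the inputs of [moderate_variances()].
#'
#' @param m probes x samples numeric matrix (columns must match
#'   `design$samples`).
#' @param design an `endotol_design` from [build_design()].
#' @return List with `coef` (tested coefficient per probe), `coefficients`
#'   (full p-column matrix), `s2`, `df` (scalar), `stdev_unscaled` (scalar
#'   `sqrt((X'X)^{-1})` entry for the tested coefficient) and `fitted`.
#' @export
fit_probe_models <- function(m, design) {
  if (!inherits(design, "endotol_design")) abort("`design` must come from build_design().")
  X <- design$X
  if (is.null(colnames(m)) || !identical(colnames(m), rownames(X))) {
    if (!is.null(colnames(m)) && setequal(colnames(m), rownames(X))) {
      m <- m[, rownames(X), drop = FALSE]
    } else {
      abort("columns of `m` must match the design samples.")
    }
  }
  if (anyNA(m)) abort("`m` contains missing values; drop incomplete probes first.")
  n <- nrow(X)
  p <- ncol(X)
  df <- n - p
  qrX <- qr(X)
  coefs <- t(qr.coef(qrX, t(m)))
  fitted <- coefs %*% t(X)
  res <- m - fitted
  s2 <- rowSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  list(
    coef = coefs[, design$coef],
    coefficients = coefs,
    s2 = as.numeric(s2),
    df = df,
    stdev_unscaled = sqrt(xtx_inv[design$coef, design$coef]),
    fitted = fitted
  )
}

# Newton solve of trigamma(y) = x, vectorized; monotone decreasing trigamma
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y), na.rm = TRUE) < 1e-10) break
  }
  y[x > 1e7] <- 1 / sqrt(x[x > 1e7])
  y[x < 1e-6] <- 1 / x[x < 1e-6]
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-probe residual variances toward a common prior by treating the
#' observed `s2` as scaled F draws around a prior variance `s0_2` with prior
#' degrees of freedom `d0`, estimated by method of moments on `log(s2)`
#' (digamma/trigamma matching). The moderated variance is the usual weighted
#' combination `(d0 * s0_2 + df * s2) / (d0 + df)`; when the observed
#' log-variances are no more dispersed than chi-square sampling alone allows,
#' `d0` is `Inf` and every probe gets the common variance.
#'
#' @param s2 per-probe residual mean squares (length >= 10 recommended).
#' @param df residual degrees of freedom (scalar, >= 1).
#' @return List with `d0`, `s0_2`, `s2_tilde` and `df_total = d0 + df`.
#' @export
moderate_variances <- function(s2, df) {
  check_number(df, "df", lower = 1)
  if (all(s2 == 0)) abort("all residual variances are zero; data are degenerate.")
  if (any(s2 < 0)) abort("negative residual variance.")
  pos <- s2 > 0
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e)
  resid_var <- evar - trigamma(df / 2)
  if (is.finite(resid_var) && resid_var > 0) {
    d0 <- 2 * trigamma_inverse(resid_var)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  s2_tilde <- if (is.finite(d0)) (d0 * s0_2 + df * s2) / (d0 + df) else rep(s0_2, length(s2))
  list(d0 = d0, s0_2 = s0_2, s2_tilde = s2_tilde, df_total = d0 + df)
}

#' Benjamini-Hochberg step-up FDR
#'
#' `q_i = min over p_(j) >= p_(i) of min(1, p_(j) * m / j)`, the classical
#' step-up adjustment; monotone in `p` and always `>= p`.
#'
#' @param p vector of p values in `[0, 1]`; `NA`/`NaN` are an error.
#' @return Vector of q values in the input order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) abort("`p` contains NA/NaN.")
  if (any(p < 0 | p > 1)) abort("p values must lie in [0, 1].")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Moderated differential methylation on M values
#'
#' The full per-probe pipeline: betas are logit-transformed to M values,
#' a linear model with intercept, condition and (paired design) donor
#' indicator columns is fitted per probe, residual variances are moderated
#' empirically ([moderate_variances()]), moderated t statistics and BH
#' q values are computed, and the raw-beta group difference
#' `delta_beta = mean beta(treated) - mean beta(reference)` is attached.
#' Probes with any missing beta are dropped (no imputation) with a message.
#'
#' @param beta probes x samples beta matrix in `[0, 1]`.
#' @param sheet sample sheet tibble (`sample`, `condition`, donor column).
#' @param contrast `c(treated, reference)` condition labels.
#' @param donor_col donor column name or `NULL` for an unpaired model.
#' @param clip beta clip before the logit (see [beta_to_m()]).
#' @return A tibble of class `endotol_dm` with columns `probe`, `coef`
#'   (M-value units), `s2`, `t`, `p`, `q`, `delta_beta`; attributes carry the
#'   moderation prior (`d0`, `s0_2`), `df`, and the contrast. Use
#'   [call_dmps()] to threshold it.
#' @export
diff_methylation <- function(beta, sheet, contrast, donor_col = "donor",
                             clip = 1e-6) {
  design <- build_design(sheet, contrast, donor_col)
  beta <- beta[, design$samples, drop = FALSE]
  complete <- complete.cases(beta)
  if (!all(complete)) {
    inform(sprintf("dropping %d probe(s) with missing betas.", sum(!complete)))
    beta <- beta[complete, , drop = FALSE]
  }
  if (nrow(beta) < 2L) abort("need at least 2 complete probes.")
  m <- beta_to_m(beta, clip)
  fit <- fit_probe_models(m, design)
  mod <- moderate_variances(fit$s2, fit$df)
  t_mod <- fit$coef / (sqrt(mod$s2_tilde) * fit$stdev_unscaled)
  p <- 2 * pt(-abs(t_mod), df = mod$df_total)
  q <- bh_fdr(p)
  treated <- design$sheet$condition == contrast[1]
  delta_beta <- rowMeans(beta[, treated, drop = FALSE]) -
    rowMeans(beta[, !treated, drop = FALSE])
  out <- tibble(
    probe = rownames(beta) %||% as.character(seq_len(nrow(beta))),
    coef = unname(fit$coef),
    s2 = fit$s2,
    t = unname(t_mod),
    p = unname(p),
    q = unname(q),
    delta_beta = unname(delta_beta)
  )
  new_tbl_subclass(out, "endotol_dm",
                   d0 = mod$d0, s0_2 = mod$s0_2, df = fit$df,
                   contrast = contrast, n_samples = length(design$samples))
}

#' Call differentially methylated positions
#'
#' Keeps probes with `q < fdr` and `|delta_beta| > delta` (both strict) and
#' labels the direction: `hypo` for negative `delta_beta` (lower methylation
#' in the treated condition), `hyper` otherwise.
#'
#' @param stats output of [diff_methylation()] (needs `q` and `delta_beta`).
#' @param fdr FDR threshold in `(0, 1]` (default 0.05).
#' @param delta absolute beta-difference threshold in `(0, 1)` (default 0.2).
#' @return Tibble of passing probes with a `direction` column; hypo/hyper
#'   counts are attached as attribute `counts`.
#' @export
call_dmps <- function(stats, fdr = 0.05, delta = 0.2) {
  check_number(fdr, "fdr", lower = 1e-12, upper = 1)
  if (!(delta > 0 && delta < 1)) abort("`delta` must be in (0, 1).")
  need <- c("q", "delta_beta")
  miss <- setdiff(need, names(stats))
  if (length(miss)) abort(sprintf("`stats` is missing column(s): %s.", paste(miss, collapse = ", ")))
  out <- as_tibble(stats)[stats$q < fdr & abs(stats$delta_beta) > delta, , drop = FALSE]
  out$direction <- ifelse(out$delta_beta < 0, "hypo", "hyper")
  attr(out, "counts") <- c(hypo = sum(out$direction == "hypo"),
                           hyper = sum(out$direction == "hyper"))
  out
}

#' Remove covariate (donor) effects from betas for display
#'
#' Fits the full design on M values with the donor block coded sum-to-zero
#' (so the removed effects average out to zero across donors and balanced
#' group means are preserved), subtracts the fitted donor contribution, and
#' converts back to betas. Condition effects are kept; this is a display
#' correction, not part of the statistical test (which runs on uncorrected M
#' values).
#'
#' @param beta probes x samples beta matrix.
#' @param sheet,contrast,donor_col as in [diff_methylation()].
#' @param keep design columns to keep, from `c("intercept", "condition")`
#'   plus donor columns; defaults to every non-donor column. An empty `keep`
#'   is an error.
#' @param clip beta clip before the logit.
#' @return Corrected beta matrix in `[0, 1]`, same shape/order as the input
#'   restricted to the contrasted samples.
#' @export
remove_covariate_effects <- function(beta, sheet, contrast, donor_col = "donor",
                                     keep = NULL, clip = 1e-6) {
  design <- build_design(sheet, contrast, donor_col)
  X <- design$X[, setdiff(colnames(design$X), design$donor_cols), drop = FALSE]
  donor_cols <- character()
  if (length(design$donor_cols)) {
    donors <- factor(design$sheet[[donor_col]])
    D <- model.matrix(~donors, contrasts.arg = list(donors = "contr.sum"))[, -1, drop = FALSE]
    colnames(D) <- paste0("donor_", seq_len(ncol(D)))
    donor_cols <- colnames(D)
    X <- cbind(X, D)
    rownames(X) <- design$samples
  }
  keep <- keep %||% setdiff(colnames(X), donor_cols)
  if (!length(keep)) abort("`keep` must name at least one design column.")
  bad <- setdiff(keep, colnames(X))
  if (length(bad)) abort(sprintf("unknown design column(s): %s.", paste(bad, collapse = ", ")))
  remove_cols <- setdiff(colnames(X), keep)
  design$X <- X
  beta <- beta[, design$samples, drop = FALSE]
  m <- beta_to_m(beta, clip)
  fit <- fit_probe_models(m, design)
  if (length(remove_cols)) {
    m <- m - fit$coefficients[, remove_cols, drop = FALSE] %*%
      t(X[, remove_cols, drop = FALSE])
  }
  m_to_beta(m)
}

#' @method glance endotol_dm
#' @export
glance.endotol_dm <- function(x, ...) {
  tibble(
    n_probes = nrow(x),
    n_samples = attr(x, "n_samples"),
    df = attr(x, "df"),
    prior_df = attr(x, "d0"),
    prior_var = attr(x, "s0_2"),
    contrast = paste(attr(x, "contrast"), collapse = " vs ")
  )
}

#' @method tidy endotol_dm
#' @export
tidy.endotol_dm <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "endotol_dm")
  out
}
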