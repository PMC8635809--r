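#' Simulate an EPIC-like methylome with planted differential probes
#'
#' Emulates the structure of a paired two-condition methylation array study:
#' per-probe baseline M values drawn from a bimodal mixture (most array
#' probes sit near fully unmethylated or fully methylated), additive donor
#' random effects on the M scale shared across a donor's samples (the paired
#' design), additive per-sample noise on the M scale, and `n_dmp` planted
#' probes whose treated-condition beta is shifted by `delta_beta`. Planted
#' baselines are drawn mid-range so the requested shift stays inside
#' `[0, 1]`; infeasible draws are resampled (bounded retries).
#'
#' @param n_probes number of probes (default 20000).
#' @param n_dmp number of planted differential probes (default 300).
#' @param n_donors donors; each contributes one sample per condition
#'   (default 3).
#' @param conditions length-2 character vector `c(reference, treated)`.
#' @param delta_beta planted treated-minus-reference beta difference
#'   (default -0.3, i.e. hypomethylation in the treated condition).
#' @param donor_sd sd of donor offsets on the M scale (default 0.5).
#' @param noise_sd sd of per-sample noise on the M scale (default 0.3).
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @return List with `beta` (probes x samples matrix), `sheet` (sample,
#'   condition, donor), `truth` (tibble `probe`, `true_delta_beta` for
#'   planted probes) and `params`.
#' @export
simulate_methylome <- function(n_probes = 20000, n_dmp = 300, n_donors = 3,
                               conditions = c("untreated", "LPS"),
                               delta_beta = -0.3, donor_sd = 0.5,
                               noise_sd = 0.3, seed = 1) {
  check_number(n_probes, "n_probes", lower = 10)
  check_number(n_dmp, "n_dmp", lower = 0, upper = n_probes - 1)
  check_number(n_donors, "n_donors", lower = 2)
  if (length(conditions) != 2L) abort("`conditions` must have length 2.")
  check_number(delta_beta, "delta_beta", lower = -0.95, upper = 0.95)
  withr::with_seed(seed, {
    probes <- sprintf("cg%08d", seq_len(n_probes))
    sheet <- tibble(
      sample = as.vector(outer(seq_len(n_donors), conditions,
                               function(d, cc) paste0("D", d, "_", cc))),
      condition = rep(conditions, each = n_donors),
      donor = rep(paste0("D", seq_len(n_donors)), 2)
    )
    comp <- runif(n_probes) < 0.55
    m_ref <- rnorm(n_probes, mean = ifelse(comp, -2.5, 2.5), sd = 1)
    m_trt <- m_ref
    planted <- sort(sample.int(n_probes, n_dmp))
    if (n_dmp > 0) {
      lo <- max(0.05, 0.05 - delta_beta)
      hi <- min(0.95, 0.95 - delta_beta)
      for (attempt in 1:100) {
        base_beta <- runif(n_dmp, lo, hi)
        if (all(base_beta + delta_beta > 0 & base_beta + delta_beta < 1)) break
        if (attempt == 100) abort("could not place planted probes inside [0, 1].")
      }
      m_ref[planted] <- beta_to_m(base_beta)
      m_trt[planted] <- beta_to_m(base_beta + delta_beta)
    }
    donor_offsets <- matrix(rnorm(n_probes * n_donors, sd = donor_sd),
                            n_probes, n_donors)
    m <- matrix(NA_real_, n_probes, nrow(sheet),
                dimnames = list(probes, sheet$sample))
    for (j in seq_len(nrow(sheet))) {
      d <- match(sheet$donor[j], paste0("D", seq_len(n_donors)))
      mu <- if (sheet$condition[j] == conditions[2]) m_trt else m_ref
      m[, j] <- mu + donor_offsets[, d] + rnorm(n_probes, sd = noise_sd)
    }
    list(
      beta = m_to_beta(m),
      sheet = sheet,
      truth = tibble(probe = probes[planted],
                     true_delta_beta = rep(delta_beta, n_dmp)),
      params = list(n_probes = n_probes, n_dmp = n_dmp, n_donors = n_donors,
                    conditions = conditions, delta_beta = delta_beta,
                    donor_sd = donor_sd, noise_sd = noise_sd, seed = seed)
    )
  })
}

#' Simulate a paired RNA-seq count matrix with planted fold changes
#'
#' Gene means are log-normal; counts are negative-binomial around
#' `mean x sample size factor x donor effect` with gene-level dispersion.
#' Planted genes are multiplied by `2^lfc` in the treated condition, half up
#' and half down (signed truth recorded).
#'
#' @param n_genes number of genes (default 5000).
#' @param n_de number of planted differential genes (default 200).
#' @param lfc absolute planted log2 fold change (default 2).
#' @param dispersion NB dispersion (1/size; default 0.1).
#' @param lib_size_sd sd of log-normal per-sample library-size factors
#'   (default 0.15).
#' @param n_donors donors, one sample per condition each (default 3).
#' @param donor_sd sd of log-normal gene x donor effects (default 0.1).
#' @param conditions `c(reference, treated)`.
#' @param mean_log,sd_log log-normal parameters of gene means (defaults 4,
#'   1.2; median around 55 counts).
#' @param seed RNG seed.
#' @return List with `counts`, `sheet`, `truth` (tibble `gene`, `true_lfc`)
#'   and `params`.
#' @export
simulate_counts <- function(n_genes = 5000, n_de = 200, lfc = 2,
                            dispersion = 0.1, lib_size_sd = 0.15,
                            n_donors = 3, donor_sd = 0.1,
                            conditions = c("untreated", "LPS"),
                            mean_log = 4, sd_log = 1.2, seed = 1) {
  check_number(n_genes, "n_genes", lower = 10)
  check_number(n_de, "n_de", lower = 0, upper = n_genes - 1)
  check_number(dispersion, "dispersion", lower = 1e-9)
  withr::with_seed(seed, {
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    sheet <- tibble(
      sample = as.vector(outer(seq_len(n_donors), conditions,
                               function(d, cc) paste0("D", d, "_", cc))),
      condition = rep(conditions, each = n_donors),
      donor = rep(paste0("D", seq_len(n_donors)), 2)
    )
    base_mean <- rlnorm(n_genes, meanlog = mean_log, sdlog = sd_log)
    planted <- sort(sample.int(n_genes, n_de))
    true_lfc <- rep(c(1, -1), length.out = n_de) * lfc
    sf <- exp(rnorm(nrow(sheet), sd = lib_size_sd))
    donor_eff <- matrix(exp(rnorm(n_genes * n_donors, sd = donor_sd)),
                        n_genes, n_donors)
    counts <- matrix(0L, n_genes, nrow(sheet),
                     dimnames = list(genes, sheet$sample))
    for (j in seq_len(nrow(sheet))) {
      d <- match(sheet$donor[j], paste0("D", seq_len(n_donors)))
      mu <- base_mean * donor_eff[, d] * sf[j]
      if (sheet$condition[j] == conditions[2] && n_de > 0) {
        mu[planted] <- mu[planted] * 2^true_lfc
      }
      counts[, j] <- rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
    list(
      counts = counts,
      sheet = sheet,
      truth = tibble(gene = genes[planted], true_lfc = true_lfc),
      params = list(n_genes = n_genes, n_de = n_de, lfc = lfc,
                    dispersion = dispersion, lib_size_sd = lib_size_sd,
                    n_donors = n_donors, donor_sd = donor_sd,
                    conditions = conditions, seed = seed)
    )
  })
}

#' Simulate a four-condition tolerance re-stimulation table
#'
#' Emulates a log2-expression table of naive and LPS-pre-exposed monocytes
#' before and after LPS re-exposure. Every gene mounts a re-exposure response
#' in the naive arm; non-tolerized genes mount the same response in the
#' pre-exposed arm, while the `n_tolerized` planted genes respond by `effect`
#' log2 units less there (blunted induction). Each reported condition value
#' is the mean of `n_reps` replicate measurements with independent
#' `Normal(0, noise_sd)` noise, emulating a triplicate design; with
#' `noise_sd = 0` planted genes score exactly `effect` and all others exactly
#' 0 under [tolerization_scores()].
#'
#' @param n_genes number of genes (default 5000).
#' @param n_tolerized planted tolerized genes (default 150).
#' @param effect planted tolerization effect, log2 units (default 2).
#' @param noise_sd per-replicate measurement noise sd, log2 units
#'   (default 0.5).
#' @param n_reps replicates averaged per condition (default 3).
#' @param response_sd sd of gene-specific re-exposure responses (default 1).
#' @param seed RNG seed.
#' @return List with `expr` (tibble `gene`, `untreated`, `untreated_re`,
#'   `LPS`, `LPS_re`), `truth` (tibble `gene`, `true_effect`) and `params`.
#' @export
simulate_tolerance_timecourse <- function(n_genes = 5000, n_tolerized = 150,
                                          effect = 2, noise_sd = 0.5,
                                          n_reps = 3, response_sd = 1,
                                          seed = 1) {
  check_number(n_genes, "n_genes", lower = 10)
  check_number(n_tolerized, "n_tolerized", lower = 0, upper = n_genes - 1)
  check_number(n_reps, "n_reps", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  withr::with_seed(seed, {
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    baseline <- rnorm(n_genes, 5, 2)
    response <- rnorm(n_genes, 2, response_sd)
    planted <- sort(sample.int(n_genes, n_tolerized))
    deficit <- numeric(n_genes)
    deficit[planted] <- effect
    meas <- function(mu) {
      if (noise_sd == 0) return(mu)
      rowMeans(matrix(mu + rnorm(n_genes * n_reps, sd = noise_sd),
                      n_genes, n_reps))
    }
    expr <- tibble(
      gene = genes,
      untreated = meas(baseline),
      untreated_re = meas(baseline + response),
      LPS = meas(baseline),
      LPS_re = meas(baseline + response - deficit)
    )
    list(
      expr = expr,
      truth = tibble(gene = genes[planted],
                     true_effect = rep(effect, n_tolerized)),
      params = list(n_genes = n_genes, n_tolerized = n_tolerized,
                    effect = effect, noise_sd = noise_sd, n_reps = n_reps,
                    response_sd = response_sd, seed = seed)
    )
  })
}

#' Built-in sharp interferon-response-like PWM
#'
#' A 9-bp count matrix concentrated on the palindromic-core consensus
#' `TTCCGGGAA` (a GAS-like element of the kind bound by phosphorylated STAT
#' dimers), used as the default planted motif in [simulate_regions()].
#'
#' @param name motif name (default `"STAT_like"`).
#' @return A `pwm` object.
#' @export
stat_like_pwm <- function(name = "STAT_like") {
  consensus <- c("T", "T", "C", "C", "G", "G", "G", "A", "A")
  counts <- matrix(0, 4, length(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 100
  new_pwm(name, counts)
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Simulate a contig with CpGs, motifs, peaks and TSSs
#'
#' Generates an i.i.d. uniform nucleotide contig, places target and
#' background CpGs with a minimum spacing (so ±`flank` motif windows do not
#' overlap between CpGs), plants the motif consensus (random strand) within
#' ±`flank` of target CpGs at rate `motif_rate_target` and of background
#' CpGs at rate `motif_rate_background`, centers one peak of half-width
#' `peak_halfwidth` near each target CpG, labels CpGs with genomic-feature
#' and CpG-island-context categories whose distributions differ between
#' targets and background, and scatters stranded TSSs.
#'
#' @param n_target_cpgs,n_background_cpgs CpG counts (defaults 200, 2000).
#' @param contig_length contig size in bp (default 5e6).
#' @param motif `pwm` whose consensus is planted (default [stat_like_pwm()]).
#' @param motif_rate_target,motif_rate_background planting probabilities per
#'   window (defaults 0.6, 0.05).
#' @param peak_halfwidth peak half-width in bp (default 100).
#' @param peak_jitter sd of the peak-center offset from the CpG (default 20).
#' @param flank window half-width used for planting (default 250).
#' @param n_tss number of TSSs (default 100).
#' @param seed RNG seed.
#' @return List with `seqs` (named character), `cpgs` (tibble `name`,
#'   `chrom`, `pos`, `group`, `genomic_feature`, `island_context`), `peaks`
#'   and `tss` interval tibbles, `pwm`, `truth` (planted motif-carrying CpG
#'   ids and peak-proximal CpG ids) and `params`.
#' @export
simulate_regions <- function(n_target_cpgs = 200, n_background_cpgs = 2000,
                             contig_length = 5e6, motif = stat_like_pwm(),
                             motif_rate_target = 0.6,
                             motif_rate_background = 0.05,
                             peak_halfwidth = 100, peak_jitter = 20,
                             flank = 250, n_tss = 100, seed = 1) {
  n_cpgs <- n_target_cpgs + n_background_cpgs
  spacing <- 2 * flank + ncol(motif$counts) + 10
  if (n_cpgs * spacing > contig_length - 2 * spacing) {
    abort("contig too short for the requested CpG count; increase contig_length.")
  }
  withr::with_seed(seed, {
    base <- sample(c("A", "C", "G", "T"), contig_length, replace = TRUE)
    # spaced CpG positions: jittered grid keeps windows disjoint
    slots <- floor((contig_length - 2 * spacing) / spacing)
    chosen <- sort(sample.int(slots, n_cpgs))
    pos <- spacing + (chosen - 1L) * spacing +
      sample.int(max(1L, spacing - 2L * flank - 20L), n_cpgs, replace = TRUE)
    grp_idx <- sample.int(n_cpgs, n_target_cpgs)
    group <- rep("background", n_cpgs)
    group[grp_idx] <- "target"
    name <- sprintf("cg%06d", seq_len(n_cpgs))
    L <- ncol(motif$counts)
    consensus <- paste(rownames(motif$counts)[apply(motif$counts, 2, which.max)],
                       collapse = "")
    rate <- ifelse(group == "target", motif_rate_target, motif_rate_background)
    has_motif <- runif(n_cpgs) < rate
    for (i in which(has_motif)) {
      at <- pos[i] + sample(seq(-flank, flank - L), 1)
      mer <- if (runif(1) < 0.5) consensus else revcomp(consensus)
      base[(at + 1):(at + L)] <- strsplit(mer, "")[[1]]
    }
    seqs <- setNames(paste(base, collapse = ""), "chr1")
    targets <- which(group == "target")
    centers <- pos[targets] + round(rnorm(n_target_cpgs, sd = peak_jitter))
    peaks <- genomic_intervals(
      "chr1",
      pmax(0, centers - peak_halfwidth),
      centers + peak_halfwidth + 1,
      name = sprintf("peak%04d", seq_len(n_target_cpgs))
    )
    feat_levels <- c("promoter", "exon", "intron", "intergenic")
    isl_levels <- c("island", "shore", "open_sea")
    feature <- ifelse(group == "target",
                      sample(feat_levels, n_cpgs, TRUE, prob = c(0.10, 0.10, 0.35, 0.45)),
                      sample(feat_levels, n_cpgs, TRUE, prob = c(0.30, 0.20, 0.25, 0.25)))
    island <- ifelse(group == "target",
                     sample(isl_levels, n_cpgs, TRUE, prob = c(0.10, 0.20, 0.70)),
                     sample(isl_levels, n_cpgs, TRUE, prob = c(0.35, 0.25, 0.40)))
    cpgs <- tibble(name = name, chrom = "chr1", pos = as.integer(pos),
                   group = group, genomic_feature = feature,
                   island_context = island)
    tss <- tibble(
      chrom = "chr1",
      pos = sort(sample.int(contig_length - 1L, n_tss)),
      strand = sample(c("+", "-"), n_tss, replace = TRUE),
      gene = sprintf("GENE%04d", seq_len(n_tss))
    )
    list(
      seqs = seqs, cpgs = cpgs, peaks = peaks, tss = tss, pwm = motif,
      truth = list(motif_cpgs = name[has_motif],
                   peak_cpgs = name[targets]),
      params = list(n_target_cpgs = n_target_cpgs,
                    n_background_cpgs = n_background_cpgs,
                    contig_length = contig_length,
                    motif_rate_target = motif_rate_target,
                    motif_rate_background = motif_rate_background,
                    peak_halfwidth = peak_halfwidth, peak_jitter = peak_jitter,
                    flank = flank, n_tss = n_tss, seed = seed)
    )
  })
}

#' Write a simulated region set to standard files
#'
#' Emits FASTA (contig), TSV (CpG annotation), and BED (peaks, TSS) files so
#' the simulated fixture can round-trip through the package's parsers.
#'
#' @param sim output of [simulate_regions()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_region_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "contig.fa"),
    cpgs = file.path(dir, "cpgs.tsv"),
    peaks = file.path(dir, "peaks.bed"),
    tss = file.path(dir, "tss.bed")
  )
  write_fasta(sim$seqs, paths["fasta"])
  utils::write.table(sim$cpgs, paths["cpgs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed(sim$peaks, paths["peaks"])
  write_bed(genomic_intervals(sim$tss$chrom, sim$tss$pos, sim$tss$pos + 1L,
                              name = sim$tss$gene, strand = sim$tss$strand),
            paths["tss"])
  paths
}

#' Simulate every input of the pipeline from one seed
#'
#' Convenience wrapper deriving one sub-stream seed per generator from a
#' single master seed, so a whole study fixture is reproduced by one number.
#'
#' @param seed master seed.
#' @param ... currently unused.
#' @return List with `methylome`, `counts`, `timecourse` and `regions`
#'   elements (each as returned by its generator).
#' @export
simulate_study <- function(seed = 1, ...) {
  sub <- (as.integer(seed) + c(101L, 202L, 303L, 404L)) %% .Machine$integer.max
  list(
    methylome = simulate_methylome(seed = sub[1]),
    counts = simulate_counts(seed = sub[2]),
    timecourse = simulate_tolerance_timecourse(seed = sub[3]),
    regions = simulate_regions(seed = sub[4])
  )
}
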