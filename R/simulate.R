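#' Synthetic-cohort generator configuration
#'
#' Builds the configuration for the synthetic medulloblastoma cohort
#' generator. Defaults emulate the statistical structure of a
#' methylation-profiled childhood cohort: seven subgroups at the discovery
#' proportions of a 409-patient classified cohort, beta-value block
#' ("metagene") structure with low-risk subgroups marked by shared
#' hypermethylated blocks, subgroup-specific log-normal age distributions
#' whose SHH infant/child mixture densities cross at 4.3 years, subgroup
#' covariate frequencies (for example isochromosome 17q in 76% of high-risk
#' group 4), and four-tier 5-year progression-free survival anchors of
#' 0.91 / 0.81 / 0.42 / 0.28.
#'
#' @param n_samples Number of patients per cohort (default 428).
#' @param n_probes Number of CpG probes (default 2000).
#' @param subgroup_proportions Named non-negative weights over the seven
#'   subgroups, summing to 1.
#' @param block_fraction Fraction of probes in each of the six signature
#'   blocks (default 0.05).
#' @param beta_high,beta_low,beta_background Beta-value means for signature
#'   blocks in carrier / non-carrier subgroups and for background probes.
#' @param concentration Beta-distribution concentration (shape1 + shape2);
#'   larger is less noisy (default 30).
#' @param age_params Named list of `c(meanlog, sdlog)` per subgroup
#'   (log-years).
#' @param covariate_freqs Named list of per-subgroup frequencies for each
#'   clinical flag; see `default_covariate_freqs()`.
#' @param survival_s5 Named 5-year progression-free survival probabilities
#'   per risk tier; `other` applies to patients outside the risk-stratified
#'   survival cohort (infants, non-irradiated, unassignable).
#' @param censor_rate Exponential random-censoring rate per year
#'   (default 0.02); administrative censoring is applied at 10 years.
#' @param os_lag_mean Mean (years) of the exponential lag added to
#'   progression times to produce overall-survival times (default 1).
#'
#' @return An object of class `mb_sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 428,
                       n_probes = 2000,
                       subgroup_proportions = default_subgroup_proportions(),
                       block_fraction = 0.05,
                       beta_high = 0.8,
                       beta_low = 0.2,
                       beta_background = 0.5,
                       concentration = 30,
                       age_params = default_age_params(),
                       covariate_freqs = default_covariate_freqs(),
                       survival_s5 = c(favourable = 0.91, standard = 0.81,
                                       high = 0.42, very_high = 0.28,
                                       other = 0.65),
                       censor_rate = 0.02,
                       os_lag_mean = 1) {
  cfg <- list(n_samples = n_samples, n_probes = n_probes,
              subgroup_proportions = subgroup_proportions,
              block_fraction = block_fraction, beta_high = beta_high,
              beta_low = beta_low, beta_background = beta_background,
              concentration = concentration, age_params = age_params,
              covariate_freqs = covariate_freqs, survival_s5 = survival_s5,
              censor_rate = censor_rate, os_lag_mean = os_lag_mean)
  class(cfg) <- "mb_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  p <- cfg$subgroup_proportions
  if (!setequal(names(p), mb_subgroup7_levels())) {
    stop("subgroup_proportions must be named by the seven subgroups")
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("subgroup_proportions must be non-negative and sum to 1")
  }
  for (m in c(cfg$beta_high, cfg$beta_low, cfg$beta_background)) {
    if (m <= 0 || m >= 1) stop("beta means must lie in (0, 1)")
  }
  if (cfg$block_fraction <= 0 || cfg$block_fraction * 6 > 1) {
    stop("block_fraction must be in (0, 1/6]")
  }
  if (any(cfg$survival_s5 <= 0) || any(cfg$survival_s5 > 1)) {
    stop("survival_s5 values must lie in (0, 1]")
  }
  if (cfg$n_samples < 1 || cfg$n_probes < 120) {
    stop("need n_samples >= 1 and n_probes >= 120")
  }
  invisible(cfg)
}

#' @export
print.mb_sim_config <- function(x, ...) {
  cat(sprintf("mb_sim_config: %d samples x %d probes, 7 subgroups\n",
              x$n_samples, x$n_probes))
  invisible(x)
}

#' Default seven-subgroup proportions
#'
#' Discovery-cohort composition over 409 classified patients:
#' 33 WNT, 65 SHH-Infant, 38 SHH-Child, 50 Grp3-LR, 65 Grp3-HR,
#' 73 Grp4-LR, 85 Grp4-HR.
#' @return Named numeric vector summing to 1.
#' @export
default_subgroup_proportions <- function() {
  counts <- c("MB_WNT" = 33, "MB_SHH-Infant" = 65, "MB_SHH-Child" = 38,
              "MB_Grp3-LR" = 50, "MB_Grp3-HR" = 65,
              "MB_Grp4-LR" = 73, "MB_Grp4-HR" = 85)
  counts / sum(counts)
}

#' Default per-subgroup log-normal age parameters
#'
#' Infant SHH is centred at a median of 1.5 years (sdlog 0.5); the child SHH
#' location is calibrated so that the proportion-weighted infant and child
#' densities intersect at 4.3 years (giving a child median of 8.7 years,
#' sdlog 0.35). Group 3 is younger than group 4.
#'
#' @return Named list of `c(meanlog, sdlog)` vectors.
#' @export
default_age_params <- function() {
  list("MB_WNT"        = c(meanlog = log(9),    sdlog = 0.35),
       "MB_SHH-Infant" = c(meanlog = log(1.5),  sdlog = 0.50),
       "MB_SHH-Child"  = c(meanlog = 2.165255,  sdlog = 0.35),
       "MB_Grp3-LR"    = c(meanlog = log(5),    sdlog = 0.55),
       "MB_Grp3-HR"    = c(meanlog = log(4.5),  sdlog = 0.60),
       "MB_Grp4-LR"    = c(meanlog = log(8.5),  sdlog = 0.40),
       "MB_Grp4-HR"    = c(meanlog = log(8),    sdlog = 0.40))
}

#' Default per-subgroup clinical covariate frequencies
#'
#' Frequencies reflect the published subgroup portraits: CTNNB1 mutation and
#' chromosome 6 loss mark WNT; desmoplastic pathology marks infant SHH; TP53
#' and TERT mutations, MYCN amplification and chromosome 9q loss mark
#' childhood SHH; MYC amplification and LCA pathology mark high-risk group 3;
#' i17q (frequency 0.76) marks high-risk group 4; chromosome 11 loss and 17
#' gain mark low-risk group 4.
#'
#' @return Named list; each element is a frequency vector over the seven
#'   subgroups (order of [mb_subgroup7_levels()]), except `pathology`, a
#'   4 x 7 probability matrix over classic / DN-MBEN / LCA / NOS.
#' @export
default_covariate_freqs <- function() {
  sg <- mb_subgroup7_levels()
  v <- function(...) stats::setNames(c(...), sg)
  pathology <- matrix(
    #        WNT  SHH-I SHH-C G3LR  G3HR  G4LR  G4HR
    c(0.85, 0.30, 0.44, 0.80, 0.55, 0.85, 0.80,   # classic
      0.02, 0.60, 0.27, 0.05, 0.03, 0.03, 0.02,   # DN/MBEN
      0.05, 0.05, 0.25, 0.10, 0.35, 0.07, 0.12,   # LCA
      0.08, 0.05, 0.04, 0.05, 0.07, 0.05, 0.06),  # NOS
    nrow = 4, byrow = TRUE,
    dimnames = list(c("classic", "DN/MBEN", "LCA", "NOS"), sg))
  list(
    male       = v(0.50, 0.60, 0.58, 0.65, 0.65, 0.73, 0.73),
    m_plus     = v(0.10, 0.20, 0.15, 0.25, 0.32, 0.22, 0.40),
    r_plus     = v(0.25, 0.25, 0.16, 0.25, 0.25, 0.25, 0.25),
    myc_amp    = v(0.01, 0.01, 0.01, 0.04, 0.25, 0.01, 0.02),
    mycn_amp   = v(0.02, 0.05, 0.25, 0.02, 0.03, 0.05, 0.05),
    tp53_mut   = v(0.05, 0.02, 0.27, 0.01, 0.01, 0.01, 0.01),
    tert_mut   = v(0.02, 0.02, 0.35, 0.01, 0.01, 0.01, 0.01),
    ctnnb1_mut = v(0.90, 0.01, 0.01, 0.00, 0.00, 0.00, 0.00),
    chr6_loss  = v(0.85, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02),
    i17q       = v(0.02, 0.02, 0.02, 0.10, 0.30, 0.20, 0.76),
    chr13_loss = v(0.02, 0.02, 0.02, 0.15, 0.05, 0.15, 0.05),
    chr7q_gain = v(0.02, 0.02, 0.05, 0.05, 0.10, 0.30, 0.50),
    chr11_loss = v(0.02, 0.02, 0.02, 0.02, 0.02, 0.25, 0.05),
    chr17_gain = v(0.02, 0.02, 0.02, 0.05, 0.05, 0.20, 0.10),
    chr9q_loss = v(0.02, 0.05, 0.51, 0.02, 0.02, 0.02, 0.02),
    pathology  = pathology)
}

#' Signature-block membership of the six simulated metagenes
#'
#' Six probe blocks define the seven subgroups: a WNT block; a pan-SHH block;
#' a child-SHH-specific block (the V4 analogue); group-3 and group-4 blocks;
#' and a block shared by the two low-risk group-3/4 subgroups (the V1
#' analogue, hypermethylated in low-risk disease).
#'
#' @return 6 x 7 logical matrix (blocks x subgroups).
#' @export
sim_block_membership <- function() {
  sg <- mb_subgroup7_levels()
  m <- matrix(FALSE, 6, 7, dimnames = list(paste0("V", 1:6), sg))
  m["V1", c("MB_Grp3-LR", "MB_Grp4-LR")] <- TRUE      # shared low-risk
  m["V2", "MB_WNT"] <- TRUE
  m["V3", c("MB_SHH-Infant", "MB_SHH-Child")] <- TRUE # pan-SHH
  m["V4", "MB_SHH-Child"] <- TRUE                     # child-SHH specific
  m["V5", c("MB_Grp3-LR", "MB_Grp3-HR")] <- TRUE
  m["V6", c("MB_Grp4-LR", "MB_Grp4-HR")] <- TRUE
  m
}

#' Simulate a beta-value matrix with metagene block structure
#'
#' Draws subgroup labels from the configured proportions, then draws each
#' beta value from a Beta distribution whose mean is the block-specific mean
#' for that sample's subgroup (high in carrier subgroups, low otherwise,
#' background elsewhere) at the configured concentration.
#'
#' @param cfg An [sim_config()] object.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @param id_prefix Prefix for generated sample identifiers.
#'
#' @return A list with `matrix` (a [probe_matrix]) and `truth`, a list
#'   holding `subgroup7` (named character), `block_scores` (6 x n matrix of
#'   true block mean levels per sample) and `blocks` (probe-block index).
#' @export
simulate_methylome <- function(cfg, seed = NULL, id_prefix = "S") {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_samples
  p <- cfg$n_probes
  sg <- mb_subgroup7_levels()
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  labels <- sample(sg, n, replace = TRUE, prob = cfg$subgroup_proportions)
  names(labels) <- ids

  member <- sim_block_membership()
  bsize <- max(1L, floor(cfg$block_fraction * p))
  blocks <- rep(0L, p)  # 0 = background
  for (b in 1:6) blocks[((b - 1) * bsize + 1):(b * bsize)] <- b

  # probe-by-sample matrix of Beta means
  mean_bs <- ifelse(member, cfg$beta_high, cfg$beta_low)  # 6 x 7
  mu <- matrix(cfg$beta_background, p, n)
  sig <- blocks > 0
  mu[sig, ] <- mean_bs[blocks[sig], match(labels, sg)]

  conc <- cfg$concentration
  vals <- matrix(stats::rbeta(p * n, mu * conc, (1 - mu) * conc), p, n,
                 dimnames = list(sprintf("cg%05d", seq_len(p)), ids))
  scores <- mean_bs[, match(labels, sg), drop = FALSE]
  colnames(scores) <- ids
  list(matrix = probe_matrix(vals),
       truth = list(subgroup7 = labels, block_scores = scores,
                    blocks = blocks))
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lower = 0.05, upper = 18) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * (n - length(out)) + 8, meanlog, sdlog)
    out <- c(out, x[x > lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Simulate clinical records for a labelled cohort
#'
#' Ages are drawn from subgroup-specific log-normal distributions (truncated
#' to (0.05, 18\] years); sex, metastatic stage, resection status, pathology
#' and the molecular / cytogenetic flags are drawn independently at the
#' per-subgroup frequencies in `cfg$covariate_freqs`. Craniospinal
#' irradiation is assigned to patients aged 3 or older (infants are treated
#' on radiotherapy-sparing protocols).
#'
#' @param cfg An [sim_config()] object.
#' @param truth Truth list from [simulate_methylome()] (needs `subgroup7`).
#' @param seed Optional integer seed.
#' @return A clinical `data.frame` (see [clinical-table]) without survival
#'   columns.
#' @export
simulate_clinical <- function(cfg, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- truth$subgroup7
  n <- length(labels)
  fq <- cfg$covariate_freqs
  draw <- function(freqs) stats::runif(n) < freqs[labels]
  ap <- cfg$age_params
  age <- numeric(n)
  for (g in unique(labels)) {
    i <- labels == g
    age[i] <- rtrunc_lnorm(sum(i), ap[[g]]["meanlog"], ap[[g]]["sdlog"])
  }
  pathology <- vapply(labels, function(g) {
    sample(rownames(fq$pathology), 1L, prob = fq$pathology[, g])
  }, character(1))
  clin <- data.frame(
    sample_id = names(labels),
    age_at_diagnosis = age,
    sex = ifelse(draw(fq$male), "male", "female"),
    m_stage = ifelse(draw(fq$m_plus), "M+", "M-"),
    resection = ifelse(draw(fq$r_plus), "R+", "R-"),
    pathology = unname(pathology),
    myc_amp = draw(fq$myc_amp), mycn_amp = draw(fq$mycn_amp),
    tp53_mut = draw(fq$tp53_mut), tert_mut = draw(fq$tert_mut),
    ctnnb1_mut = draw(fq$ctnnb1_mut), chr6_loss = draw(fq$chr6_loss),
    i17q = draw(fq$i17q), chr13_loss = draw(fq$chr13_loss),
    chr7q_gain = draw(fq$chr7q_gain), chr11_loss = draw(fq$chr11_loss),
    chr17_gain = draw(fq$chr17_gain), chr9q_loss = draw(fq$chr9q_loss),
    csi_treated = age >= 3,
    subgroup7 = unname(labels),
    subgroup4 = subgroup7_to_subgroup4(unname(labels)),
    stringsAsFactors = FALSE, row.names = NULL)
  validate_clinical(clin)
  clin
}

#' Simulate progression-free and overall survival
#'
#' Progression-free survival times are exponential with rate
#' `-log(S5) / 5` for the risk tier recorded in `truth$risk_group`, so the
#' true 5-year survival equals the configured anchor. Independent
#' exponential censoring at `cfg$censor_rate` per year and administrative
#' right-censoring at 10 years are applied. Overall survival adds an
#' exponential lag to progression times for event cases.
#'
#' @param cfg An [sim_config()] object.
#' @param truth Truth list carrying `risk_group`, a character vector named by
#'   sample identifier with values in
#'   \{favourable, standard, high, very_high, unassignable, excluded\}.
#' @param clin Clinical `data.frame` to update.
#' @param seed Optional integer seed.
#' @return `clin` with `time_pfs`, `event_pfs`, `time_os`, `event_os` added.
#' @export
simulate_survival <- function(cfg, truth, clin, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  risk <- truth$risk_group[clin$sample_id]
  if (any(is.na(risk))) stop("truth$risk_group must cover every sample")
  s5 <- cfg$survival_s5
  tier <- ifelse(risk %in% names(s5), risk, "other")
  if (any(s5 <= 0)) stop("survival_s5 of 0 implies an infinite hazard")
  lambda <- -log(s5[tier]) / 5
  n <- nrow(clin)
  t_event <- ifelse(lambda > 0, stats::rexp(n, pmax(lambda, 1e-12)), Inf)
  t_cens <- if (cfg$censor_rate > 0) stats::rexp(n, cfg$censor_rate) else
    rep(Inf, n)
  t_cens <- pmin(t_cens, 10)  # administrative right-censoring at 10 years
  clin$time_pfs <- pmin(t_event, t_cens)
  clin$event_pfs <- t_event <= t_cens
  lag <- stats::rexp(n, 1 / cfg$os_lag_mean)
  t_death <- ifelse(clin$event_pfs, clin$time_pfs + lag, Inf)
  clin$time_os <- pmin(t_death, t_cens, 10)
  clin$event_os <- t_death <= pmin(t_cens, 10)
  validate_clinical(clin)
  clin
}

#' Simulate a complete cohort
#'
#' Runs [simulate_methylome()], [simulate_clinical()], assigns ground-truth
#' risk tiers by applying the overall four-tier stratification rules
#' ([stratify_overall()]) to the true covariates, and then draws survival
#' with [simulate_survival()].
#'
#' @param cfg An [sim_config()] object.
#' @param seed Optional integer seed controlling the whole cohort.
#' @param name Cohort name (also the sample-identifier prefix).
#' @return A list of class `mb_cohort` with elements `name`, `matrix`,
#'   `clinical` and `truth` (which gains `risk_group`).
#' @export
simulate_cohort <- function(cfg, seed = NULL, name = "discovery") {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 3)
  meth <- simulate_methylome(cfg, seed = seeds[1],
                             id_prefix = toupper(substr(name, 1, 1)))
  clin <- simulate_clinical(cfg, meth$truth, seed = seeds[2])
  risk <- stratify_overall(clin, variant = "base")
  meth$truth$risk_group <- stats::setNames(risk, clin$sample_id)
  clin <- simulate_survival(cfg, meth$truth, clin, seed = seeds[3])
  structure(list(name = name, matrix = meth$matrix, clinical = clin,
                 truth = meth$truth),
            class = "mb_cohort")
}

#' @export
print.mb_cohort <- function(x, ...) {
  cat(sprintf("mb_cohort '%s': %d samples, %d probes\n",
              x$name, ncol(x$matrix), nrow(x$matrix)))
  print(table(x$truth$subgroup7))
  invisible(x)
}

#' Simulate an independent discovery / validation cohort pair
#'
#' Two independent draws from the same generative model with disjoint sample
#' identifiers and a shared probe set, for exercising cross-cohort metagene
#' projection.
#'
#' @param cfg An [sim_config()] object.
#' @param seed Optional integer seed.
#' @return List with `discovery` and `validation` cohorts.
#' @export
simulate_cohort_pair <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 2)
  list(discovery = simulate_cohort(cfg, seed = seeds[1], name = "discovery"),
       validation = simulate_cohort(cfg, seed = seeds[2], name = "validation"))
}
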