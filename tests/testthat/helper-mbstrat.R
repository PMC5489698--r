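# shared fixtures and independent oracles

# adjusted Rand index, direct from the pair-counting formula
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# two-sided Fisher p by full hypergeometric enumeration over fixed margins
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tiny beta matrix with two clean probe blocks separating two sample groups
two_block_matrix <- function(n_per = 10, p_per = 30, seed = 1,
                             noise = 0.02) {
  set.seed(seed)
  n <- 2 * n_per
  p <- 2 * p_per
  mu <- matrix(0.1, p, n)
  mu[1:p_per, 1:n_per] <- 0.9
  mu[(p_per + 1):p, (n_per + 1):n] <- 0.9
  vals <- pmin(pmax(mu + stats::rnorm(p * n, 0, noise), 0), 1)
  dimnames(vals) <- list(sprintf("cg%03d", 1:p), sprintf("s%03d", 1:n))
  probe_matrix(vals)
}

# config for a small 4-subgroup (4-block) cohort: only subgroups whose
# signatures are single, disjoint blocks get positive weight
four_block_config <- function(n_samples = 100, n_probes = 500) {
  p4 <- stats::setNames(rep(0, 7), mb_subgroup7_levels())
  p4[c("MB_WNT", "MB_SHH-Infant", "MB_Grp3-HR", "MB_Grp4-HR")] <- 0.25
  sim_config(n_samples = n_samples, n_probes = n_probes,
             subgroup_proportions = p4)
}

# minimal clinical data frame for stratification tests; every flag known
# FALSE, M-/R-, classic pathology, eligible age and CSI unless overridden
make_record <- function(..., n = 1) {
  base <- data.frame(
    sample_id = sprintf("P%03d", seq_len(n)),
    age_at_diagnosis = 8, sex = "male", m_stage = "M-", resection = "R-",
    pathology = "classic", myc_amp = FALSE, mycn_amp = FALSE,
    tp53_mut = FALSE, tert_mut = FALSE, ctnnb1_mut = FALSE,
    chr6_loss = FALSE, i17q = FALSE, chr13_loss = FALSE,
    chr7q_gain = FALSE, chr11_loss = FALSE, chr17_gain = FALSE,
    chr9q_loss = FALSE, csi_treated = TRUE,
    subgroup7 = "MB_Grp4-LR", stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base$subgroup4 <- subgroup7_to_subgroup4(base$subgroup7)
  base
}

# exponential survival data with a binary covariate of true log-hazard beta
sim_exp_survival <- function(n, beta = 0, base_rate = 0.2,
                             censor_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  t_event <- stats::rexp(n, base_rate * exp(beta * x))
  t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else Inf
  data.frame(time = pmin(t_event, t_cens), event = t_event <= t_cens, x = x)
}
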