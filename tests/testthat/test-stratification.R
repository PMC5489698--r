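test_that("childhood-SHH scheme grades by the four high-risk features", {
  base <- make_record(subgroup7 = "MB_SHH-Child", age_at_diagnosis = 10)
  expect_equal(unname(stratify_shh_child(base)), "favourable")
  expect_equal(unname(stratify_shh_child(
    make_record(subgroup7 = "MB_SHH-Child", mycn_amp = TRUE))), "very_high")
  expect_equal(unname(stratify_shh_child(
    make_record(subgroup7 = "MB_SHH-Child", pathology = "LCA"))), "very_high")
  expect_equal(unname(stratify_shh_child(
    make_record(subgroup7 = "MB_SHH-Child", m_stage = NA))), "excluded")
  # a known positive dominates other unknowns
  expect_equal(unname(stratify_shh_child(
    make_record(subgroup7 = "MB_SHH-Child", m_stage = "M+",
                resection = NA))), "very_high")
  expect_error(stratify_shh_child(make_record(subgroup7 = "MB_Grp4-LR")),
               "domain")
})

test_that("combined group 3/4 scheme applies rules in printed order", {
  expect_equal(unname(stratify_grp34_combined(
    make_record(subgroup7 = "MB_Grp3-HR", myc_amp = TRUE))), "very_high")
  expect_equal(unname(stratify_grp34_combined(
    make_record(subgroup7 = "MB_Grp4-LR", chr13_loss = TRUE))), "favourable")
  # chromosome 13 loss takes precedence over the HR/LR split
  expect_equal(unname(stratify_grp34_combined(
    make_record(subgroup7 = "MB_Grp3-HR", chr13_loss = TRUE))), "favourable")
  expect_equal(unname(stratify_grp34_combined(
    make_record(subgroup7 = "MB_Grp4-LR"))), "standard")
  expect_equal(unname(stratify_grp34_combined(
    make_record(subgroup7 = "MB_Grp4-HR"))), "high")
  # MYC-amplified group 4 cannot be graded
  expect_equal(unname(stratify_grp34_combined(
    make_record(subgroup7 = "MB_Grp4-LR", myc_amp = TRUE))), "unassignable")
  # missing rule features exclude the record
  expect_equal(unname(stratify_grp34_combined(
    make_record(subgroup7 = "MB_Grp3-LR", myc_amp = NA))), "excluded")
  expect_equal(unname(stratify_grp34_combined(
    make_record(subgroup7 = "MB_Grp3-LR", chr13_loss = NA))), "excluded")
})

test_that("overall scheme combines subgroup rules and eligibility", {
  expect_equal(unname(stratify_overall(
    make_record(subgroup7 = "MB_WNT"))), "favourable")
  expect_equal(unname(stratify_overall(
    make_record(subgroup7 = "MB_SHH-Infant", age_at_diagnosis = 2,
                csi_treated = FALSE))), "excluded")
  expect_equal(unname(stratify_overall(
    make_record(subgroup7 = "MB_Grp4-HR"))), "high")
  expect_equal(unname(stratify_overall(
    make_record(subgroup7 = "MB_SHH-Child", tp53_mut = TRUE))), "favourable")
  expect_equal(unname(stratify_overall(
    make_record(subgroup7 = "MB_SHH-Child", m_stage = "M+"))), "very_high")
  expect_equal(unname(stratify_overall(make_record(subgroup7 = "NC"))),
               "unassignable")
  # age / irradiation eligibility window
  expect_equal(unname(stratify_overall(
    make_record(subgroup7 = "MB_WNT", age_at_diagnosis = 2.5,
                csi_treated = FALSE))), "excluded")
  expect_equal(unname(stratify_overall(
    make_record(subgroup7 = "MB_WNT", csi_treated = FALSE))), "excluded")
})

test_that("overall base scheme restricted to group 3/4 equals the combined scheme", {
  cfg <- sim_config(n_samples = 800, n_probes = 120)
  meth <- simulate_methylome(cfg, seed = 52)
  clin <- simulate_clinical(cfg, meth$truth, seed = 53)
  g34 <- clin[clin$subgroup7 %in% c("MB_Grp3-LR", "MB_Grp3-HR",
                                    "MB_Grp4-LR", "MB_Grp4-HR") &
                clin$csi_treated & clin$age_at_diagnosis >= 3 &
                clin$age_at_diagnosis <= 16, ]
  expect_equal(stratify_overall(g34, "base"), stratify_grp34_combined(g34))
})

test_that("M+ redistribution empties the standard tier into favourable/high", {
  lr_mminus <- make_record(subgroup7 = "MB_Grp4-LR", m_stage = "M-")
  lr_mplus <- make_record(subgroup7 = "MB_Grp3-LR", m_stage = "M+")
  expect_equal(unname(stratify_overall(lr_mminus, "base")), "standard")
  expect_equal(unname(stratify_overall(lr_mminus, "mplus_redistribution")),
               "favourable")
  expect_equal(unname(stratify_overall(lr_mplus, "mplus_redistribution")),
               "high")
  # LR without chromosome 13 data but known M- becomes gradable (favourable)
  lr_nochr13 <- make_record(subgroup7 = "MB_Grp4-LR", chr13_loss = NA)
  expect_equal(unname(stratify_overall(lr_nochr13, "base")), "excluded")
  expect_equal(unname(stratify_overall(lr_nochr13, "mplus_redistribution")),
               "favourable")
})

test_that("PNET5 comparator flags any established high-risk feature", {
  expect_equal(unname(stratify_pnet5(make_record(m_stage = "M+"))), "high")
  expect_equal(unname(stratify_pnet5(make_record(mycn_amp = TRUE))), "high")
  expect_equal(unname(stratify_pnet5(make_record())), "standard")
  expect_equal(unname(stratify_pnet5(make_record(resection = NA))),
               "excluded")
})

test_that("cytogenetic comparator follows its printed rule order", {
  g4 <- function(...) make_record(subgroup7 = "MB_Grp4-LR", ...)
  g3 <- function(...) make_record(subgroup7 = "MB_Grp3-HR", ...)
  # low-risk rule precedes the M+ rule
  expect_equal(unname(stratify_cytogenetic(
    g4(chr11_loss = TRUE, m_stage = "M+"))), "favourable")
  expect_equal(unname(stratify_cytogenetic(g4(chr17_gain = TRUE))),
               "favourable")
  expect_equal(unname(stratify_cytogenetic(g4(m_stage = "M+"))), "high")
  expect_equal(unname(stratify_cytogenetic(g4())), "standard")
  expect_equal(unname(stratify_cytogenetic(g3(i17q = TRUE))), "high")
  expect_equal(unname(stratify_cytogenetic(g3(myc_amp = TRUE))), "high")
  expect_equal(unname(stratify_cytogenetic(g3())), "standard")
  expect_equal(unname(stratify_cytogenetic(g3(i17q = NA))), "excluded")
  expect_error(stratify_cytogenetic(make_record(subgroup7 = "MB_WNT")),
               "domain")
})

test_that("group-4-only scheme uses 7q gain and metastatic status", {
  g4 <- function(...) make_record(subgroup7 = "MB_Grp4-HR", ...)
  expect_equal(unname(stratify_grp4_alone(g4(chr7q_gain = TRUE))), "high")
  expect_equal(unname(stratify_grp4_alone(g4(m_stage = "M+"))), "high")
  expect_equal(unname(stratify_grp4_alone(g4())), "standard")
  expect_equal(unname(stratify_grp4_alone(g4(m_stage = NA))), "excluded")
})

test_that("every scheme partitions records into exactly one tier", {
  cfg <- sim_config(n_samples = 500, n_probes = 120)
  coh <- simulate_cohort(cfg, seed = 54)
  for (s in names(mb_risk_schemes())) {
    r <- apply_scheme(coh$clinical, s)
    expect_length(r, nrow(coh$clinical))
    expect_true(all(r %in% risk_levels()))
    expect_false(any(is.na(r)))
  }
})

test_that("scheme comparison favours the generative scheme by AUC", {
  cfg <- sim_config(n_samples = 2500, n_probes = 120)
  coh <- simulate_cohort(cfg, seed = 55)
  cmp <- compare_schemes(coh$clinical, c("overall", "pnet5"), t = 5)
  auc <- stats::setNames(cmp$auc, cmp$scheme)
  expect_gte(auc[["overall"]], auc[["pnet5"]])
  expect_gt(auc[["overall"]], 0.6)
  # a constant risk score carries no discrimination
  d <- data.frame(time = coh$clinical$time_pfs,
                  event = coh$clinical$event_pfs)
  expect_equal(time_dependent_auc(rep(1, nrow(d)), d, t = 5), 0.5)
  # permuted risk labels are uninformative
  set.seed(56)
  r <- apply_scheme(coh$clinical, "overall")
  keep <- r %in% c("favourable", "standard", "high", "very_high")
  ord <- stats::setNames(1:4, c("favourable", "standard", "high",
                                "very_high"))
  perm_auc <- time_dependent_auc(sample(ord[r[keep]]), d[keep, ], t = 5)
  expect_equal(perm_auc, 0.5, tolerance = 0.08)
})
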