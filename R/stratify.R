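#' Risk-tier levels
#'
#' Four clinical risk tiers anchored to 5-year progression-free survival
#' (favourable > 90%, standard 75-90%, high 40-75%, very high < 40%), plus
#' `unassignable` (rule conflict, for example MYC-amplified group 4) and
#' `excluded` (outside the scheme's domain or missing a required feature).
#'
#' @return Character vector of the six tier labels in increasing risk order.
#' @export
risk_levels <- function() {
  c("favourable", "standard", "high", "very_high", "unassignable", "excluded")
}

graded_risk_levels <- function() c("favourable", "standard", "high",
                                   "very_high")

# three-valued helpers: logical vectors with NA = unknown
is_lca <- function(clin) clin$pathology == "LCA"
is_mplus <- function(clin) clin$m_stage == "M+"
is_rplus <- function(clin) clin$resection == "R+"

require_subgroup <- function(clin, allowed, col = "subgroup7") {
  bad <- !(clin[[col]] %in% allowed)
  if (any(bad)) {
    stop("record(s) outside the scheme's subgroup domain: ",
         paste(unique(clin[[col]][bad]), collapse = ", "))
  }
  invisible(clin)
}

#' Risk stratification of childhood SHH medulloblastoma
#'
#' Any one of MYCN amplification, LCA pathology, metastatic (M+) or
#' residual (R+) disease makes a childhood-SHH patient very high risk; a
#' patient with all four features known absent is favourable. Records with
#' any of the four features unknown (and none positive) are excluded.
#'
#' @param clin Clinical `data.frame` ([clinical-table]) of MB_SHH-Child
#'   records only.
#' @return Character vector of [risk_levels()] values, named by sample.
#' @export
stratify_shh_child <- function(clin) {
  require_subgroup(clin, "MB_SHH-Child")
  any_hr <- clin$mycn_amp | is_lca(clin) | is_mplus(clin) | is_rplus(clin)
  out <- ifelse(is.na(any_hr), "excluded",
                ifelse(any_hr, "very_high", "favourable"))
  stats::setNames(out, clin$sample_id)
}

#' Risk stratification of combined group 3/4 medulloblastoma
#'
#' Four tiers: favourable (chromosome 13 loss, no MYC amplification);
#' very high (MYC-amplified group 3); standard (low-risk subgroup, no MYC
#' amplification, no chromosome 13 loss); high (high-risk subgroup, no MYC
#' amplification, no chromosome 13 loss). MYC-amplified group 4 is
#' unassignable; records missing MYC or (when needed) chromosome 13 status
#' are excluded.
#'
#' @param clin Clinical `data.frame` of MB_Grp3-LR/HR and MB_Grp4-LR/HR
#'   records only.
#' @return Character vector of [risk_levels()] values, named by sample.
#' @export
stratify_grp34_combined <- function(clin) {
  require_subgroup(clin, c("MB_Grp3-LR", "MB_Grp3-HR",
                           "MB_Grp4-LR", "MB_Grp4-HR"))
  grp3 <- clin$subgroup7 %in% c("MB_Grp3-LR", "MB_Grp3-HR")
  lr <- clin$subgroup7 %in% c("MB_Grp3-LR", "MB_Grp4-LR")
  myc <- clin$myc_amp
  chr13 <- clin$chr13_loss
  out <- rep("excluded", nrow(clin))
  known_myc <- !is.na(myc)
  out[known_myc & myc & grp3] <- "very_high"
  out[known_myc & myc & !grp3] <- "unassignable"
  no_myc <- known_myc & !myc
  out[no_myc & !is.na(chr13) & chr13] <- "favourable"
  out[no_myc & !is.na(chr13) & !chr13 & lr] <- "standard"
  out[no_myc & !is.na(chr13) & !chr13 & !lr] <- "high"
  stats::setNames(out, clin$sample_id)
}

#' Overall four-tier risk stratification of childhood medulloblastoma
#'
#' Combines the subgroup-specific models into one scheme for patients aged
#' 3-16 years treated with craniospinal irradiation: WNT is favourable;
#' childhood SHH follows [stratify_shh_child()]; groups 3/4 follow
#' [stratify_grp34_combined()]. Infant SHH and patients outside the age /
#' treatment window are excluded; non-classifiable subgroups are
#' unassignable.
#'
#' The `mplus_redistribution` variant additionally redistributes the
#' standard tier by metastatic status: non-MYC-amplified low-risk group 3/4
#' patients without chromosome 13 loss move to favourable if M- and to high
#' if M+ (patients without chromosome 13 data but known M- also become
#' favourable).
#'
#' @param clin Clinical `data.frame` ([clinical-table]); any subgroups.
#' @param variant "base" (default) or "mplus_redistribution".
#' @return Character vector of [risk_levels()] values, named by sample.
#' @export
stratify_overall <- function(clin,
                             variant = c("base", "mplus_redistribution")) {
  variant <- match.arg(variant)
  n <- nrow(clin)
  out <- rep("excluded", n)
  age <- clin$age_at_diagnosis
  eligible <- !is.na(age) & age >= 3 & age <= 16 &
    !is.na(clin$csi_treated) & clin$csi_treated
  sg <- clin$subgroup7
  nc <- eligible & (is.na(sg) | sg == "NC")
  out[nc] <- "unassignable"
  out[eligible & !is.na(sg) & sg == "MB_WNT"] <- "favourable"
  shh <- eligible & !is.na(sg) & sg == "MB_SHH-Child"
  if (any(shh)) out[shh] <- stratify_shh_child(clin[shh, , drop = FALSE])
  g34 <- eligible & !is.na(sg) &
    sg %in% c("MB_Grp3-LR", "MB_Grp3-HR", "MB_Grp4-LR", "MB_Grp4-HR")
  if (any(g34)) {
    risk34 <- stratify_grp34_combined(clin[g34, , drop = FALSE])
    if (variant == "mplus_redistribution") {
      sub <- clin[g34, , drop = FALSE]
      lr <- sub$subgroup7 %in% c("MB_Grp3-LR", "MB_Grp4-LR")
      no_myc <- !is.na(sub$myc_amp) & !sub$myc_amp
      no_chr13 <- is.na(sub$chr13_loss) | !sub$chr13_loss
      redo <- lr & no_myc & no_chr13
      mp <- is_mplus(sub)
      risk34[redo & !is.na(mp) & !mp] <- "favourable"
      risk34[redo & !is.na(mp) & mp] <- "high"
      risk34[redo & is.na(mp)] <- "excluded"
    }
    out[g34] <- risk34
  }
  stats::setNames(out, clin$sample_id)
}

#' PNET5-style clinical-trial risk stratification
#'
#' Any of LCA pathology, M+ disease, R+ disease, or MYC/MYCN amplification
#' makes a patient high risk; all four known absent is standard risk;
#' otherwise excluded.
#'
#' @param clin Clinical `data.frame`.
#' @return Character vector of [risk_levels()] values, named by sample.
#' @export
stratify_pnet5 <- function(clin) {
  mycn_any <- clin$myc_amp | clin$mycn_amp
  any_hr <- is_lca(clin) | is_mplus(clin) | is_rplus(clin) | mycn_any
  out <- ifelse(is.na(any_hr), "excluded",
                ifelse(any_hr, "high", "standard"))
  stats::setNames(out, clin$sample_id)
}

#' Cytogenetic risk stratification of group 3/4 medulloblastoma
#'
#' Published comparator scheme, rules applied in printed order: group 4 with
#' chromosome 11 loss or chromosome 17 gain is low risk (favourable tier);
#' remaining group 4 is standard (M-) or high (M+); group 3 with MYC
#' amplification, i17q or M+ disease is high risk, otherwise standard.
#' Records whose rule-relevant features are unknown are excluded.
#'
#' @param clin Clinical `data.frame` of group 3/4 records (by `subgroup4`).
#' @return Character vector of [risk_levels()] values, named by sample.
#' @export
stratify_cytogenetic <- function(clin) {
  require_subgroup(clin, c("MB_Grp3", "MB_Grp4"), col = "subgroup4")
  grp4 <- clin$subgroup4 == "MB_Grp4"
  out <- rep("excluded", nrow(clin))
  low <- clin$chr11_loss | clin$chr17_gain
  mp <- is_mplus(clin)
  i4 <- grp4 & !is.na(low) & low
  out[i4] <- "favourable"
  rest4 <- grp4 & !is.na(low) & !low
  out[rest4 & !is.na(mp) & !mp] <- "standard"
  out[rest4 & !is.na(mp) & mp] <- "high"
  hr3 <- clin$myc_amp | clin$i17q | mp
  out[!grp4 & !is.na(hr3) & hr3] <- "high"
  out[!grp4 & !is.na(hr3) & !hr3] <- "standard"
  stats::setNames(out, clin$sample_id)
}

#' Group-4-only risk stratification
#'
#' Chromosome 7q gain or M+ disease defines high risk within group 4;
#' both known absent is standard; otherwise excluded.
#'
#' @param clin Clinical `data.frame` of group 4 records (by `subgroup4`).
#' @return Character vector of [risk_levels()] values, named by sample.
#' @export
stratify_grp4_alone <- function(clin) {
  require_subgroup(clin, "MB_Grp4", col = "subgroup4")
  hr <- clin$chr7q_gain | is_mplus(clin)
  out <- ifelse(is.na(hr), "excluded", ifelse(hr, "high", "standard"))
  stats::setNames(out, clin$sample_id)
}

#' Available risk-stratification schemes
#'
#' Registry mapping scheme names to the stratification function and its
#' subgroup domain. Records outside a scheme's domain are marked excluded
#' when the scheme is applied cohort-wide via [apply_scheme()].
#'
#' @return Named list of scheme descriptors (`fn`, `domain`).
#' @export
mb_risk_schemes <- function() {
  g34_7 <- function(clin) clin$subgroup7 %in%
    c("MB_Grp3-LR", "MB_Grp3-HR", "MB_Grp4-LR", "MB_Grp4-HR")
  g34_4 <- function(clin) clin$subgroup4 %in% c("MB_Grp3", "MB_Grp4")
  list(
    overall = list(fn = function(clin) stratify_overall(clin, "base"),
                   domain = function(clin) rep(TRUE, nrow(clin))),
    overall_mplus = list(
      fn = function(clin) stratify_overall(clin, "mplus_redistribution"),
      domain = function(clin) rep(TRUE, nrow(clin))),
    grp34 = list(fn = stratify_grp34_combined, domain = g34_7),
    pnet5 = list(fn = stratify_pnet5,
                 domain = function(clin) rep(TRUE, nrow(clin))),
    cytogenetic = list(fn = stratify_cytogenetic, domain = g34_4),
    grp4 = list(fn = stratify_grp4_alone,
                domain = function(clin) clin$subgroup4 %in% "MB_Grp4"),
    shh_child = list(fn = stratify_shh_child,
                     domain = function(clin) clin$subgroup7 %in%
                       "MB_SHH-Child"))
}

#' Apply a named risk scheme across a cohort
#'
#' Applies one scheme from [mb_risk_schemes()] to a whole cohort; records
#' outside the scheme's subgroup domain are marked `excluded`.
#'
#' @param clin Clinical `data.frame`.
#' @param scheme Scheme name (see [mb_risk_schemes()]).
#' @return Character vector of [risk_levels()] values, named by sample.
#' @export
apply_scheme <- function(clin, scheme) {
  reg <- mb_risk_schemes()
  if (!scheme %in% names(reg)) {
    stop("unknown scheme '", scheme, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  s <- reg[[scheme]]
  out <- stats::setNames(rep("excluded", nrow(clin)), clin$sample_id)
  dom <- s$domain(clin)
  dom[is.na(dom)] <- FALSE
  if (any(dom)) out[dom] <- s$fn(clin[dom, , drop = FALSE])
  out
}

#' Compare risk schemes by time-dependent AUC
#'
#' Encodes each scheme's graded tiers ordinally (favourable = 1 ...
#' very high = 4; the AUC is invariant to the specific monotone encoding)
#' and evaluates [time_dependent_auc()] of the ordinal risk score for
#' progression-free survival at `t` years. Excluded and unassignable records
#' are dropped per scheme; by default the comparison is restricted to the
#' samples gradable under every scheme (shared complete cases).
#'
#' @param clin Clinical `data.frame` with `time_pfs` and `event_pfs`.
#' @param schemes Character vector of scheme names (see [mb_risk_schemes()]).
#' @param t Evaluation time in years (default 5).
#' @param shared Restrict all schemes to the common gradable samples
#'   (default `TRUE`).
#' @return Data frame with `scheme`, `n`, `auc`.
#' @export
compare_schemes <- function(clin, schemes, t = 5, shared = TRUE) {
  check_survival_pfs(clin)
  risk <- lapply(schemes, function(s) apply_scheme(clin, s))
  names(risk) <- schemes
  gradable <- lapply(risk, function(r) names(r)[r %in% graded_risk_levels()])
  pool <- if (shared) Reduce(intersect, gradable) else NULL
  if (shared && !length(pool)) stop("no sample gradable under every scheme")
  ord <- stats::setNames(1:4, graded_risk_levels())
  rows <- lapply(schemes, function(s) {
    ids <- if (shared) pool else gradable[[s]]
    idx <- match(ids, clin$sample_id)
    d <- data.frame(time = clin$time_pfs[idx], event = clin$event_pfs[idx])
    data.frame(scheme = s, n = length(ids),
               auc = time_dependent_auc(ord[risk[[s]][ids]], d, t = t))
  })
  do.call(rbind, rows)
}

check_survival_pfs <- function(clin) {
  if (!all(c("time_pfs", "event_pfs") %in% names(clin))) {
    stop("clinical table needs time_pfs and event_pfs columns")
  }
  invisible(clin)
}
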