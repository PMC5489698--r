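#' @name clinical-table
#' @title Clinical annotation tables
#'
#' @description
#' Clinical records are held in a plain `data.frame`, one row per patient,
#' with the column schema below. Unknown values are encoded as `NA`
#' throughout; they are never silently imputed, and each downstream analysis
#' documents its own complete-case behaviour.
#'
#' \describe{
#'   \item{sample_id}{character, unique.}
#'   \item{age_at_diagnosis}{years, in \[0, 18\].}
#'   \item{sex}{"male" or "female".}
#'   \item{m_stage}{metastatic stage by Chang criteria: "M+" or "M-".}
#'   \item{resection}{"R+" (residuum > 1.5 cm2) or "R-".}
#'   \item{pathology}{"classic", "DN/MBEN", "LCA" or "NOS".}
#'   \item{myc_amp, mycn_amp, tp53_mut, tert_mut, ctnnb1_mut}{logical gene
#'     amplification/mutation flags.}
#'   \item{chr6_loss, i17q, chr13_loss, chr7q_gain, chr11_loss, chr17_gain,
#'     chr9q_loss}{logical cytogenetic flags.}
#'   \item{csi_treated}{logical; craniospinal irradiation with curative
#'     intent.}
#'   \item{time_pfs, time_os}{follow-up time in years, >= 0.}
#'   \item{event_pfs, event_os}{logical; TRUE = event observed, FALSE =
#'     censored.}
#'   \item{subgroup4}{consensus four-subgroup label: "MB_WNT", "MB_SHH",
#'     "MB_Grp3", "MB_Grp4" or "NC".}
#'   \item{subgroup7}{seven-subgroup label, one of
#'     [mb_subgroup7_levels()] or "NC".}
#' }
NULL

#' Seven-subgroup label set
#'
#' The seven methylation subgroups of childhood medulloblastoma: WNT;
#' age-split SHH (infant vs child); and the low-risk / high-risk splits of
#' groups 3 and 4.
#'
#' @return Character vector of the seven subgroup labels.
#' @export
mb_subgroup7_levels <- function() {
  c("MB_WNT", "MB_SHH-Infant", "MB_SHH-Child",
    "MB_Grp3-LR", "MB_Grp3-HR", "MB_Grp4-LR", "MB_Grp4-HR")
}

#' Four-subgroup label set
#' @return Character vector of the four consensus subgroup labels.
#' @export
mb_subgroup4_levels <- function() c("MB_WNT", "MB_SHH", "MB_Grp3", "MB_Grp4")

#' Collapse seven-subgroup labels to the consensus four
#'
#' @param subgroup7 Character vector of seven-subgroup labels (NC and `NA`
#'   pass through).
#' @return Character vector of four-subgroup labels.
#' @export
subgroup7_to_subgroup4 <- function(subgroup7) {
  map <- c("MB_WNT" = "MB_WNT",
           "MB_SHH-Infant" = "MB_SHH", "MB_SHH-Child" = "MB_SHH",
           "MB_Grp3-LR" = "MB_Grp3", "MB_Grp3-HR" = "MB_Grp3",
           "MB_Grp4-LR" = "MB_Grp4", "MB_Grp4-HR" = "MB_Grp4",
           "NC" = "NC")
  out <- unname(map[subgroup7])
  out[is.na(subgroup7)] <- NA_character_
  out
}

clinical_enum_levels <- function() {
  list(sex = c("male", "female"),
       m_stage = c("M+", "M-"),
       resection = c("R+", "R-"),
       pathology = c("classic", "DN/MBEN", "LCA", "NOS"),
       subgroup4 = c(mb_subgroup4_levels(), "NC"),
       subgroup7 = c(mb_subgroup7_levels(), "NC"))
}

clinical_flag_columns <- function() {
  c("myc_amp", "mycn_amp", "tp53_mut", "tert_mut", "ctnnb1_mut",
    "chr6_loss", "i17q", "chr13_loss", "chr7q_gain", "chr11_loss",
    "chr17_gain", "chr9q_loss", "csi_treated", "event_pfs", "event_os")
}

#' Validate a clinical table
#'
#' Checks the schema in [clinical-table]: unique sample identifiers, ages in
#' \[0, 18\], non-negative survival times, and enum columns restricted to
#' their documented levels.
#'
#' @param clin A clinical `data.frame`.
#' @return `clin`, invisibly, or an error.
#' @export
validate_clinical <- function(clin) {
  if (!"sample_id" %in% names(clin)) stop("missing sample_id column")
  if (anyDuplicated(clin$sample_id)) stop("duplicated sample_id values")
  age <- clin$age_at_diagnosis
  if (any(!is.na(age) & (age < 0 | age > 18))) {
    stop("age_at_diagnosis must lie in [0, 18] years")
  }
  for (tc in c("time_pfs", "time_os")) {
    if (tc %in% names(clin) && any(!is.na(clin[[tc]]) & clin[[tc]] < 0)) {
      stop(tc, " contains negative survival times")
    }
  }
  lv <- clinical_enum_levels()
  for (col in intersect(names(lv), names(clin))) {
    bad <- setdiff(unique(stats::na.omit(clin[[col]])), lv[[col]])
    if (length(bad)) {
      stop(col, " contains unrecognised level(s): ",
           paste(bad, collapse = ", "))
    }
  }
  for (col in intersect(clinical_flag_columns(), names(clin))) {
    if (!is.logical(clin[[col]])) stop(col, " must be logical (TRUE/FALSE/NA)")
  }
  invisible(clin)
}

#' Read a clinical annotation table
#'
#' Reads a delimited text file following the [clinical-table] schema. `NA`
#' and empty cells encode unknowns. Unrecognised tokens in enum columns are
#' converted to `NA` with a warning; `true/false`, `TRUE/FALSE`, `1/0` and
#' `yes/no` are all accepted for flag columns.
#'
#' @param path Path to the text file.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects from
#'   \{tab, comma\}.
#' @return A validated clinical `data.frame`.
#' @export
read_clinical_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  clin <- utils::read.table(path, header = TRUE, sep = delimiter,
                            na.strings = c("NA", ""), check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "\"",
                            comment.char = "")
  if (!"sample_id" %in% names(clin)) stop("missing sample_id column")
  clin$sample_id <- as.character(clin$sample_id)
  lv <- clinical_enum_levels()
  for (col in intersect(names(lv), names(clin))) {
    vals <- as.character(clin[[col]])
    bad <- !is.na(vals) & !(vals %in% lv[[col]])
    if (any(bad)) {
      warning(sprintf("%s: %d unrecognised token(s) (%s) set to unknown",
                      col, sum(bad),
                      paste(unique(vals[bad]), collapse = ", ")))
      vals[bad] <- NA_character_
    }
    clin[[col]] <- vals
  }
  for (col in intersect(clinical_flag_columns(), names(clin))) {
    clin[[col]] <- parse_flag(clin[[col]], col)
  }
  validate_clinical(clin)
  clin
}

parse_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  tok <- tolower(as.character(x))
  out <- rep(NA, length(tok))
  out[tok %in% c("true", "t", "1", "yes")] <- TRUE
  out[tok %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !is.na(tok) & is.na(out)
  if (any(bad)) {
    warning(sprintf("%s: %d unrecognised token(s) set to unknown",
                    col, sum(bad)))
  }
  out
}

#' Write a clinical annotation table
#'
#' @param clin A clinical `data.frame`.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clin, path, delimiter = "\t") {
  utils::write.table(clin, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
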