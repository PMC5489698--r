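#' Probe-by-sample beta-value matrix
#'
#' A `probe_matrix` is a numeric matrix of DNA-methylation beta values
#' (methylated / total signal, in \[0, 1\]) with CpG probe identifiers as row
#' names and sample identifiers as column names. It is the substrate for
#' metagene factorisation, consensus clustering and cross-cohort projection.
#'
#' @param values Numeric matrix, probes in rows and samples in columns, with
#'   unique, non-empty dimnames. Values must lie in \[0, 1\]; `NA` marks a
#'   missing beta value.
#'
#' @return An object of class `probe_matrix` (a validated numeric matrix).
#' @export
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' pm <- probe_matrix(m)
probe_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  structure(values, class = c("probe_matrix", "matrix", "array")) |>
    validate_probe_matrix()
}

validate_probe_matrix <- function(x) {
  pid <- rownames(x)
  sid <- colnames(x)
  if (is.null(pid) || is.null(sid) || any(!nzchar(pid)) || any(!nzchar(sid))) {
    stop("probe and sample identifiers (dimnames) are required")
  }
  if (anyDuplicated(pid)) {
    stop("duplicated probe identifiers: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("duplicated sample identifiers: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  v <- x[!is.na(x)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop("beta values must lie in [0, 1]; range observed: ",
         paste(signif(range(v), 4), collapse = " .. "))
  }
  x
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes x %d samples (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t"
  else if (lengths(regmatches(header, gregexpr(",", header))) > 0) ","
  else stop("could not detect delimiter (neither tab nor comma in header): ",
            path)
}

#' Read a beta-value matrix from delimited text
#'
#' Expects probe identifiers in the first column and sample identifiers in the
#' header row. The delimiter is auto-detected from \{tab, comma\} unless given.
#' Blank cells and `NA` tokens become missing values.
#'
#' @param path Path to the text file.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects.
#' @param clip If `TRUE`, values outside \[0, 1\] are clipped into range
#'   (with a warning) instead of raising an error.
#'
#' @return A [probe_matrix].
#' @export
read_beta_matrix <- function(path, delimiter = NULL, clip = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, row.names = NULL,
                          na.strings = c("NA", ""), colClasses = NA,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("malformed header: need probe column plus samples")
  probes <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric beta values in ", path)
  rownames(vals) <- probes
  if (clip) {
    out <- !is.na(vals) & (vals < 0 | vals > 1)
    if (any(out)) {
      warning(sum(out), " value(s) outside [0, 1] clipped into range")
      vals[out] <- pmin(pmax(vals[out], 0), 1)
    }
  }
  probe_matrix(vals)
}

#' Write a beta-value matrix to delimited text
#'
#' @param x A [probe_matrix].
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, delimiter = "\t") {
  df <- data.frame(probe_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict two cohorts to a shared probe space
#'
#' Cross-cohort metagene projection requires both beta matrices to be indexed
#' by the same probes in the same order; this intersects their probe sets.
#'
#' @param a,b [probe_matrix] objects.
#' @param min_overlap Minimum tolerated fraction of the smaller probe set
#'   retained by the intersection (default 0.9); below this an error is
#'   raised, since heavy probe loss signals incompatible platforms.
#'
#' @return A list with elements `a`, `b` (both restricted to the common
#'   probes, ordered as in `a`) and `retained` (the overlap fraction).
#' @export
harmonise_probes <- function(a, b, min_overlap = 0.9) {
  common <- intersect(rownames(a), rownames(b))
  retained <- length(common) / min(nrow(a), nrow(b))
  if (retained < min_overlap) {
    stop(sprintf(
      "probe overlap %.1f%% is below the %.1f%% threshold (%d shared probes)",
      100 * retained, 100 * min_overlap, length(common)))
  }
  common <- rownames(a)[rownames(a) %in% common]  # preserve a's order
  list(a = probe_matrix(a[common, , drop = FALSE]),
       b = probe_matrix(b[common, , drop = FALSE]),
       retained = retained)
}

#' Select the most variable probes
#'
#' Keeps the `n` probes with the largest across-sample standard deviation, a
#' conventional feature-reduction step before matrix factorisation of
#' genome-wide methylation data. Probes with any missing value are dropped
#' first (complete-probe analysis). Ties in standard deviation at the cutoff
#' are broken towards the lexicographically smaller probe identifier; the
#' original probe order is preserved among the selected probes.
#'
#' @param x A [probe_matrix].
#' @param n Number of probes to keep (default 10000).
#' @return A [probe_matrix] with `n` rows.
#' @export
select_variable_probes <- function(x, n = 10000) {
  if (n <= 0) stop("`n` must be positive")
  complete <- !apply(is.na(unclass(x)), 1, any)
  v <- unclass(x)[complete, , drop = FALSE]
  if (n > nrow(v)) {
    stop(sprintf("n = %d exceeds the %d complete probes available",
                 n, nrow(v)))
  }
  sds <- apply(v, 1, stats::sd)
  keep <- rownames(v)[order(-sds, rownames(v))[seq_len(n)]]
  probe_matrix(v[rownames(v) %in% keep, , drop = FALSE])
}
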