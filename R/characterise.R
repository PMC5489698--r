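#' Chi-squared enrichment test with residual panel
#'
#' Pearson chi-squared test of independence for a feature-by-subgroup
#' contingency table, returning the cellwise Pearson residuals
#' `(O - E) / sqrt(E)` used to display where subgroup enrichment occurs.
#' Yates' continuity correction is applied on request (2 x 2 tables only,
#' as is standard).
#'
#' @param tab Integer matrix or table of counts, at least 2 x 2.
#' @param yates Apply Yates' continuity correction (default `FALSE`).
#' @param residual_type "pearson" (default; `(O - E)/sqrt(E)`) or "adjusted"
#'   (divided additionally by `sqrt((1-row)(1-col))` leverage terms).
#' @return List with `statistic`, `p`, `residuals`, `expected`, `df`.
#' @export
chi_squared_enrichment <- function(tab, yates = FALSE,
                                   residual_type = c("pearson", "adjusted")) {
  residual_type <- match.arg(residual_type)
  tab <- as.matrix(tab)
  check_counts(tab)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  if (any(ht$expected == 0)) stop("expected count of zero; test undefined")
  res <- if (residual_type == "pearson") ht$residuals else ht$stdres
  list(statistic = unname(ht$statistic), p = ht$p.value,
       residuals = res, expected = ht$expected,
       df = unname(ht$parameter))
}

check_counts <- function(tab) {
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2 x 2")
  if (anyNA(tab) || any(tab < 0)) stop("counts must be non-negative")
  if (any(abs(tab - round(tab)) > 1e-8)) stop("counts must be integers")
  invisible(tab)
}

#' Two-sided Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by probability-mass ordering: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one — the convention implemented by
#' [stats::fisher.test()], which this wraps after validation.
#'
#' @param tab 2 x 2 matrix or table of non-negative integer counts with a
#'   positive grand total.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2 x 2")
  check_counts(tab)
  if (sum(tab) == 0) stop("all-zero table")
  stats::fisher.test(tab)$p.value
}

#' One-way ANOVA of ages across subgroups
#'
#' Classical one-way analysis of variance on untransformed ages, used to test
#' subgroup-specific age differences.
#'
#' @param values Numeric vector (ages in years).
#' @param groups Group labels, same length; at least 2 groups with at least 2
#'   observations each.
#' @return List with `F` and `p`.
#' @export
anova_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  if (stats::var(values) == 0) stop("degenerate data: zero total variance")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  f <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  if (!is.finite(f)) {  # zero residual variance, non-zero between-group SS
    f <- Inf
    p <- 0
  }
  list(F = f, p = p)
}

#' Fit log-normal age distributions for two groups
#'
#' Per-group maximum-likelihood fit of a log-normal age distribution:
#' `mu = mean(log(age))`, `sigma = sqrt(mean((log(age) - mu)^2))` (ML
#' denominator). Component weights are the group proportions
#' (`weighting = "proportional"`, mixture view, the default) or 0.5 each.
#'
#' @param ages Positive numeric vector (years).
#' @param labels Two-level group labels, same length; each group needs at
#'   least 3 observations.
#' @param weighting "proportional" (default) or "equal".
#' @return Object of class `lognormal_age_model`: data frame with columns
#'   `group`, `n`, `mu`, `sigma`, `weight`.
#' @export
fit_age_lognormals <- function(ages, labels,
                               weighting = c("proportional", "equal")) {
  weighting <- match.arg(weighting)
  if (any(is.na(ages)) || any(ages <= 0)) stop("ages must be positive")
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two groups required")
  if (any(table(labels) < 3)) stop("each group needs at least 3 ages")
  fit_one <- function(x) {
    mu <- mean(log(x))
    sigma <- sqrt(mean((log(x) - mu)^2))
    if (sigma == 0) stop("degenerate group: all ages identical (sigma = 0)")
    c(mu = mu, sigma = sigma)
  }
  pars <- vapply(levels(labels), function(g) fit_one(ages[labels == g]),
                 c(mu = 0, sigma = 0))
  n <- as.integer(table(labels))
  w <- if (weighting == "proportional") n / sum(n) else c(0.5, 0.5)
  structure(data.frame(group = levels(labels), n = n,
                       mu = pars["mu", ], sigma = pars["sigma", ],
                       weight = w, row.names = NULL),
            class = c("lognormal_age_model", "data.frame"))
}

#' Intersection of two weighted log-normal densities
#'
#' Solves `w1 * f1(x) = w2 * f2(x)` for the age at which the two weighted
#' log-normal densities cross. In `y = log(x)` the equation is quadratic when
#' the two sigma differ and linear when they are equal (then, with equal
#' weights, the cutoff is the geometric mean of the medians). The root lying
#' strictly between the two group medians is returned; ages below the cutoff
#' belong to the younger group.
#'
#' @param model A `lognormal_age_model` from [fit_age_lognormals()], or any
#'   data frame with columns `mu`, `sigma`, `weight` (two rows).
#' @return The cutoff in years.
#' @export
intersect_lognormals <- function(model) {
  if (nrow(model) != 2) stop("model must describe exactly two groups")
  mu <- model$mu
  s <- model$sigma
  w <- model$weight
  # in y = log x the 1/x Jacobian cancels:
  # a y^2 + b y + c = 0
  a <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
  b <- mu[1] / s[1]^2 - mu[2] / s[2]^2
  cc <- mu[2]^2 / (2 * s[2]^2) - mu[1]^2 / (2 * s[1]^2) +
    log((w[1] * s[2]) / (w[2] * s[1]))
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) stop("densities are identical; no unique crossing")
    -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("densities do not cross")
    (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  med <- sort(exp(mu))
  x <- exp(roots)
  inside <- x > med[1] & x < med[2]
  if (!any(inside)) {
    stop("no density crossing between the group medians (",
         signif(med[1], 3), ", ", signif(med[2], 3), ")")
  }
  unname(x[inside][1])
}

#' Age-based SHH subgroup classification
#'
#' Assigns SHH-activated medulloblastoma patients to the infant or childhood
#' subgroup by the age cutoff where the two fitted log-normal age densities
#' cross (4.3 years by default). Ages below the cutoff are infant; ages at or
#' above it are childhood.
#'
#' @param age Age(s) at diagnosis in years, >= 0.
#' @param cutoff Cutoff in years (default 4.3).
#' @return Character vector: "MB_SHH-Infant" or "MB_SHH-Child".
#' @export
classify_shh_by_age <- function(age, cutoff = 4.3) {
  if (any(is.na(age)) || any(age < 0)) stop("ages must be non-negative")
  ifelse(age < cutoff, "MB_SHH-Infant", "MB_SHH-Child")
}
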