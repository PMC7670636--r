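#' Standardize values to z-scores
#'
#' Mean 0, sample standard deviation 1 (divide by n - 1).
#'
#' @param x numeric vector with at least two distinct values.
#' @return standardized numeric vector.
#' @export
zscoreValues <- function(x) {
  if (length(unique(x)) < 2L) stop("cannot z-score a constant input")
  (x - mean(x)) / stats::sd(x)
}

#' Pulse pressure from blood pressures
#'
#' Pulse pressure is systolic minus diastolic blood pressure, the pulsatile
#' component of BP used as a covariate and bivariate phenotype.
#'
#' @param systolic,diastolic blood pressures in mmHg.
#' @return numeric pulse pressure.
#' @export
pulsePressure <- function(systolic, diastolic) systolic - diastolic

# Build a standardized numeric design matrix from cohort columns; sex and
# group-like character columns become 0/1 indicators.
covariateMatrix <- function(cohort, covariates) {
  cols <- lapply(covariates, function(cv) {
    if (!cv %in% names(cohort))
      stop(sprintf("covariate '%s' not in cohort table", cv))
    v <- cohort[[cv]]
    if (is.character(v) || is.factor(v)) {
      lv <- sort(unique(as.character(v)))
      if (length(lv) != 2L)
        stop(sprintf("covariate '%s' must be numeric or two-level", cv))
      v <- as.numeric(as.character(v) == lv[2])
    }
    if (length(unique(v)) < 2L)
      stop(sprintf("covariate '%s' is constant", cv))
    zscoreValues(v)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Residual-approach covariate adjustment
#'
#' Implements the residual approach used before twin modelling: the
#' phenotype is z-scored, regressed by ordinary least squares on an
#' intercept plus the standardized covariates pooled over all subjects,
#' and the residuals are re-standardized. Family clustering is deliberately
#' ignored at this step (it enters through the twin models).
#'
#' Covariate subsets mirror the adjustment tiers used in heritability
#' reporting: unadjusted = age + sex; partial adds regional volume or ICV;
#' complete adds both.
#'
#' @param cohort a cohort data.frame (see [simulateTwinCohort()]).
#' @param phenotype name of the trait column to adjust.
#' @param covariates character vector of covariate column names.
#' @return the cohort with the phenotype column replaced by standardized
#'   residuals; fitted coefficients in `attr(, "adjustment")`.
#' @export
residualize <- function(cohort, phenotype, covariates = c("age", "sex")) {
  if (!phenotype %in% names(cohort))
    stop(sprintf("phenotype '%s' not in cohort table", phenotype))
  if (anyDuplicated(covariates))
    stop("duplicate covariates in adjustment spec")
  y <- zscoreValues(cohort[[phenotype]])
  X <- covariateMatrix(cohort, covariates)
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1L) {
    bad <- covariates[qx$pivot[(qx$rank + 1L):(ncol(X) + 1L)] - 1L]
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  res <- fit$residuals
  if (stats::sd(res) < 1e-8)
    stop("residuals are constant: phenotype fully explained by covariates")
  out <- cohort
  out[[phenotype]] <- zscoreValues(res)
  attr(out, "adjustment") <- list(phenotype = phenotype,
                                  covariates = covariates,
                                  coefficients = fit$coefficients)
  out
}
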