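## Inferential layer: age-adjusted epigenetic age, covariate-adjusted
## cross-sectional GLMs, change-score longitudinal models, and
## missing-completely-at-random checks. Sex is coded F = 0, M = 1
## throughout (recorded in the result metadata).

#' Age-adjusted epigenetic age (AgeAccelGrim)
#'
#' OLS residuals of GrimAge regressed on chronological age within the
#' cohort: positive values indicate accelerated mortality risk relative to
#' age peers. Residuals have mean zero and zero sample correlation with
#' age.
#'
#' @param grimage numeric vector, GrimAge in years.
#' @param age numeric vector, chronological age in years.
#' @return numeric vector of residuals (years).
#' @export
age_accel <- function(grimage, age) {
  if (length(grimage) != length(age) || length(age) < 3)
    stop_invalid("grimage and age must have equal length >= 3")
  if (sd(age) < 1e-12)
    stop("degenerate design: age is constant, AgeAccelGrim undefined")
  unname(stats::residuals(lm(grimage ~ age)))
}

#' Covariate-adjusted general linear model
#'
#' OLS with intercept; reports coefficient, standard error, t and
#' two-sided p for every term, highlighting a term of interest. The
#' baseline models of the analysis are instantiated as
#' `response ~ age_accel_grim + age + sex + <volume term(s)>`.
#'
#' @param response numeric vector.
#' @param covariates named list/data.frame of numeric vectors (code sex
#'   as 0/1).
#' @param term_of_interest name of the focal covariate (default the first).
#' @return object of class `glm_result`: data.frame `terms` (term,
#'   estimate, se, t, p), `df_residual`, `n`, `term_of_interest`,
#'   `sex_coding`.
#' @export
fit_glm <- function(response, covariates, term_of_interest = NULL) {
  X <- as.data.frame(covariates)
  term_of_interest <- term_of_interest %||% names(X)[1]
  stopifnot(term_of_interest %in% names(X))
  d <- cbind(.y = response, X)
  n <- nrow(d)
  if (n <= ncol(X) + 1) stop_invalid("n must exceed the number of terms")
  fit <- lm(.y ~ ., data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("collinearity error: term(s) ", paste(bad, collapse = ", "),
         " aliased in the design")
  }
  s <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                      t = s[, 3], p = s[, 4], row.names = NULL)
  structure(list(terms = terms, df_residual = fit$df.residual, n = n,
                 term_of_interest = term_of_interest,
                 sex_coding = "F=0, M=1"),
            class = "glm_result")
}

#' Extract the focal term of a `glm_result`
#' @param x `glm_result`.
#' @return one-row data.frame (term, estimate, se, t, p).
#' @export
glm_term <- function(x) {
  x$terms[x$terms$term == x$term_of_interest, , drop = FALSE]
}

#' @export
print.glm_result <- function(x, ...) {
  cat("glm_result: n =", x$n, ", residual df =", x$df_residual,
      "(", x$sex_coding, "; nominal p, no multiplicity correction )\n")
  print(x$terms, digits = 4)
  invisible(x)
}

#' Within-subject longitudinal model (change-score ANCOVA)
#'
#' The concrete realization of a within-subjects ANOVA with
#' between-subject controls: the change `y_followup - y_baseline` over
#' complete pairs is regressed on an intercept, the term of interest and
#' the covariates (centred, so the intercept is the covariate-adjusted
#' mean change). The F statistic (1 numerator df) for the term of interest
#' equals the square of its t; with no term of interest the intercept's F
#' tests mean change between timepoints.
#'
#' @param y_baseline,y_followup numeric vectors, matched by position;
#'   incomplete pairs are dropped (listwise deletion).
#' @param covariates named list/data.frame of numeric controls
#'   (e.g. sex, baseline age, a volume term).
#' @param term_of_interest name of the focal covariate, or NULL to test the
#'   mean change itself.
#' @return object of class `longitudinal_result`: `term`, `estimate`,
#'   `F_statistic`, `df_numerator` (1), `df_denominator`, `p_value`,
#'   `n_complete`.
#' @export
longitudinal_model <- function(y_baseline, y_followup, covariates = NULL,
                               term_of_interest = NULL) {
  stopifnot(length(y_baseline) == length(y_followup))
  X <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  ok <- !is.na(y_baseline) & !is.na(y_followup)
  if (!is.null(X)) ok <- ok & stats::complete.cases(X)
  if (!any(ok)) stop("no complete longitudinal pairs")
  dy <- (y_followup - y_baseline)[ok]
  n <- length(dy)
  if (!is.null(X)) {
    X <- X[ok, , drop = FALSE]
    X[] <- lapply(X, function(v) v - mean(v)) # centred controls
  }
  n_terms <- 1L + if (is.null(X)) 0L else ncol(X)
  if (n < n_terms + 2) stop_invalid("too few complete pairs (", n, ")")
  d <- if (is.null(X)) data.frame(.dy = dy) else cbind(.dy = dy, X)
  fit <- lm(.dy ~ ., data = d)
  s <- summary(fit)$coefficients
  focal <- if (is.null(term_of_interest)) "(Intercept)" else term_of_interest
  if (!focal %in% rownames(s))
    stop_invalid("term_of_interest '", focal, "' not among covariates")
  tval <- s[focal, 3]
  # a saturated zero-residual fit yields 0/0: an exactly-zero effect
  if (!is.finite(tval)) tval <- if (abs(s[focal, 1]) < 1e-12) 0 else Inf
  dfden <- fit$df.residual
  structure(list(term = focal, estimate = s[focal, 1],
                 F_statistic = tval^2, df_numerator = 1L,
                 df_denominator = dfden,
                 p_value = pf(tval^2, 1, dfden, lower.tail = FALSE),
                 n_complete = n),
            class = "longitudinal_result")
}

#' @export
print.longitudinal_result <- function(x, ...) {
  cat(sprintf("longitudinal_result: %s, F(1, %d) = %.3f, p = %.4g (n = %d)\n",
              x$term, x$df_denominator, x$F_statistic, x$p_value,
              x$n_complete))
  invisible(x)
}

#' Missing-completely-at-random checks
#'
#' For each baseline variable, a pooled-variance two-sample t-test of
#' subjects retained at follow-up against those not retained.
#'
#' @param cohort data.frame with at least `timepoint`,
#'   `retained_at_followup` and the baseline variables.
#' @param variables variables to test.
#' @return data.frame (variable, t_statistic, df, p); rows are `NA` when a
#'   group has fewer than 2 observations.
#' @export
missingness_tests <- function(cohort,
                              variables = c("age_years", "sex01",
                                            "total_brain_volume",
                                            "wmh_volume", "grimage_years",
                                            "age_accel_grim")) {
  base <- cohort[cohort$timepoint == "baseline", , drop = FALSE]
  if (!"sex01" %in% names(base) && "sex" %in% names(base))
    base$sex01 <- as.numeric(base$sex == "M")
  g <- base$retained_at_followup
  if (!any(g) || all(g))
    stop("both retained and non-retained groups must be non-empty")
  out <- lapply(variables, function(v) {
    x <- base[[v]][g]; y <- base[[v]][!g]
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2)
      return(data.frame(variable = v, t_statistic = NA_real_, df = NA_real_,
                        p = NA_real_))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(variable = v, t_statistic = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  do.call(rbind, out)
}
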