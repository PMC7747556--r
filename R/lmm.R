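# Day/night log-activity linear mixed models with all-subsets AIC
# candidate generation and conditional model averaging.

LMM_TERMS <- c("day_type", "age", "sex", "mass")

#' Assemble the mixed-model summary table
#'
#' One row per subject-day per stratum: log(mean activity + offset) for the
#' daytime and nighttime strata, the day type, and the subject covariates.
#' Continuous predictors get centered/scaled (mean 0, SD 1) copies
#' (`age_std`, `mass_std`) alongside the raw values, so standardized and
#' raw fits use the same table.
#'
#' @param summaries row-bound output of [summarizeActivity()] across
#'   subjects.
#' @param metadata cohort metadata (columns id, age, sex, mass).
#' @param offset positive count added before the log (default 1, so
#'   zero-activity strata stay finite).
#' @return data.frame with columns subject, date, stratum
#'   ("daytime"/"nighttime"), day_type, log_activity, age, sex, mass,
#'   age_std, mass_std; rows with missing summaries are dropped.
#' @export
buildSummaryTable <- function(summaries, metadata, offset = 1) {
  if (!is.numeric(offset) || offset <= 0) {
    stop("offset must be a positive count", call. = FALSE)
  }
  metadata$id <- as.character(metadata$id)
  long <- rbind(
    data.frame(summaries[c("subject", "date", "day_type")],
               stratum = "daytime", mean_count = summaries$daytime_mean),
    data.frame(summaries[c("subject", "date", "day_type")],
               stratum = "nighttime", mean_count = summaries$nighttime_mean))
  long <- long[!is.na(long$mean_count), , drop = FALSE]
  long$log_activity <- log(long$mean_count + offset)
  m <- match(long$subject, metadata$id)
  if (anyNA(m)) {
    stop("no metadata for subject(s): ",
         paste(unique(long$subject[is.na(m)]), collapse = ", "),
         call. = FALSE)
  }
  long$age <- metadata$age[m]
  long$sex <- factor(metadata$sex[m], levels = c("F", "M"))
  long$mass <- metadata$mass[m]
  long$day_type <- factor(long$day_type, levels = c("weekday", "weekend"))
  long$age_std <- as.numeric(scale(long$age))
  long$mass_std <- as.numeric(scale(long$mass))
  stopifnot(all(is.finite(long$log_activity)))
  rownames(long) <- NULL
  long[order(long$subject, long$date, long$stratum), ]
}

#' Fit one random-intercept model for a stratum
#'
#' Gaussian linear mixed model of log activity on a subset of the fixed
#' terms with a per-subject random intercept, fitted by maximum likelihood
#' (not REML) so AIC values are comparable across fixed-effect sets.
#' Standardized copies of the continuous predictors are used when
#' `standardized = TRUE`. A singular fit (random-intercept variance
#' estimated at zero) is returned with `singular = TRUE`, not an error.
#'
#' @param table output of [buildSummaryTable()].
#' @param fixedTerms subset of `c("day_type", "age", "sex", "mass")`
#'   (possibly empty: intercept-only).
#' @param response `"daytime"` or `"nighttime"`.
#' @param standardized use `age_std`/`mass_std` in place of raw values.
#' @return list with `model` (the merMod), `terms`, `aic`, `logLik`,
#'   `coefficients`, `se` (fixed effects), `singular`.
#' @export
fitRandomInterceptModel <- function(table, fixedTerms = LMM_TERMS,
                                    response = c("daytime", "nighttime"),
                                    standardized = TRUE) {
  response <- match.arg(response)
  stopifnot(all(fixedTerms %in% LMM_TERMS))
  dat <- table[table$stratum == response, , drop = FALSE]
  if (length(unique(dat$subject)) < 2L) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  for (term in intersect(fixedTerms, c("day_type", "sex"))) {
    if (length(unique(dat[[term]])) < 2L) {
      stop("term '", term, "' has a single observed level in the ",
           response, " stratum; it cannot be estimated", call. = FALSE)
    }
  }
  vars <- fixedTerms
  if (standardized) {
    vars[vars == "age"] <- "age_std"
    vars[vars == "mass"] <- "mass_std"
  }
  rhs <- paste(c("1", vars, "(1 | subject)"), collapse = " + ")
  fml <- stats::as.formula(paste("log_activity ~", rhs))
  fit <- suppressMessages(
    lme4::lmer(fml, data = dat, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore")))
  fe <- lme4::fixef(fit)
  list(model = fit, terms = fixedTerms, aic = AIC(fit),
       logLik = as.numeric(logLik(fit)), coefficients = fe,
       se = sqrt(diag(as.matrix(vcov(fit)))),
       singular = lme4::isSingular(fit))
}

# Coefficient names produced by a term under the codings above.
termCoefNames <- function(term, standardized) {
  switch(term,
    day_type = "day_typeweekend",
    sex = "sexM",
    age = if (standardized) "age_std" else "age",
    mass = if (standardized) "mass_std" else "mass")
}

prettyTermLabel <- c(day_type = "Day type (weekend)", age = "Age",
                     sex = "Sex (male)", mass = "Body mass")

# Natural (conditional) average of one term across the models containing
# it: weights renormalized over those models, unconditional SE including
# between-model variance (revised model-averaging variance estimator).
conditionalAverage <- function(beta, se, weight) {
  w <- weight / sum(weight)
  est <- sum(w * beta)
  list(estimate = est, se = sqrt(sum(w * (se^2 + (beta - est)^2))))
}

#' All-subsets candidate models and conditional model averaging
#'
#' Fits every subset of the fixed terms (2^k candidate models, all with
#' the random intercept), ranks them by ML AIC, retains those with
#' delta-AIC below `deltaMax`, and averages coefficients over the retained
#' set with Akaike weights \eqn{w_m \propto \exp(-\Delta_m/2)}:
#'
#' * **conditional (natural) average** -- each term averaged only over the
#'   retained models that contain it, with weights renormalized over those
#'   models (the headline estimate);
#' * **full average** -- zero substituted where a term is absent (reported
#'   alongside).
#'
#' The unconditional SE includes between-model variance,
#' \eqn{SE = \sqrt{\sum_m w_m (se_m^2 + (\beta_m - \bar\beta)^2)}}; z is
#' |estimate|/SE with a standard-normal p value, and the 95% CI is
#' estimate +/- 1.96 SE.
#'
#' @inheritParams fitRandomInterceptModel
#' @param fullTerms the terms of the full model (all subsets of these are
#'   fitted).
#' @param deltaMax retain candidate models with delta-AIC strictly below
#'   this (default 10).
#' @param useAICc rank and weight by the small-sample AICc instead of AIC.
#' @return a [ModelAverageResult].
#' @examples
#' \dontrun{
#' tab <- buildSummaryTable(summaries, subjects(cohort))
#' dredgeAndAverage(tab, response = "daytime")
#' }
#' @export
dredgeAndAverage <- function(table, response = c("daytime", "nighttime"),
                             fullTerms = LMM_TERMS, deltaMax = 10,
                             standardized = TRUE, useAICc = FALSE) {
  response <- match.arg(response)
  stopifnot(deltaMax > 0)
  k <- length(fullTerms)
  subsets <- lapply(seq_len(2^k) - 1L, function(m) fullTerms[bitwAnd(
    m, 2^(seq_len(k) - 1L)) > 0])
  fits <- lapply(subsets, fitRandomInterceptModel, table = table,
                 response = response, standardized = standardized)

  aic <- vapply(fits, `[[`, numeric(1), "aic")
  if (useAICc) {
    nObs <- sum(table$stratum == response)
    kPar <- vapply(fits, function(f) length(f$coefficients) + 2, numeric(1))
    aic <- aic + 2 * kPar * (kPar + 1) / pmax(nObs - kPar - 1, 1)
  }
  delta <- aic - min(aic)
  retained <- delta < deltaMax
  if (!any(retained)) stop("internal error: no model retained", call. = FALSE)
  w <- exp(-delta / 2) * retained
  w <- w / sum(w)

  models <- data.frame(
    terms = vapply(subsets, function(s) if (length(s)) paste(s, collapse = "+")
                   else "(intercept)", character(1)),
    df = vapply(fits, function(f) length(f$coefficients) + 2L, integer(1)),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = aic, delta = delta, weight = w, retained = retained,
    singular = vapply(fits, `[[`, logical(1), "singular"))
  models <- models[order(models$delta), ]
  rownames(models) <- NULL

  rows <- lapply(fullTerms, function(term) {
    cn <- termCoefNames(term, standardized)
    has <- vapply(subsets, function(s) term %in% s, logical(1)) & retained
    beta <- vapply(fits[has], function(f) unname(f$coefficients[cn]), numeric(1))
    se <- vapply(fits[has], function(f) unname(f$se[cn]), numeric(1))
    avg <- conditionalAverage(beta, se, w[has])
    est <- avg$estimate
    seAvg <- avg$se
    estFull <- sum(w[has] * beta)              # zero where the term is absent
    z <- abs(est) / seAvg
    data.frame(term = prettyTermLabel[[term]], estimate = est, se = seAvg,
               z = z, p = 2 * pnorm(-z), ci_low = est - 1.96 * seAvg,
               ci_high = est + 1.96 * seAvg, full_estimate = estFull,
               weight = sum(w[has]))
  })
  coefs <- do.call(rbind, rows)
  rownames(coefs) <- NULL
  new("ModelAverageResult", response = response, coefficients = coefs,
      models = models)
}

# Weights of models containing each term, after delta-AIC retention --
# exposed for reporting (variable importance).
termWeights <- function(result) {
  setNames(result@coefficients$weight, result@coefficients$term)
}
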