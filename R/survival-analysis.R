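#' @include AllClasses.R
NULL

.checkSurvival <- function(time, event) {
  if (any(time <= 0)) stop("survival times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0/1")
  invisible(TRUE)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator (S(0) = 1, steps at event times only), overall
#' or per group, with censoring marks.
#'
#' @param time follow-up times in years (> 0).
#' @param event 0/1 event indicators (0 = censored).
#' @param group optional group labels.
#' @return data.frame: group, time, n_risk, n_event, n_censor, surv.
#' @export
kaplanMeier <- function(time, event, group = NULL) {
  .checkSurvival(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = as.factor(group)))
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(as.factor(group)),
                                     length(sm$time))
  else sub("^g=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, n_censor = sm$n.censor, surv = sm$surv,
             stringsAsFactors = FALSE)
}

#' k-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance, full follow-up.
#'
#' @param time,event as in \code{\link{kaplanMeier}}.
#' @param group group labels (>= 2 non-empty groups).
#' @return list: \code{chisq}, \code{df} (k - 1), \code{p}.
#' @export
logrankTest <- function(time, event, group) {
  .checkSurvival(time, event)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("log-rank test requires >= 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = group))
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling (Breslow available);
#' Wald confidence intervals; hazard ratios per covariate.
#'
#' @param time,event as in \code{\link{kaplanMeier}}.
#' @param covariates data.frame of covariates (factors or numerics; no
#'   constant columns).
#' @param ties "efron" (default) or "breslow".
#' @param conf confidence level (default 0.95).
#' @return data.frame: term, coef, HR, lower, upper, se, z, p.
#' @export
coxPH <- function(time, event, covariates, ties = c("efron", "breslow"),
                  conf = 0.95) {
  ties <- match.arg(ties)
  .checkSurvival(time, event)
  if (sum(event) == 0) stop("no events: Cox model cannot be fitted")
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2,
                  logical(1))
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(covariates)[const], collapse = ", "))
  if (sum(event) < ncol(covariates))
    stop("fewer events than covariates")
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(colnames(covariates),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(iter.max = 50))
  if (any(abs(stats::coef(fit)) > 15))
    stop("apparent separation: a coefficient diverged (|coef| > 15)")
  if (fit$iter >= 50)
    stop("Cox model did not converge in 50 iterations")
  s <- summary(fit, conf.int = conf)
  cf <- s$coefficients
  ci <- s$conf.int
  data.frame(term = rownames(cf), coef = cf[, "coef"],
             HR = cf[, "exp(coef)"],
             lower = ci[, 3], upper = ci[, 4],
             se = cf[, "se(coef)"], z = cf[, "z"],
             p = cf[, "Pr(>|z|)"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Compare survival across genomic subtypes
#'
#' Convenience wrapper: Kaplan-Meier curves, log-rank test, and (optionally)
#' a multivariate Cox model with the conventional covariates (LN status,
#' ER status, tumor size, grade 3 vs 1/2) plus subtype.
#'
#' @param clin clinical DataFrame (see \code{\link{readClinicalTable}}).
#' @param labels named subtype labels (samples matching \code{clin} rows).
#' @param endpoint "os" or "dmfs".
#' @param covariates run the multivariate model too (default FALSE).
#' @return list: \code{km}, \code{logrank}, and optionally \code{cox}.
#' @export
compareSurvival <- function(clin, labels, endpoint = c("os", "dmfs"),
                            covariates = FALSE) {
  endpoint <- match.arg(endpoint)
  shared <- intersect(rownames(clin), names(labels))
  clin <- clin[shared, , drop = FALSE]
  labels <- labels[shared]
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  time <- clin[[tcol]]; event <- clin[[ecol]]
  ok <- !is.na(time) & !is.na(event) & time > 0
  out <- list(km = kaplanMeier(time[ok], event[ok], labels[ok]),
              logrank = logrankTest(time[ok], event[ok], labels[ok]))
  if (covariates) {
    cov <- data.frame(
      ln_pos = as.integer(clin$ln_status == "pos"),
      er_pos = as.integer(clin$er_status == "pos"),
      size_mm = clin$size_mm,
      grade3 = as.integer(clin$grade == 3),
      subtype = factor(labels))
    ok2 <- ok & stats::complete.cases(cov)
    out$cox <- coxPH(time[ok2], event[ok2], cov[ok2, , drop = FALSE])
  }
  out
}
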