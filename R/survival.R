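#' Kaplan-Meier product-limit estimate
#'
#' Standard convention: at tied times, deaths precede censorings.
#'
#' @param time positive follow-up times (months).
#' @param event event indicator (1 = death, 0 = censored).
#' @return a `km_estimate`: list with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` and the underlying `survfit` object.
#' @export
km_estimate <- function(time, event) {
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  fit <- survfit(Surv(time, event) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = fit$surv, fit = fit),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$fit$n, ", events =", sum(x$n_event), "\n")
  print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                   surv = round(x$surv, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.km_estimate <- function(x, xlab = "Months", ylab = "Overall survival", ...) {
  plot(x$fit, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param time,event as in [km_estimate()].
#' @param group binary group indicator (two nonempty groups required).
#' @return a `logrank_test`: `chi_square` (1 df), `p_value`, group sizes,
#'   observed and expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.integer(factor(group))
  if (length(unique(group)) != 2L)
    stop("log-rank test needs exactly two nonempty groups", call. = FALSE)
  sd <- survdiff(Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  structure(list(chi_square = chisq,
                 p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
                 n = as.vector(table(group)),
                 observed = unname(sd$obs), expected = unname(sd$exp)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f (1 df), p = %.4g; n = %s\n",
              x$chi_square, x$p_value, paste(x$n, collapse = " vs ")))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood (Efron tie handling by default) and
#' reports per-covariate hazard ratios with 95% Wald confidence intervals
#' and the model likelihood-ratio chi-square versus the null model.
#' Monotone-likelihood / non-converged fits are flagged via `converged`,
#' never silently returned as ordinary estimates.
#'
#' @param time,event follow-up and event indicator.
#' @param covariates data frame (or matrix) of covariates; none may be
#'   constant; rows align with `time`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return a `cox_fit`: `coefficients` data frame (term, beta, se, hr,
#'   ci_lo, ci_hi, p), `lr_chisq`, `lr_df`, `lr_p`, `n`, `n_events`,
#'   `converged`, and the underlying `coxph` object as `model`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) == 0L) stop("no covariates", call. = FALSE)
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  const <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2L, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(covariates)[const], collapse = ", "),
         call. = FALSE)
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  converged <- TRUE
  notes <- character()
  fit <- withCallingHandlers(
    coxph(Surv(.time, .event) ~ ., data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        converged <<- FALSE
        notes <<- c(notes, conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  coefs <- data.frame(term = rownames(co),
                      beta = co[, "coef"],
                      se = co[, "se(coef)"],
                      hr = co[, "exp(coef)"],
                      ci_lo = ci[, "lower .95"],
                      ci_hi = ci[, "upper .95"],
                      p = co[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 lr_chisq = unname(s$logtest["test"]),
                 lr_df = unname(s$logtest["df"]),
                 lr_p = unname(s$logtest["pvalue"]),
                 n = s$n, n_events = s$nevent,
                 ties = ties, converged = converged, notes = notes,
                 model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 2, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties): n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  if (!x$converged) cat("** fit did not converge (monotone likelihood?) **\n")
  co <- x$coefficients
  cat(sprintf("  %-20s HR (95%% CI) = %.*f (%.*f-%.*f), p = %.3g\n",
              co$term, digits, co$hr, digits, co$ci_lo, digits, co$ci_hi, co$p),
      sep = "")
  cat(sprintf("  LR chi-square = %.2f (%d df), p = %.3g\n",
              x$lr_chisq, x$lr_df, x$lr_p))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) setNames(object$coefficients$beta,
                                               object$coefficients$term)

#' @export
summary.cox_fit <- function(object, ...) object$coefficients

#' Administrative censoring at a follow-up horizon
#'
#' Events after `horizon` become censored at the horizon; follow-up is
#' truncated there. Never increases the event count.
#'
#' @param time,event follow-up and event indicator.
#' @param horizon months (default 120, i.e. 10-year overall survival).
#' @return data frame `time`, `event`.
#' @export
censor_at_horizon <- function(time, event, horizon = 120) {
  event <- ifelse(time > horizon, 0, event)
  data.frame(time = pmin(time, horizon), event = event)
}

# stage III-IV vs I-II indicator; accepts I..IV, 1..4, or already-binary 0/1
.stage_binary <- function(stage) {
  if (is.numeric(stage) && all(stage %in% c(0, 1, NA))) return(stage)
  s <- as.character(stage)
  out <- ifelse(s %in% c("III", "IV", "3", "4"), 1L,
                ifelse(s %in% c("I", "II", "1", "2"), 0L, NA_integer_))
  out
}

#' Stepwise AIC covariate entry around a protected base model
#'
#' Forward-backward stepwise selection minimizing AIC, where the base
#' covariates (typically the marker under study plus stage) can never be
#' dropped and the candidates (e.g. age, alcohol use) may enter.
#'
#' @param time,event follow-up and event indicator.
#' @param base data frame of protected covariates.
#' @param candidates data frame of optional covariates.
#' @param ties tie handling for the Cox fits.
#' @return list: `fit` (a `cox_fit` of the final model), `selected`
#'   (candidate names retained), `trace` (stepwise path from
#'   [MASS::stepAIC()]).
#' @export
stepwise_aic <- function(time, event, base, candidates = NULL,
                         ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  base <- as.data.frame(base)
  candidates <- if (is.null(candidates)) base[, 0, drop = FALSE]
                else as.data.frame(candidates)
  dat <- cbind(data.frame(.time = time, .event = event), base, candidates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  base_terms <- names(base)
  cand_terms <- names(candidates)
  lower <- stats::reformulate(base_terms)
  upper <- stats::reformulate(c(base_terms, cand_terms))
  full0 <- coxph(stats::reformulate(base_terms, response = "Surv(.time, .event)"),
                 data = dat, ties = ties, model = TRUE)
  if (length(cand_terms) == 0L) {
    final_terms <- base_terms
    trace <- NULL
  } else {
    stepped <- MASS::stepAIC(full0, scope = list(lower = lower, upper = upper),
                             direction = "both", trace = 0)
    final_terms <- attr(stats::terms(stepped), "term.labels")
    trace <- stepped$anova
  }
  fit <- cox_fit(dat$.time, dat$.event, dat[, final_terms, drop = FALSE], ties = ties)
  list(fit = fit, selected = setdiff(final_terms, base_terms), trace = trace)
}
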