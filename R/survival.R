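# Outcome association of repertoire statistics. Kaplan-Meier, log-rank and
# Cox machinery delegate to the survival package (product-limit estimator,
# survdiff, coxph with Breslow tie handling) behind a tidy interface.

#' Median split of a per-patient statistic
#'
#' `low` = strictly below the sample median (the "below-median" group);
#' values equal to the median go to `high`. The median is computed over all
#' non-missing values; missing values get `NA`.
#'
#' @param values Numeric vector (e.g. per-patient diversity).
#' @return Factor with levels `low`, `high`.
#' @examples
#' median_split(c(1, 2, 2, 3)) # low, high, high, high
#' @export
median_split <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) abort("Median split needs at least 2 values.")
  med <- median(v)
  if (all(v == med)) abort("All values equal; median split is degenerate.")
  factor(ifelse(values < med, "low", "high"), levels = c("low", "high"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function. With only censored
#' observations the curve is flat at 1.
#'
#' @param records Data frame with `time` (non-negative) and `event`
#'   (logical or 0/1).
#' @return A `km_curve`: tibble with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (rows at each observed time).
#' @export
km_estimate <- function(records) {
  records <- check_survival_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' @rdname km_estimate
#' @param x A `km_curve`.
#' @param ... Unused.
#' @method glance km_curve
#' @export
glance.km_curve <- function(x, ...) {
  med <- x$time[x$surv <= 0.5][1]
  tibble(n = if (nrow(x)) x$n_risk[1] else 0L,
         n_events = sum(x$n_event),
         median_survival = if (length(med)) med else NA_real_)
}

#' Two-group survival comparison
#'
#' Reports the standard log-rank statistic (observed vs expected events
#' under pooled risk sets) and the Cox partial-likelihood ratio test for
#' the group indicator. The likelihood-ratio p-value is the default
#' curve-comparison test; the log-rank statistic is reported alongside.
#'
#' @inheritParams km_estimate
#' @param group Factor or vector with exactly two levels, one per record.
#' @return One-row tibble: `logrank_chisq`, `logrank_p`, `cox_lrt_chisq`,
#'   `cox_lrt_p`, `n`, `n_events`.
#' @export
survival_group_test <- function(records, group) {
  records <- check_survival_records(records)
  group <- as.factor(group)
  if (length(group) != nrow(records)) {
    abort("`group` must have one value per record.")
  }
  tab <- table(group)
  if (length(tab) != 2L || any(tab == 0L)) {
    abort("Exactly two non-empty groups are required.")
  }
  if (sum(records$event) < 1L) abort("At least one event is required.")
  d <- cbind(records, .group = group)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ .group, data = d)
  # the partial-likelihood ratio remains valid under monotone likelihood,
  # so the infinite-coefficient warning is muffled here
  cx <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ .group, data = d,
                    ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  lrt <- 2 * (cx$loglik[2] - cx$loglik[1])
  tibble(
    logrank_chisq = sd_fit$chisq,
    logrank_p = stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
    cox_lrt_chisq = lrt,
    cox_lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    n = nrow(records),
    n_events = sum(records$event)
  )
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model (Breslow tie handling) of the survival outcome on the
#' given covariates and reports per-covariate hazard ratios with 95%
#' confidence intervals from the observed information. Monotone likelihood
#' (complete separation) is reported as an unbounded hazard ratio in the
#' `diagnostic` column rather than an error.
#'
#' @inheritParams km_estimate
#' @param covariates Character vector of covariate column names in
#'   `records` (numeric or factor).
#' @return A `cox_screen`: tibble with `term`, `beta`, `hr`, `se`,
#'   `conf_low`, `conf_high`, `p_value`, `diagnostic`; model-level
#'   statistics are available via [glance()].
#' @export
cox_fit <- function(records, covariates) {
  records <- check_survival_records(records)
  missing <- setdiff(covariates, names(records))
  if (length(missing)) {
    abort(sprintf("Covariate(s) not in `records`: %s.",
                  paste(missing, collapse = ", ")))
  }
  if (sum(records$event) < 1L) abort("At least one event is required.")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit)
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  unbounded <- is.na(beta) | abs(beta) > 15 | se > 100
  out <- tibble(
    term = names(beta),
    beta = unname(beta),
    hr = exp(unname(beta)),
    se = unname(se),
    conf_low = exp(unname(beta) - 1.96 * unname(se)),
    conf_high = exp(unname(beta) + 1.96 * unname(se)),
    p_value = unname(s$coefficients[, "Pr(>|z|)"]),
    diagnostic = ifelse(unbounded,
                        "unbounded estimate (monotone likelihood)",
                        NA_character_)
  )
  attr(out, "loglik") <- fit$loglik
  attr(out, "score") <- fit$score
  attr(out, "n") <- fit$n
  attr(out, "n_events") <- fit$nevent
  class(out) <- c("cox_screen", class(out))
  out
}

#' @rdname cox_fit
#' @param x A `cox_screen`.
#' @param ... Unused.
#' @method glance cox_screen
#' @export
glance.cox_screen <- function(x, ...) {
  ll <- attr(x, "loglik")
  tibble(
    n = attr(x, "n"),
    n_events = attr(x, "n_events"),
    loglik = ll[2],
    lrt_chisq = 2 * (ll[2] - ll[1]),
    lrt_p = stats::pchisq(2 * (ll[2] - ll[1]), df = nrow(x), lower.tail = FALSE),
    score_chisq = attr(x, "score")
  )
}

check_survival_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 1L) {
    abort("`records` must be a data frame with at least one row.")
  }
  need <- setdiff(c("time", "event"), names(records))
  if (length(need)) {
    abort(sprintf("`records` lacks column(s): %s.", paste(need, collapse = ", ")))
  }
  if (any(is.na(records$time)) || any(records$time < 0)) {
    abort("`time` must be non-negative and non-missing.")
  }
  records <- as_tibble(records)
  records$event <- as.integer(as.logical(records$event))
  records
}
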