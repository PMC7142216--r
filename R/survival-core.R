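#' Fit a Cox proportional-hazards model with the three overall tests
#'
#' Fits `h(t | x) = h0(t) exp(beta' x)` by maximum partial likelihood
#' (Efron tie handling by default, via the survival package) and reports the
#' three overall model tests -- likelihood ratio, Wald, and score (log-rank)
#' -- each against a chi-square with `ncol(covariates)` degrees of freedom.
#' The screening and integration stages gate genes on these p-values.
#'
#' Non-convergence and singular information matrices are reportable states
#' (`converged = FALSE`, p-values `NA`), never exceptions, so genome-wide
#' screens do not abort; callers treat such fits as non-significant.
#'
#' @param covariates Numeric vector or n x p matrix of covariates
#'   (z-scored upstream; no standardization is applied here).
#' @param time Observed times in days.
#' @param event 0/1 event indicators.
#' @param ties `"efron"` (default) or `"breslow"` tie approximation.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance passed to the fitter.
#' @return An object of class `cox_fit` with elements `beta`, `se`,
#'   `loglik_null`, `loglik_fit`, `p_lrt`, `p_wald`, `p_score`,
#'   `converged`, `n`, `n_events`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(100)
#' t <- rexp(100, exp(0.8 * x))
#' fit_cox(x, t, rep(1, 100))
fit_cox <- function(covariates, time, event, ties = c("efron", "breslow"),
                    max_iter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  x <- as.matrix(covariates)
  if (nrow(x) != length(time) || length(time) != length(event)) {
    stopf("covariates, time and event must have matching lengths")
  }
  if (sum(event) < 1) stopf("at least one event is required")
  const <- apply(x, 2, function(col) {
    isTRUE(stats::var(col, na.rm = TRUE) == 0) || all(!is.finite(col))
  })
  if (any(const)) {
    stopf("constant covariate column(s): %s",
          paste(which(const), collapse = ", "))
  }

  # coxph.fit is the same Newton/step-halving engine behind coxph(), called
  # without the formula machinery: the screen runs it thousands of times.
  fit <- tryCatch(
    suppressWarnings(survival::coxph.fit(
      x, survival::Surv(time, event), strata = NULL, offset = NULL,
      init = NULL,
      control = survival::coxph.control(iter.max = max_iter, eps = tol),
      weights = NULL, method = ties, rownames = NULL
    )),
    error = function(e) NULL
  )

  p <- ncol(x)
  not_converged <- structure(list(
    beta = rep(NA_real_, p), se = rep(NA_real_, p),
    loglik_null = NA_real_, loglik_fit = NA_real_,
    p_lrt = NA_real_, p_wald = NA_real_, p_score = NA_real_,
    converged = FALSE, n = nrow(x), n_events = sum(event)
  ), class = "cox_fit")
  if (is.null(fit) || anyNA(fit$coefficients)) return(not_converged)
  beta <- unname(fit$coefficients)
  vdiag <- diag(as.matrix(fit$var))
  # iteration cap, non-finite information, or a runaway coefficient
  # (monotone likelihood: |beta| -> infinity) all count as non-convergence
  if (fit$iter >= max_iter || any(!is.finite(vdiag)) || any(vdiag <= 0) ||
      any(abs(beta) > 15)) {
    return(not_converged)
  }
  se <- unname(sqrt(vdiag))
  lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
  wald <- drop(t(beta) %*% solve(as.matrix(fit$var), beta))
  sc <- fit$score
  structure(list(
    beta = beta, se = se,
    loglik_null = fit$loglik[1], loglik_fit = fit$loglik[2],
    p_lrt = stats::pchisq(lrt, df = p, lower.tail = FALSE),
    p_wald = stats::pchisq(wald, df = p, lower.tail = FALSE),
    p_score = stats::pchisq(sc, df = p, lower.tail = FALSE),
    converged = TRUE, n = nrow(x), n_events = sum(event)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> p=%d, n=%d, events=%d, converged=%s\n",
              length(x$beta), x$n, x$n_events, x$converged))
  cat("  beta:", signif(x$beta, 4), "\n")
  cat(sprintf("  p(LRT)=%.3g p(Wald)=%.3g p(score)=%.3g\n",
              x$p_lrt, x$p_wald, x$p_score))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs in which the subject with the higher
#' risk score fails first. A pair is comparable iff the smaller observed time
#' belongs to an event (tied times are not comparable); ties in risk score
#' count 1/2. C = 1 is perfect discrimination, C = 0.5 is random.
#'
#' @param risk Numeric risk scores (higher = predicted earlier failure).
#' @param time Observed times.
#' @param event 0/1 event indicators.
#' @return The concordance index in `[0, 1]`.
#' @export
#' @examples
#' t <- c(2, 4, 6, 8)
#' concordance_index(-t, t, rep(1, 4))  # 1: risk reverses time exactly
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  if (length(time) != n || length(event) != n) {
    stopf("risk, time and event must have equal lengths")
  }
  # comparable[i, j]: subject i failed strictly before subject j was observed
  comparable <- outer(time, time, "<") & (event == 1)
  n_comp <- sum(comparable)
  if (n_comp == 0) stopf("no comparable pairs")
  higher <- outer(risk, risk, ">")
  tied <- outer(risk, risk, "==")
  (sum(comparable & higher) + 0.5 * sum(comparable & tied)) / n_comp
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Observed times.
#' @param event 0/1 event indicators; censored subjects leave the risk set
#'   without a survival drop.
#' @return An object of class `km_curve`: a data.frame with columns `time`
#'   (unique observed times), `survival` and `at_risk`. S(0) = 1 implicitly.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stopf("at least one subject is required")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = sf$time, survival = sf$surv, at_risk = sf$n.risk)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-sample log-rank test
#'
#' Standard log-rank chi-square(1) test comparing the survival of two groups,
#' as used to contrast median-split high- and low-risk strata.
#'
#' @param group Two-level factor/vector of group labels.
#' @param time Observed times.
#' @param event 0/1 event indicators.
#' @return The log-rank p-value.
#' @export
logrank_test <- function(group, time, event) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stopf("exactly two groups are required")
  if (sum(event) < 1) stopf("at least one event is required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  unname(stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
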