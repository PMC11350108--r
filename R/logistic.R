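#' Logistic risk modelling of VF survivorship
#'
#' The modelling chain used to discriminate VF survivors within an HCM
#' cohort: univariate screening, collinearity rejection, logistic regression
#' fitted by Newton's method on z-scaled covariates, backward stepwise
#' selection on Wald p-values, and odds-ratio back-transformation to the
#' original measurement units.
#'
#' @name risk_model
NULL

#' Fit a logistic regression by Newton's method
#'
#' Newton-Raphson maximization of the binomial log-likelihood with an
#' intercept, iterated to a gradient norm below `tol` or `max_iter`
#' iterations. Wald standard errors come from the observed information at
#' the optimum; the likelihood-ratio p-value compares against the
#' intercept-only model with df = number of covariates.
#'
#' Complete separation manifests as diverging coefficients; with
#' `strict = TRUE` (default) a coefficient exceeding `sep_limit` on scaled
#' data raises an error naming the covariate, with `strict = FALSE` the
#' iteration simply stops there (capped fit, used inside cross-validation
#' where separated training folds are legitimate).
#'
#' @param X numeric design matrix (no intercept column), ideally z-scaled
#' @param y binary response (0/1 or logical)
#' @param max_iter maximum Newton iterations
#' @param tol convergence tolerance on the score norm
#' @param strict raise on separation / singular information?
#' @param sep_limit absolute coefficient bound signalling separation
#' @return a `logistic_fit`: list with `coef`, `se`, `z`, `p` (Wald),
#'   `vcov`, `loglik`, `null_loglik`, `llr_stat`, `llr_p`, `converged`,
#'   `iterations`, `separated`, `n`
#' @export
fit_logistic_newton <- function(X, y, max_iter = 50, tol = 1e-8,
                                strict = TRUE, sep_limit = 15) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("response has a single class")
  cn <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)
  p_all <- ncol(Xd)
  beta <- numeric(p_all)
  beta[1] <- stats::qlogis(mean(y))
  converged <- FALSE
  separated <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- as.vector(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- crossprod(Xd, y - mu)
    info <- crossprod(Xd, Xd * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      if (strict) stop("singular information matrix: rank-deficient design")
      break
    }
    beta <- beta + as.vector(step)
    if (any(abs(beta[-1]) > sep_limit)) {
      separated <- TRUE
      if (strict) {
        worst <- cn[which.max(abs(beta[-1]))]
        stop("complete separation detected (coefficient for '", worst,
             "' diverging); refit without it or use strict = FALSE")
      }
      break
    }
    if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
  }
  eta <- as.vector(Xd %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(Xd, Xd * w)
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p_all, p_all))
  se <- sqrt(pmax(diag(vcov), 0))
  zval <- beta / se
  loglik <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  p0 <- mean(y)
  null_loglik <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  llr_stat <- 2 * (loglik - null_loglik)
  df <- ncol(X)
  names(beta) <- names(se) <- names(zval) <- c("(Intercept)", cn)
  structure(list(
    coef = beta, se = se, z = zval,
    p = 2 * stats::pnorm(-abs(zval)),
    vcov = vcov, loglik = loglik, null_loglik = null_loglik,
    llr_stat = llr_stat,
    llr_p = stats::pchisq(llr_stat, df, lower.tail = FALSE),
    converged = converged, iterations = it, separated = separated,
    n = length(y)
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (Newton), n =", x$n, "\n")
  tab <- data.frame(coef = x$coef, se = x$se, z = x$z, p = x$p)
  print(round(tab, 4))
  cat(sprintf("log-likelihood %.3f (null %.3f), LLR p = %.4g\n",
              x$loglik, x$null_loglik, x$llr_p))
  if (x$separated) cat("NOTE: separation detected; coefficients capped\n")
  invisible(x)
}

#' Predict probabilities from a logistic fit
#' @param object a `logistic_fit`
#' @param newdata numeric matrix on the same (scaled) covariate scale
#' @param ... unused
#' @return predicted probabilities
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  Xd <- cbind(1, as.matrix(newdata))
  stats::plogis(as.vector(Xd %*% object$coef))
}

#' Fit the risk model on a feature table with scaling and odds ratios
#'
#' Z-scales the requested measures (training-data mean/SD), fits by
#' Newton's method, and back-transforms the scaled coefficients to odds
#' ratios per original unit (per ms or per ms/mm) with Wald 95% confidence
#' intervals.
#'
#' @param table feature table with a `group` column
#' @param measures covariate column names
#' @param positive group label treated as the event (default `"HCM_VF"`)
#' @param ... passed to [fit_logistic_newton()]
#' @return a `risk_model_fit`: the `logistic_fit` plus `scaling`
#'   (means/SDs), `or` (odds-ratio table per unscaled unit), `measures`,
#'   `positive`
#' @export
fit_risk_model <- function(table, measures, positive = "HCM_VF", ...) {
  stopifnot(all(measures %in% names(table)))
  X <- as.matrix(table[, measures, drop = FALSE])
  if (anyNA(X)) stop("missing values in fitted columns")
  y <- as.numeric(table$group == positive)
  if (sum(y) < 2L || sum(1 - y) < 2L) stop("need >= 2 subjects per group")
  mu <- colMeans(X); sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant measure cannot be scaled: ",
                          paste(measures[sds == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  fit <- fit_logistic_newton(Z, y, ...)
  b <- fit$coef[-1] / sds
  se_u <- fit$se[-1] / sds
  or <- data.frame(
    measure = measures,
    odds_ratio = exp(b),
    ci_lo = exp(b - 1.96 * se_u),
    ci_hi = exp(b + 1.96 * se_u),
    p = fit$p[-1],
    row.names = NULL
  )
  structure(c(unclass(fit),
              list(scaling = list(mean = mu, sd = sds), or = or,
                   measures = measures, positive = positive)),
            class = c("risk_model_fit", "logistic_fit"))
}

#' Univariate screening of candidate measures
#'
#' Keeps the measures whose two-group Wilcoxon rank-sum p-value is below
#' `alpha`.
#'
#' @inheritParams fit_risk_model
#' @param alpha significance threshold
#' @return character vector of qualifying measures (possibly empty)
#' @export
screen_univariate <- function(table, measures, positive = "HCM_VF",
                              alpha = 0.05) {
  y <- table$group == positive
  keep <- vapply(measures, function(m) {
    wilcoxon_rank_sum(table[[m]][y], table[[m]][!y])$p < alpha
  }, logical(1))
  measures[keep]
}

#' Reject collinear measures
#'
#' For every pair with |Pearson r| at or above `r_threshold`, drops the
#' peak-phase member (recovery-phase measures are retained by convention);
#' when both or neither are peak-phase, the later one in `measures` is
#' dropped. Decisions are recorded in the `dropped` attribute.
#'
#' @inheritParams fit_risk_model
#' @param r_threshold absolute Pearson correlation threshold
#' @return retained measures, with attribute `dropped` (data.frame)
#' @export
drop_collinear <- function(table, measures, r_threshold = 0.9) {
  if (length(measures) < 2L) return(measures)
  kept <- measures
  log <- list()
  repeat {
    if (length(kept) < 2L) break
    R <- stats::cor(as.matrix(table[, kept, drop = FALSE]))
    diag(R) <- 0
    hit <- which(abs(R) == max(abs(R)), arr.ind = TRUE)[1, ]
    if (abs(R[hit[1], hit[2]]) < r_threshold) break
    pair <- kept[hit]
    is_peak <- grepl("^peak_", pair)
    drop <- if (xor(is_peak[1], is_peak[2])) pair[is_peak] else pair[2]
    log[[length(log) + 1L]] <- data.frame(
      dropped = drop, kept = setdiff(pair, drop),
      r = R[hit[1], hit[2]])
    kept <- setdiff(kept, drop)
  }
  attr(kept, "dropped") <- if (length(log)) do.call(rbind, log) else
    data.frame(dropped = character(0), kept = character(0), r = numeric(0))
  kept
}

#' Backward stepwise selection by Wald p-value
#'
#' Iteratively refits after removing the single covariate with the largest
#' Wald p-value exceeding `p_stop`, until every remaining covariate has
#' p <= `p_stop` (or one covariate remains and still fails, in which case
#' the empty model is returned).
#'
#' @inheritParams fit_risk_model
#' @param p_stop retention threshold on the Wald p-value
#' @return list with `fit` (a `risk_model_fit` or NULL), `retained`,
#'   `removal_order`
#' @export
backward_stepwise <- function(table, measures, positive = "HCM_VF",
                              p_stop = 0.15, ...) {
  kept <- measures
  removed <- character(0)
  fit <- NULL
  while (length(kept) >= 1L) {
    fit <- fit_risk_model(table, kept, positive = positive, ...)
    pv <- fit$p[-1]
    if (all(pv <= p_stop)) break
    worst <- kept[which.max(pv)]
    removed <- c(removed, worst)
    kept <- setdiff(kept, worst)
    fit <- NULL
  }
  list(fit = fit, retained = if (is.null(fit)) character(0) else kept,
       removal_order = removed)
}
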