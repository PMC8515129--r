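# Newton/IRLS maximum-likelihood logistic regression on a design matrix.
# Converges on the gradient infinity-norm; detects complete separation
# instead of diverging silently.
logit_newton <- function(X, y, tol = 1e-8, maxit = 100) {
  p <- ncol(X)
  beta <- numeric(p)
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll_old <- ll(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu))
    if (max(abs(grad)) < tol) {
      # a finite gradient zero cannot perfectly separate the classes: if
      # it does, the likelihood is still increasing in |beta| and the MLE
      # does not exist
      if (all((2 * y - 1) * eta > 0))
        stop("non-finite MLE (separation detected)")
      w <- mu * (1 - mu)
      info <- crossprod(X * w, X)
      cov <- tryCatch(solve(info), error = function(e)
        stop("information matrix is singular"))
      return(list(coef = beta, vcov = cov, loglik = ll_old,
                  iterations = it, converged = TRUE))
    }
    if (max(abs(beta)) > 50) {
      signed <- (2 * y - 1) * eta
      if (all(signed > 0))
        stop("non-finite MLE (separation detected)")
    }
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, grad), error = function(e)
      stop("information matrix is singular"))
    # step-halving keeps the likelihood non-decreasing
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- ll(cand)
      if (ll_new >= ll_old - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- cand
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta)
  if (all((2 * y - 1) * eta > 0) && max(abs(beta)) > 10)
    stop("non-finite MLE (separation detected)")
  stop(sprintf(
    "logistic fit did not converge in %d iterations (|grad| = %.3g)",
    maxit, max(abs(drop(crossprod(X, y - stats::plogis(eta)))))))
}

#' Logistic regression with Wald tests
#'
#' Maximum-likelihood logistic regression fitted by Newton/IRLS iterations
#' to a gradient infinity-norm below `tol`, reporting for each variable
#' the coefficient, its standard error from the inverse observed
#' information, the Wald statistic `Coef/S.E.`, and the two-sided normal
#' p-value — the Coef / S.E. / Wald / P layout of univariate and
#' multivariate recurrence-factor tables.
#'
#' In `"univariate"` mode each predictor is fitted separately against the
#' outcome (with intercept); in `"multivariate"` mode all predictors enter
#' one joint model.  Complete separation raises an error rather than
#' returning a divergent fit.
#'
#' @param data data frame holding outcome and predictors.
#' @param outcome name of a binary (0/1 or logical) outcome column; both
#'   classes must be present.
#' @param predictors character vector of numeric predictor columns.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param tol gradient convergence tolerance.
#' @param maxit maximum Newton iterations.
#' @return A data frame of class `logistic_fit` with columns `variable`,
#'   `coef`, `se`, `wald`, `p` (intercept rows omitted in univariate mode,
#'   included as attribute `intercepts`).
#' @export
logistic_fit <- function(data, outcome, predictors,
                         mode = c("multivariate", "univariate"),
                         tol = 1e-8, maxit = 100) {
  mode <- match.arg(mode)
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1 or logical)")
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  miss <- setdiff(predictors, names(data))
  if (length(miss)) stop("predictors not in data: ",
                         paste(miss, collapse = ", "))
  one_fit <- function(vars) {
    cols <- lapply(data[vars], function(v) as.numeric(v))
    keep <- stats::complete.cases(as.data.frame(cols), y)
    X <- cbind(`(Intercept)` = 1,
               as.matrix(as.data.frame(cols))[keep, , drop = FALSE])
    yy <- y[keep]
    if (nrow(X) <= ncol(X))
      stop("need more observations than parameters")
    fit <- logit_newton(X, yy, tol = tol, maxit = maxit)
    se <- sqrt(diag(fit$vcov))
    data.frame(variable = colnames(X), coef = fit$coef, se = se,
               wald = fit$coef / se,
               p = 2 * stats::pnorm(-abs(fit$coef / se)),
               row.names = NULL)
  }
  if (mode == "multivariate") {
    tab <- one_fit(predictors)
    intercepts <- tab[tab$variable == "(Intercept)", ]
    tab <- tab[tab$variable != "(Intercept)", ]
  } else {
    rows <- lapply(predictors, function(v) {
      tab <- one_fit(v)
      cbind(tab[tab$variable == v, ],
            intercept = tab$coef[tab$variable == "(Intercept)"])
    })
    tab <- do.call(rbind, rows)
    intercepts <- tab$intercept
    tab$intercept <- NULL
  }
  rownames(tab) <- NULL
  structure(tab, intercepts = intercepts, mode = mode,
            class = c("logistic_fit", "data.frame"))
}

#' @export
print.logistic_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s logistic regression (Wald tests)\n",
              attr(x, "mode")))
  out <- data.frame(Variable = x$variable,
                    Coef = round(x$coef, digits),
                    S.E. = round(x$se, digits),
                    Wald = round(x$wald, 2),
                    P = signif(x$p, 3))
  print(out, row.names = FALSE)
  invisible(x)
}
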