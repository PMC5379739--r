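#' Logistic regression for adherence-outcome models
#'
#' Maximum-likelihood logistic regression of a binary outcome on an
#' adherence predictor (already scaled to the reporting unit, e.g. 10%
#' steps of an adherence percentage or 1 log10 of a drug concentration),
#' optionally adjusted for baseline covariates. Complete-case: rows with any
#' missing value are dropped. When (quasi-)complete separation is detected,
#' the fit falls back to Firth's bias-reduced penalized likelihood and is
#' flagged, since small event counts make separation likely.
#'
#' @param y binary outcome (0/1 or logical).
#' @param x adherence predictor in reporting units.
#' @param covariates optional data frame of additional model terms.
#' @return list with `coefficients`, `vcov`, `fitted`, `n`, `events`,
#'   `method` (`"ml"` or `"firth"`), `separation` flag and `ok`; or a
#'   degenerate result (`ok = FALSE`, `reason`) when the outcome has a
#'   single class or the predictor is constant.
#' @export
fit_logistic <- function(y, x, covariates = NULL) {
  df <- data.frame(y = as.integer(y), adherence = as.numeric(x))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  events <- sum(df$y)
  if (n == 0 || events == 0 || events == n) {
    return(list(ok = FALSE, reason = "single outcome class", n = n,
                events = events))
  }
  if (length(unique(df$adherence)) < 2) {
    return(list(ok = FALSE, reason = "constant predictor", n = n,
                events = events))
  }
  fit <- suppressWarnings(
    glm(y ~ ., family = binomial(), data = df)
  )
  p <- fit$fitted.values
  separated <- !fit$converged ||
    any(abs(coef(fit)[-1]) > 15, na.rm = TRUE) ||
    (all(p[df$y == 1] > 1 - 1e-6) && all(p[df$y == 0] < 1e-6))
  if (separated) {
    X <- stats::model.matrix(y ~ ., data = df)
    firth <- firth_logistic(X, df$y)
    return(list(ok = TRUE, coefficients = firth$coefficients,
                vcov = firth$vcov, fitted = firth$fitted, n = n,
                events = events, method = "firth", separation = TRUE))
  }
  list(ok = TRUE, coefficients = coef(fit), vcov = vcov(fit),
       fitted = unname(p), n = n, events = events, method = "ml",
       separation = FALSE)
}

#' Firth bias-reduced logistic regression
#'
#' Newton-Raphson on the Firth-penalized score
#' \eqn{U^*(\beta) = X'(y - p + h(1/2 - p))}, where `h` holds the diagonal
#' of the logistic hat matrix. The penalty (Jeffreys prior) keeps estimates
#' finite under complete separation.
#'
#' @param X model matrix (including intercept).
#' @param y binary response vector.
#' @param max_iter,tol Newton iteration controls.
#' @return list with `coefficients`, `vcov` (inverse penalized information),
#'   `fitted` and `iterations`.
#' @export
firth_logistic <- function(X, y, max_iter = 200, tol = 1e-8) {
  # ridge-guarded solve: near-singular information (tiny weights during the
  # iteration, or collinear small cells) gets a small diagonal inflation
  safe_solve <- function(A, b = diag(ncol(A))) {
    tryCatch(solve(A, b),
             error = function(e) solve(A + diag(1e-6, ncol(A)), b))
  }
  beta <- rep(0, ncol(X))
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    info_inv <- safe_solve(info)
    h <- rowSums((XW %*% info_inv) * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(info_inv %*% score)
    # damp overshooting steps so the penalized iteration stays stable
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  w <- pmax(p * (1 - p), 1e-10)
  info <- crossprod(X * sqrt(w))
  vc <- safe_solve(info)
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(coefficients = setNames(beta, colnames(X)), vcov = vc,
       fitted = p, iterations = iter)
}

#' Odds ratio (per reporting unit) from a fitted model
#'
#' Wald odds ratio, 95% CI and p-value for the adherence coefficient of a
#' [fit_logistic()] result. With the predictor pre-scaled to 10%-units this
#' is the odds ratio per 10% adherence increase.
#'
#' @param fit result of [fit_logistic()].
#' @param term coefficient name (default `"adherence"`).
#' @return one-row tibble: `or`, `or_lcl`, `or_ucl`, `p`, `beta`, `se`.
#' @export
or_from_fit <- function(fit, term = "adherence") {
  if (!isTRUE(fit$ok)) {
    return(tibble::tibble(or = NA_real_, or_lcl = NA_real_, or_ucl = NA_real_,
                          p = NA_real_, beta = NA_real_, se = NA_real_))
  }
  beta <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  z <- beta / se
  tibble::tibble(or = exp(beta),
                 or_lcl = exp(beta - qnorm(0.975) * se),
                 or_ucl = exp(beta + qnorm(0.975) * se),
                 p = 2 * pnorm(-abs(z)), beta = beta, se = se)
}
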