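#' Specify a correlate model
#'
#' Declares the outcome, covariates and family of a correlate regression.
#' Process quality (NRQE) is modelled with ordinary least squares; the
#' binary outcomes (correct diagnosis, correct treatment) with logistic
#' regression, reported as average marginal effects. NRQE is allowed as a
#' covariate only for the binary outcomes; tier enters as indicator
#' variables with the village clinic (VC) as reference.
#'
#' @param outcome one of `"nrqe"`, `"correct_diagnosis"`,
#'   `"correct_treatment"`.
#' @param covariates character vector of covariate column names.
#' @param family `"linear"` or `"logistic"`; defaults to linear for `nrqe`
#'   and logistic otherwise.
#' @return an object of class `sp_model_spec`.
#' @export
model_spec <- function(outcome = c("nrqe", "correct_diagnosis", "correct_treatment"),
                       covariates,
                       family = NULL) {
  outcome <- match.arg(outcome)
  family <- family %||% if (outcome == "nrqe") "linear" else "logistic"
  if (!family %in% c("linear", "logistic")) stop_sp("unknown family '%s'", family)
  if (outcome == "nrqe" && family == "logistic") stop_sp("nrqe is a count outcome; use family='linear'")
  if ("nrqe" %in% covariates && family != "logistic") {
    stop_sp("nrqe is allowed as a covariate only for binary outcomes")
  }
  structure(list(outcome = outcome, covariates = covariates, family = family),
            class = "sp_model_spec")
}

build_design <- function(data, covariates) {
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    if (cv == "tier") {
      tier <- as_tier(data$tier)
      X <- cbind(X, tierTHC = as.numeric(tier == "THC"),
                 tierCH = as.numeric(tier == "CH"))
    } else {
      if (!cv %in% names(data)) stop_sp("covariate '%s' not in data", cv)
      X <- cbind(X, as.numeric(data[[cv]]))
      colnames(X)[ncol(X)] <- cv
    }
  }
  X
}

check_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_sp("design matrix is rank deficient; collinear column(s): %s",
            paste(drop, collapse = ", "))
  }
  const <- apply(X[, -1, drop = FALSE], 2, function(c) length(unique(c)) == 1)
  if (any(const)) stop_sp("constant covariate(s): %s",
                          paste(names(const)[const], collapse = ", "))
  invisible(TRUE)
}

#' Fit an ordinary least squares correlate model
#'
#' Least-squares coefficients with conventional homoskedastic Wald 95%
#' confidence intervals, as used for the consultation-process outcome
#' (NRQE).
#'
#' @param data data.frame containing the outcome and covariates.
#' @param spec an [model_spec()] with `family = "linear"`, or a character
#'   vector of covariates (then `outcome` must be given).
#' @param outcome outcome column when `spec` is a covariate vector.
#' @return an object of class `sp_fit`: a list with a `coefficients`
#'   data.frame (`term`, `estimate`, `se`, `conf_low`, `conf_high`,
#'   `p_value`), `n`, `family`, `converged`.
#' @export
fit_linear <- function(data, spec, outcome = NULL) {
  if (inherits(spec, "sp_model_spec")) {
    stopifnot(spec$family == "linear")
    outcome <- spec$outcome
    covariates <- spec$covariates
  } else covariates <- spec
  y <- as.numeric(data[[outcome]])
  keep <- stats::complete.cases(data[, intersect(c(outcome, covariates, "tier"), names(data))])
  data <- data[keep, ]
  y <- y[keep]
  X <- build_design(data, covariates)
  if (nrow(X) <= ncol(X)) stop_sp("need n > number of coefficients (%d)", ncol(X))
  check_rank(X)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
  tcrit <- stats::qt(0.975, df)
  tval <- ifelse(se > 0, beta / se, Inf * sign(beta))
  out <- data.frame(term = colnames(X), estimate = unname(beta), se = se,
                    conf_low = beta - tcrit * se, conf_high = beta + tcrit * se,
                    p_value = 2 * stats::pt(-abs(tval), df),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(coefficients = out, ame = NULL, n = nrow(X),
                 family = "linear", converged = TRUE),
            class = "sp_fit")
}

logistic_mu <- function(eta) stats::plogis(eta)

## average marginal effect of each covariate and its delta-method SE
compute_ame <- function(X, beta, vcov, binary_cols) {
  terms <- setdiff(colnames(X), "(Intercept)")
  ame <- se <- numeric(length(terms))
  names(ame) <- names(se) <- terms
  for (j in seq_along(terms)) {
    tm <- terms[j]
    k <- match(tm, colnames(X))
    if (tm %in% binary_cols) {
      X1 <- X0 <- X
      X1[, k] <- 1; X0[, k] <- 0
      p1 <- logistic_mu(drop(X1 %*% beta)); p0 <- logistic_mu(drop(X0 %*% beta))
      ame[j] <- mean(p1 - p0)
      grad <- colMeans(X1 * (p1 * (1 - p1)) - X0 * (p0 * (1 - p0)))
    } else {
      eta <- drop(X %*% beta)
      p <- logistic_mu(eta)
      lam <- p * (1 - p)
      ame[j] <- mean(lam) * beta[k]
      ## d/d beta_m [ mean(lam) * beta_k ] = mean(lam') X_m beta_k + 1{m=k} mean(lam)
      grad <- colMeans(X * (lam * (1 - 2 * p))) * beta[k]
      grad[k] <- grad[k] + mean(lam)
    }
    se[j] <- sqrt(drop(t(grad) %*% vcov %*% grad))
  }
  data.frame(term = terms, ame = unname(ame), se = unname(se),
             conf_low = ame - 1.96 * se, conf_high = ame + 1.96 * se,
             stringsAsFactors = FALSE)
}

#' Fit a logistic correlate model with average marginal effects
#'
#' Maximum-likelihood logit coefficients (via [stats::glm()]) with Wald 95%
#' intervals, plus the average marginal effect (AME) of every covariate: the
#' sample mean of the derivative of the predicted probability for continuous
#' covariates, or of the discrete 0-to-1 contrast for binary covariates,
#' with delta-method 95% intervals. Errors on single-class outcomes, perfect
#' separation, and non-convergence.
#'
#' @inheritParams fit_linear
#' @param max_iter maximum IRLS iterations.
#' @return an `sp_fit` with an additional `ame` data.frame (`term`, `ame`,
#'   `se`, `conf_low`, `conf_high`).
#' @export
fit_logistic_ame <- function(data, spec, outcome = NULL, max_iter = 100) {
  if (inherits(spec, "sp_model_spec")) {
    stopifnot(spec$family == "logistic")
    outcome <- spec$outcome
    covariates <- spec$covariates
  } else covariates <- spec
  y <- as.numeric(data[[outcome]])
  keep <- !is.na(y) & stats::complete.cases(
    data[, intersect(c(covariates, "tier"), names(data)), drop = FALSE])
  data <- data[keep, ]
  y <- y[keep]
  if (!all(y %in% c(0, 1))) stop_sp("outcome '%s' is not binary", outcome)
  if (length(unique(y)) < 2) stop_sp("outcome '%s' has a single class", outcome)
  X <- build_design(data, covariates)
  check_rank(X)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(maxit = max_iter)))
  if (!fit$converged) stop_sp("logistic fit did not converge in %d iterations", max_iter)
  p <- fit$fitted.values
  if (any(p > 1 - 1e-10) || any(p < 1e-10) || any(abs(fit$coefficients) > 15)) {
    stop_sp("perfect or quasi-perfect separation detected (fitted probabilities at 0/1)")
  }
  beta <- fit$coefficients
  W <- p * (1 - p)
  vcov <- chol2inv(chol(crossprod(X * sqrt(W))))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  z <- beta / se
  coefs <- data.frame(term = colnames(X), estimate = unname(beta), se = unname(se),
                      conf_low = beta - 1.96 * se, conf_high = beta + 1.96 * se,
                      p_value = 2 * stats::pnorm(-abs(z)),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  binary_cols <- colnames(X)[vapply(seq_len(ncol(X)), function(k) {
    all(X[, k] %in% c(0, 1)) && colnames(X)[k] != "(Intercept)"
  }, logical(1))]
  ame <- compute_ame(X, beta, vcov, binary_cols)
  structure(list(coefficients = coefs, ame = ame, n = nrow(X),
                 family = "logistic", converged = fit$converged),
            class = "sp_fit")
}

#' @export
print.sp_fit <- function(x, ...) {
  cat(sprintf("<sp_fit> %s model, n = %d\n", x$family, x$n))
  print(x$coefficients, row.names = FALSE, digits = 4)
  if (!is.null(x$ame)) {
    cat("average marginal effects:\n")
    print(x$ame, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Standardize and transform raw covariates for the correlate models
#'
#' Conventions used by the packaged model layouts: income enters as a
#' z-score (scale-free coefficient), patient volume as `log2(count + 1)`
#' (per-doubling interpretation), and age as an at-or-above-median contrast.
#'
#' @param providers provider table.
#' @param age_binary if TRUE (default), code age as `age >= median(age)`.
#' @return the table with added columns `income_z`, `log_patients`,
#'   `older`.
#' @export
prepare_correlates <- function(providers, age_binary = TRUE) {
  providers$income_z <- as.numeric(scale(providers$income))
  providers$log_patients <- log2(providers$diabetes_patients_2wk + 1)
  providers$older <- if (age_binary) {
    as.numeric(providers$age >= stats::median(providers$age))
  } else providers$age
  providers
}
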