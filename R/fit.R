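#' Maximum-likelihood logistic regression on a raw design matrix
#'
#' Fits by iteratively reweighted least squares (via [stats::glm.fit()])
#' followed by Newton polishing with step halving until the Euclidean norm
#' of the score vector falls below `tol`, and retains the per-observation
#' quantities that non-nested model comparison needs: log-likelihood
#' contributions, score (gradient) contributions, and the observed
#' information at the optimum. Complete or quasi-complete separation is a
#' hard error -- every downstream comparison statistic requires finite
#' per-observation log-likelihoods.
#'
#' @param x Numeric model matrix (including the intercept column).
#' @param y 0/1 outcome vector.
#' @param tol Convergence tolerance on the Euclidean score norm
#'   (default 1e-8).
#' @param maxit Maximum number of iterations (default 100).
#' @return A list with `coefficients`, `se`, `vcov`, `fitted`,
#'   `loglik_total`, `loglik_i`, `score_i` (n x k), `hessian` (k x k
#'   observed information, i.e. negative Hessian of the log-likelihood),
#'   `n`, `k`, `converged`.
#' @export
#' @examples
#' x <- cbind(1, c(rep(1, 30), rep(0, 30)))
#' y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
#' fit_logistic(x, y)$coefficients[2]  # log odds ratio of the 2x2 table
fit_logistic <- function(x, y, tol = 1e-8, maxit = 100L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("length(y) != nrow(x)", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1", call. = FALSE)
  if (all(y == 0) || all(y == 1))
    stop("degenerate outcome (all ", y[1],
         "); the logistic MLE does not exist", call. = FALSE)

  g <- suppressWarnings(stats::glm.fit(
    x, y, family = stats::binomial(),
    control = list(epsilon = 1e-12, maxit = maxit)))
  beta <- g$coefficients
  if (anyNA(beta))
    stop("rank-deficient design in fit; aliased: ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)

  loglik <- function(b) {
    eta <- drop(x %*% b)
    # numerically stable Bernoulli log-likelihood
    sum(stats::dbinom(y, 1, stats::plogis(eta), log = TRUE))
  }
  ll <- loglik(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    p <- stats::plogis(drop(x %*% beta))
    grad <- drop(crossprod(x, y - p))
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), .Machine$double.eps)
    info <- crossprod(x, x * w)
    step <- tryCatch(solve(info, grad), error = function(e)
      stop("singular information matrix during Newton polishing: ",
           conditionMessage(e), call. = FALSE))
    # halve the step until the log-likelihood does not decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    ll <- loglik(beta)
  }
  p <- stats::plogis(drop(x %*% beta))
  grad <- drop(crossprod(x, y - p))
  if (!converged && sqrt(sum(grad^2)) >= tol)
    stop("logistic fit did not converge: score norm ",
         format(sqrt(sum(grad^2))), " after ", maxit, " iterations",
         call. = FALSE)
  w <- pmax(p * (1 - p), .Machine$double.eps)
  info <- crossprod(x, x * w)
  vc <- tryCatch(solve(info), error = function(e)
    stop("singular observed information at the optimum", call. = FALSE))
  se <- sqrt(diag(vc))
  big <- abs(beta) > 15 & se > 10
  if (any(big))
    stop("complete or quasi-complete separation detected (|beta| > 15 with ",
         "exploding SE) for: ", paste(colnames(x)[big], collapse = ", "),
         call. = FALSE)
  list(
    coefficients = stats::setNames(as.numeric(beta), colnames(x)),
    se = stats::setNames(se, colnames(x)),
    vcov = vc,
    fitted = p,
    loglik_total = sum(stats::dbinom(y, 1, p, log = TRUE)),
    loglik_i = stats::dbinom(y, 1, p, log = TRUE),
    score_i = x * (y - p),
    hessian = info,
    n = nrow(x), k = ncol(x),
    converged = TRUE
  )
}

#' Fit a logistic model for an ACE predictor characterization
#'
#' The central fitting function. Given either a ready [build_design()]
#' object or a [predictor_spec()] plus data (in which case the design is
#' built internally), it maximizes the Bernoulli likelihood and returns a
#' classed fit carrying the per-observation log-likelihood, score and
#' observed-information contributions required by [vuong_compare()].
#'
#' @param object An `"ace_design"`, a `"predictor_spec"` (or
#'   NULL/"baseline" for the covariate-only model), or a raw numeric model
#'   matrix, in which case `data` must be the 0/1 outcome vector.
#' @param data,outcome,covariates Passed to [build_design()] when `object`
#'   is a spec; the outcome vector when `object` is a matrix.
#' @param label Display label for raw-matrix fits.
#' @param ... Passed to [fit_logistic()] (`tol`, `maxit`).
#' @return An object of class `"ace_fit"`.
#' @export
#' @examples
#' cfg <- ace_sim_config(n = 500, truth = truth_spec("cr_linear",
#'   intercept = -1, score_beta = 0.2), seed = 11)
#' d <- simulate_ace_data(cfg)
#' fit <- ace_logit(predictor_spec("CRCn"), data = d)
#' coef(fit)["ace_score"]
ace_logit <- function(object, data = NULL, outcome = "outcome",
                      covariates = ace_covariates(), label = NULL, ...) {
  design <- if (inherits(object, "ace_design")) {
    object
  } else if (is.matrix(object)) {
    x <- object
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    structure(list(
      y = as.numeric(data), x = x, n = nrow(x), k = ncol(x), spec = NULL,
      label = label %||% "custom design", ace_cols = integer(0),
      score = NULL, outcome = NA_character_, covariates = character(0)
    ), class = "ace_design")
  } else {
    build_design(object, data, outcome = outcome, covariates = covariates)
  }
  f <- fit_logistic(design$x, design$y, ...)
  structure(c(f, list(
    x = design$x, y = design$y,
    spec = design$spec, label = design$label,
    ace_cols = design$ace_cols, score = design$score,
    outcome = design$outcome, covariates = design$covariates
  )), class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, digits = 4, ...) {
  cat("Logistic fit:", x$label, "\n")
  cat("  n =", x$n, " k =", x$k,
      " logLik =", formatC(x$loglik_total, format = "f", digits = 2),
      " AIC =", formatC(-2 * x$loglik_total + 2 * x$k, format = "f", digits = 2),
      "\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.ace_fit <- function(object, ...) object$coefficients

#' @export
vcov.ace_fit <- function(object, ...) object$vcov

#' @export
logLik.ace_fit <- function(object, ...) {
  structure(object$loglik_total, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
predict.ace_fit <- function(object, newx = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newx)) drop(object$x %*% object$coefficients)
         else drop(as.matrix(newx) %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.ace_fit <- function(object,
                              type = c("deviance", "pearson", "response"),
                              ...) {
  type <- match.arg(type)
  y <- object$y; p <- object$fitted
  switch(type,
    response = y - p,
    pearson = (y - p) / sqrt(p * (1 - p)),
    deviance = sign(y - p) * sqrt(-2 * object$loglik_i)
  )
}

#' @export
simulate.ace_fit <- function(object, nsim = 1, seed = NULL, ...) {
  out <- with_seed(seed, replicate(nsim,
    stats::rbinom(object$n, 1L, object$fitted), simplify = FALSE))
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
summary.ace_fit <- function(object, conf_level = 0.95, ...) {
  z <- object$coefficients / object$se
  pv <- 2 * stats::pnorm(-abs(z))
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    estimate = object$coefficients,
    se = object$se,
    z = z,
    p_value = pv,
    or = exp(object$coefficients),
    or_low = exp(object$coefficients - q * object$se),
    or_high = exp(object$coefficients + q * object$se)
  )
  structure(list(label = object$label, n = object$n, k = object$k,
                 loglik = object$loglik_total,
                 aic = -2 * object$loglik_total + 2 * object$k,
                 coefficients = tab, conf_level = conf_level),
            class = "summary.ace_fit")
}

#' @export
print.summary.ace_fit <- function(x, digits = 4, ...) {
  cat("Logistic fit:", x$label, "\n")
  cat("  n =", x$n, " k =", x$k,
      " logLik =", formatC(x$loglik, format = "f", digits = 2),
      " AIC =", formatC(x$aic, format = "f", digits = 2), "\n\n")
  tab <- x$coefficients
  tab$stars <- sig_stars(tab$p_value)
  print(cbind(round(tab[, 1:7], digits), stars = tab$stars))
  invisible(x)
}

#' Forest-style plot of odds ratios
#'
#' Plots point estimates and Wald confidence intervals for the ACE
#' predictor columns (all non-intercept columns when the fit has none) on
#' the odds-ratio scale, log-spaced, with a reference line at OR = 1.
#'
#' @param x An `"ace_fit"`.
#' @param conf_level Confidence level for the intervals.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.ace_fit <- function(x, conf_level = 0.95, ...) {
  idx <- if (length(x$ace_cols)) x$ace_cols else seq_along(x$coefficients)[-1]
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  or <- exp(x$coefficients[idx])
  lo <- exp(x$coefficients[idx] - q * x$se[idx])
  hi <- exp(x$coefficients[idx] + q * x$se[idx])
  yy <- rev(seq_along(idx))
  graphics::plot(or, yy, xlim = range(c(lo, hi, 1)), log = "x",
                 pch = 19, yaxt = "n", xlab = "Odds ratio", ylab = "",
                 main = x$label, ...)
  graphics::segments(lo, yy, hi, yy)
  graphics::abline(v = 1, lty = 2)
  graphics::axis(2, at = yy, labels = names(or), las = 1, cex.axis = 0.7)
  invisible(x)
}
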