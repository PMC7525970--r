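#' Per-observation log-likelihood ratio between two fits
#'
#' `m_i = loglik_i(a) - loglik_i(b)`, the pointwise Kullback-Leibler-type
#' contrast on which both steps of the Vuong procedure operate. The two
#' fits must be on identical rows and outcomes.
#'
#' @param fit_a,fit_b [ace_logit()] fits on the same data rows.
#' @return Numeric vector of length n; its sum equals the difference of the
#'   total log-likelihoods.
#' @export
pointwise_llr <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "ace_fit"), inherits(fit_b, "ace_fit"))
  if (fit_a$n != fit_b$n || !isTRUE(all.equal(fit_a$y, fit_b$y)))
    stop("fits are not on identical rows/outcomes", call. = FALSE)
  fit_a$loglik_i - fit_b$loglik_i
}

#' Tail probability of a positively weighted sum of chi-square(1) variables
#'
#' `P(sum_j w_j X_j >= q)` with `X_j ~ iid chi-square(1)`. Two methods:
#' seeded Monte Carlo (robust, the default for the distinguishability
#' test), and Imhof-type numerical inversion of the characteristic
#' function, used as a fast deterministic cross-check.
#'
#' @param q Non-negative quantile.
#' @param weights Non-negative weights (zeros are dropped).
#' @param method `"mc"` or `"imhof"`.
#' @param mc_draws Monte Carlo sample size (default 1e6).
#' @param seed Optional seed for the Monte Carlo draws; NULL uses the
#'   current RNG stream.
#' @return Tail probability in `[0, 1]`.
#' @export
weighted_chisq_tail <- function(q, weights, method = c("mc", "imhof"),
                                mc_draws = 1e6, seed = NULL) {
  method <- match.arg(method)
  weights <- weights[weights > 1e-12 * max(weights, 0)]
  if (!length(weights)) return(as.numeric(q <= 0))
  if (q <= 0) return(1)
  if (method == "mc") {
    with_seed(seed, {
      acc <- numeric(mc_draws)
      for (w in weights) acc <- acc + w * stats::rchisq(mc_draws, df = 1)
      mean(acc >= q)
    })
  } else {
    integrand <- function(u) {
      th <- 0.5 * colSums(atan(outer(weights, u))) - 0.5 * q * u
      lrho <- 0.25 * colSums(log1p(outer(weights^2, u^2)))
      out <- sin(th) / (u * exp(lrho))
      # limit as u -> 0 is (sum(w) - q)/2
      out[u == 0] <- (sum(weights) - q) / 2
      out
    }
    val <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                            subdivisions = 2000L, stop.on.error = FALSE)$value
    min(max(0.5 + val / pi, 0), 1)
  }
}

vuong_lambda <- function(fit_a, fit_b) {
  n <- fit_a$n
  A_a <- -fit_a$hessian / n        # mean Hessian of the log-likelihood
  A_b <- -fit_b$hessian / n
  B_a <- crossprod(fit_a$score_i) / n
  B_b <- crossprod(fit_b$score_i) / n
  B_ab <- crossprod(fit_a$score_i, fit_b$score_i) / n
  Ainv_a <- tryCatch(solve(A_a), error = function(e)
    stop("singular mean Hessian for model '", fit_a$label, "'", call. = FALSE))
  Ainv_b <- tryCatch(solve(A_b), error = function(e)
    stop("singular mean Hessian for model '", fit_b$label, "'", call. = FALSE))
  W <- rbind(
    cbind(-B_a %*% Ainv_a, -B_ab %*% Ainv_b),
    cbind(t(B_ab) %*% Ainv_a, B_b %*% Ainv_b)
  )
  ev <- eigen(W, only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-6 * max(abs(ev), 1))
    warning("distinguishability matrix has non-negligible complex eigenvalues;",
            " using real parts", call. = FALSE)
  Re(ev)
}

#' Step one: the variance (distinguishability) test
#'
#' Tests whether the population variance of the per-observation
#' log-likelihood differences is zero -- i.e. whether the two models are
#' distinguishable at all. The statistic is `n * omega2_hat` with
#' `omega2_hat = mean(m^2) - mean(m)^2`; its null distribution is the
#' weighted sum `sum_j lambda_j^2 chisq_1`, where the `lambda_j` are the
#' eigenvalues of the (k_a + k_b) square matrix assembled from the models'
#' mean score cross-products and mean Hessians.
#'
#' @param fit_a,fit_b [ace_logit()] fits on identical rows.
#' @param method Tail evaluation: `"mc"` (seeded Monte Carlo, default) or
#'   `"imhof"` (numerical inversion).
#' @param mc_draws,seed Passed to [weighted_chisq_tail()].
#' @return An object of class `"vuong_variance_test"`: list with `omega2`
#'   (variance estimate), `stat` (`n * omega2`), `lambda` (eigenvalue
#'   weights before squaring), `p_value`, `n`, `method`.
#' @export
vuong_variance_test <- function(fit_a, fit_b, method = c("mc", "imhof"),
                                mc_draws = 1e6, seed = NULL) {
  method <- match.arg(method)
  m <- pointwise_llr(fit_a, fit_b)
  n <- length(m)
  omega2 <- mean(m^2) - mean(m)^2
  stat <- n * omega2
  lambda <- vuong_lambda(fit_a, fit_b)
  p <- if (omega2 < 1e-14) 1 else
    weighted_chisq_tail(stat, lambda^2, method = method,
                        mc_draws = mc_draws, seed = seed)
  structure(list(omega2 = omega2, stat = stat, lambda = lambda,
                 p_value = p, n = n, method = method),
            class = "vuong_variance_test")
}

#' @export
print.vuong_variance_test <- function(x, ...) {
  cat("Vuong variance (distinguishability) test\n")
  cat("  omega2 =", format(x$omega2), " n*omega2 =", format(x$stat),
      " p =", format.pval(x$p_value), " (", x$method, " tail)\n")
  invisible(x)
}

#' Step two: the closeness z-test
#'
#' Only meaningful for models that step one declared distinguishable:
#' `z = sum(m_i) / (sqrt(n) * omega_hat)` is asymptotically standard normal
#' under equal closeness of the two models to the truth; the two-sided p
#' comes from the normal. Positive `z` favors `fit_a` (the "column" model
#' in comparison-matrix layouts); swapping the fits flips the sign.
#'
#' @param fit_a,fit_b [ace_logit()] fits on identical rows.
#' @return List with `z`, `p_value`, `lr` (summed log-likelihood ratio),
#'   `omega2`, of class `"vuong_closeness_test"`.
#' @export
vuong_closeness_test <- function(fit_a, fit_b) {
  m <- pointwise_llr(fit_a, fit_b)
  n <- length(m)
  omega2 <- mean(m^2) - mean(m)^2
  if (omega2 < 1e-14)
    stop("omega-hat is zero; the closeness test is undefined ",
         "(the variance test should have stopped the procedure)",
         call. = FALSE)
  z <- sum(m) / (sqrt(n) * sqrt(omega2))
  structure(list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 lr = sum(m), omega2 = omega2, n = n),
            class = "vuong_closeness_test")
}

#' @export
print.vuong_closeness_test <- function(x, ...) {
  cat("Vuong closeness test: z =", fmt_num(x$z, 3),
      " p =", format.pval(x$p_value), "\n")
  invisible(x)
}

#' Two-step Vuong comparison of two (partially) non-nested fits
#'
#' Runs the variance/distinguishability test; if it does not reject at
#' `alpha` the models are declared `indistinguishable` and the closeness
#' test is suppressed. Otherwise the closeness z-test decides: significant
#' positive `z` gives verdict `a_better`, significant negative `z` gives
#' `b_better`, and a non-significant `z` gives `distinguishable_equal_fit`
#' (reported as "NDF", non-different fit, in matrix layouts).
#'
#' Nested pairs (e.g. a covariate-only baseline against an ACE model) can
#' be pushed through the same machinery with `nested = TRUE`, which adds a
#' classical likelihood-ratio chi-square for reference and emits a warning
#' that the non-nested asymptotics are a convention for such pairs.
#'
#' @param fit_a,fit_b [ace_logit()] fits on identical rows. `fit_a` plays
#'   the "column" role: positive z favors it.
#' @param alpha Two-sided significance level for both steps (default 0.05).
#' @param method,mc_draws,seed Tail evaluation controls, see
#'   [vuong_variance_test()].
#' @param nested Set TRUE when one model nests the other.
#' @return An object of class `"vuong_comparison"`.
#' @export
#' @examples
#' cfg <- ace_sim_config(n = 800, truth = truth_spec("cr_linear",
#'   intercept = -1, score_beta = 0.25), seed = 5)
#' d <- simulate_ace_data(cfg)
#' fa <- ace_logit(predictor_spec("CRCn"), data = d)
#' fb <- ace_logit(predictor_spec("MIR"), data = d)
#' vuong_compare(fa, fb, method = "imhof")
vuong_compare <- function(fit_a, fit_b, alpha = 0.05,
                          method = c("mc", "imhof"), mc_draws = 1e6,
                          seed = NULL, nested = FALSE) {
  method <- match.arg(method)
  vt <- vuong_variance_test(fit_a, fit_b, method = method,
                            mc_draws = mc_draws, seed = seed)
  m <- pointwise_llr(fit_a, fit_b)
  z <- NA_real_; p_z <- NA_real_
  if (vt$p_value < alpha) {
    ct <- vuong_closeness_test(fit_a, fit_b)
    z <- ct$z; p_z <- ct$p_value
    verdict <- if (p_z < alpha) {
      if (z > 0) "a_better" else "b_better"
    } else "distinguishable_equal_fit"
  } else {
    verdict <- "indistinguishable"
  }
  lrt <- NULL
  if (nested) {
    warning("nested pair compared with the non-nested two-step procedure ",
            "(convention for partially non-nested tables); a classical ",
            "likelihood-ratio test is reported alongside", call. = FALSE)
    big <- if (fit_a$k >= fit_b$k) fit_a else fit_b
    small <- if (fit_a$k >= fit_b$k) fit_b else fit_a
    lr_stat <- 2 * (big$loglik_total - small$loglik_total)
    df <- big$k - small$k
    lrt <- list(stat = lr_stat, df = df,
                p_value = stats::pchisq(lr_stat, df, lower.tail = FALSE),
                larger = big$label)
  }
  structure(list(
    model_a = fit_a$label, model_b = fit_b$label,
    lr = sum(m), omega2 = vt$omega2, omega_stat = vt$stat,
    lambda = vt$lambda, p_omega = vt$p_value,
    z = z, p_z = p_z, alpha = alpha, verdict = verdict,
    nested = nested, lrt = lrt, method = method,
    aic_a = -2 * fit_a$loglik_total + 2 * fit_a$k,
    aic_b = -2 * fit_b$loglik_total + 2 * fit_b$k
  ), class = "vuong_comparison")
}

#' @export
print.vuong_comparison <- function(x, ...) {
  cat("Two-step Vuong comparison (alpha =", x$alpha, ")\n")
  cat("  A:", x$model_a, "\n  B:", x$model_b, "\n")
  cat("  Step 1 (distinguishability): n*omega2 =", fmt_num(x$omega_stat, 3),
      sig_stars(x$p_omega), " p =", format.pval(x$p_omega), "\n")
  if (!is.na(x$z)) {
    cat("  Step 2 (closeness): z =", fmt_num(x$z, 3), sig_stars(x$p_z),
        " p =", format.pval(x$p_z),
        " (positive z favors A)\n")
  } else {
    cat("  Step 2 suppressed: models not distinguishable\n")
  }
  cat("  Verdict:", x$verdict, "\n")
  if (!is.null(x$lrt))
    cat("  Nested LRT: chisq =", fmt_num(x$lrt$stat, 2), "df =", x$lrt$df,
        " p =", format.pval(x$lrt$p_value), "\n")
  invisible(x)
}
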