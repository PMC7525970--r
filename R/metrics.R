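#' Concordance statistic (c-statistic / AUC)
#'
#' Fraction of (case, non-case) pairs in which the case receives the higher
#' predicted probability, ties counted one half. Computed through midranks,
#' which is algebraically identical to exhaustive pair enumeration with
#' half-credit ties (the Mann-Whitney formulation).
#'
#' @param pred Numeric predictions (any strictly increasing transform gives
#'   the same value).
#' @param y 0/1 outcomes; both classes must be present.
#' @return The concordance statistic in `[0, 1]`.
#' @export
#' @examples
#' c_statistic(c(0.9, 0.8, 0.7, 0.4, 0.2), c(1, 1, 0, 1, 0))  # 5/6
c_statistic <- function(pred, y) {
  stopifnot(length(pred) == length(y))
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present", call. = FALSE)
  r <- rank(pred, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Descriptive fit metrics for a logistic model
#'
#' Computes the three descriptive indices used to compare candidate models:
#' AIC (`-2 logLik + 2k`), Nagelkerke pseudo R-squared (Cox-Snell
#' `1 - exp(2 (l0 - l1) / n)` rescaled by its maximum `1 - exp(2 l0 / n)`),
#' and the concordance statistic. For MIR fits the range of variance
#' inflation factors over the ACE columns is included.
#'
#' @param fit An [ace_logit()] fit.
#' @param null_fit The intercept-plus-nothing fit on the same rows (the
#'   null model for the pseudo R-squared), from [null_logit()].
#' @return An object of class `"fit_metrics"`: list with `aic`,
#'   `r2_cox_snell`, `r2_nagelkerke`, `c_stat`, and `vif_range` (MIR only,
#'   otherwise NULL).
#' @export
fit_metrics <- function(fit, null_fit) {
  stopifnot(inherits(fit, "ace_fit"), inherits(null_fit, "ace_fit"))
  if (fit$n != null_fit$n || !isTRUE(all.equal(fit$y, null_fit$y)))
    stop("fit and null_fit are not on the same rows/outcome", call. = FALSE)
  n <- fit$n
  l1 <- fit$loglik_total
  l0 <- null_fit$loglik_total
  cs <- 1 - exp(2 * (l0 - l1) / n)
  nk <- cs / (1 - exp(2 * l0 / n))
  vr <- if (!is.null(fit$spec) && fit$spec$family == "MIR")
    range(vif_ace(fit)) else NULL
  structure(list(
    aic = -2 * l1 + 2 * fit$k,
    r2_cox_snell = cs,
    r2_nagelkerke = nk,
    c_stat = c_statistic(fit$fitted, fit$y),
    vif_range = vr
  ), class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat("AIC =", formatC(x$aic, format = "f", digits = 2),
      " Nagelkerke R2 =", fmt_num(x$r2_nagelkerke),
      " c-stat =", fmt_num(x$c_stat), "\n")
  if (!is.null(x$vif_range))
    cat("VIF range (ACE columns):", fmt_num(x$vif_range[1], 2), "-",
        fmt_num(x$vif_range[2], 2), "\n")
  invisible(x)
}

#' Intercept-only logistic fit on the rows of an existing fit or dataset
#'
#' @param y 0/1 outcome vector, or an `"ace_fit"` whose rows to reuse.
#' @return An `"ace_fit"` with a single intercept column.
#' @export
null_logit <- function(y) {
  if (inherits(y, "ace_fit")) y <- y$y
  design <- structure(list(
    y = as.numeric(y), x = cbind(`(Intercept)` = rep(1, length(y))),
    n = length(y), k = 1L, spec = NULL, label = "Intercept only",
    ace_cols = integer(0), score = NULL, outcome = NA_character_,
    covariates = character(0)
  ), class = "ace_design")
  ace_logit(design)
}

#' Variance inflation factors for the ACE predictor columns
#'
#' For each ACE column `j` of the design, `VIF_j = 1 / (1 - R2_j)` where
#' `R2_j` is from the least-squares regression of column `j` on all other
#' design columns (covariate dummies plus the other ACE columns). By
#' default the regression is unweighted ordinary least squares; setting
#' `weighted = TRUE` uses the IRLS working weights from the fit.
#'
#' @param fit An [ace_logit()] fit with ACE predictor columns.
#' @param weighted Use information weights `p(1-p)` from the fit.
#' @return Named numeric vector of VIFs; perfectly collinear columns are
#'   reported as `Inf` with a warning naming the column.
#' @export
vif_ace <- function(fit, weighted = FALSE) {
  stopifnot(inherits(fit, "ace_fit"))
  cols <- fit$ace_cols
  if (!length(cols)) stop("fit has no ACE predictor columns", call. = FALSE)
  x <- fit$x
  w <- if (weighted) fit$fitted * (1 - fit$fitted) else rep(1, fit$n)
  out <- stats::setNames(numeric(length(cols)), colnames(x)[cols])
  for (i in seq_along(cols)) {
    j <- cols[i]
    others <- x[, -j, drop = FALSE]
    target <- x[, j]
    cf <- stats::lm.wfit(others, target, w)$coefficients
    cf[is.na(cf)] <- 0
    res <- target - drop(others %*% cf)
    wm <- sum(w * target) / sum(w)
    tss <- sum(w * (target - wm)^2)
    rss <- sum(w * res^2)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) {
      warning("perfect collinearity: column '", colnames(x)[j],
              "' is exactly explained by the other design columns",
              call. = FALSE)
      out[i] <- Inf
    } else out[i] <- 1 / (1 - r2)
  }
  out
}
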