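#' Code item responses as binary exposures
#'
#' Items 1-5 (yes/no) are exposed iff "yes" under either threshold. The
#' frequency items 6-11 are exposed iff the response meets the threshold:
#' `"once"` counts both "once" and "more_than_once" as exposed (any
#' occurrence); `"more_than_once"` counts only repeated occurrence.
#'
#' @param data Screened response table (no missing items).
#' @param threshold `"once"` or `"more_than_once"`.
#' @return An object of class `"ace_exposures"`: list with `matrix` (n x 11
#'   0/1 matrix, columns named per [ace_item_labels()]), `score` (row sums),
#'   `threshold` and `items = 11`.
#' @export
#' @examples
#' cfg <- ace_sim_config(n = 50, seed = 1)
#' e <- code_exposures(generate_responses(cfg), "once")
#' table(e$score)
code_exposures <- function(data, threshold = c("once", "more_than_once")) {
  threshold <- match.arg(threshold)
  miss_cols <- setdiff(ACE_ITEM_COLS, names(data))
  if (length(miss_cols))
    stop("missing item columns: ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  items <- data[ACE_ITEM_COLS]
  if (anyNA(items))
    stop("item responses contain missing values; run screen_responses() first",
         call. = FALSE)
  E <- matrix(0L, nrow(data), 11L,
              dimnames = list(NULL, ACE_ITEM_LABELS))
  for (j in ACE_YESNO) {
    v <- as.character(items[[j]])
    bad <- !v %in% c("yes", "no")
    if (any(bad))
      stop(sprintf("item_%d has values outside {yes, no}: %s", j,
                   paste(unique(v[bad]), collapse = ", ")), call. = FALSE)
    E[, j] <- as.integer(v == "yes")
  }
  exposed_levels <- if (threshold == "once") c("once", "more_than_once")
                    else "more_than_once"
  for (j in ACE_FREQ) {
    v <- as.character(items[[j]])
    bad <- !v %in% FREQ_LEVELS
    if (any(bad))
      stop(sprintf("item_%d has values outside {never, once, more_than_once}: %s",
                   j, paste(unique(v[bad]), collapse = ", ")), call. = FALSE)
    E[, j] <- as.integer(v %in% exposed_levels)
  }
  structure(list(matrix = E, score = as.integer(rowSums(E)),
                 threshold = threshold, items = 11L),
            class = "ace_exposures")
}

#' Collapse the three sexual-adversity items into one indicator
#'
#' The 11-item exposure matrix is reduced to 9 items by replacing the
#' Sexually Touched / Sexual Touching / Forced Sex columns with a single
#' "Sexual Abuse" indicator equal to their logical OR; the score is
#' recomputed (range 0-9).
#'
#' @param exposures An 11-item [code_exposures()] result.
#' @return A 9-item `"ace_exposures"` object.
#' @export
collapse_to_nine <- function(exposures) {
  stopifnot(inherits(exposures, "ace_exposures"))
  if (exposures$items != 11L)
    stop("exposures are already collapsed to 9 items", call. = FALSE)
  E <- exposures$matrix
  sexual <- as.integer(rowSums(E[, 9:11, drop = FALSE]) > 0)
  E9 <- cbind(E[, 1:8, drop = FALSE], `Sexual Abuse` = sexual)
  structure(list(matrix = E9, score = as.integer(rowSums(E9)),
                 threshold = exposures$threshold, items = 9L),
            class = "ace_exposures")
}

#' @export
print.ace_exposures <- function(x, ...) {
  cat("ACE exposures:", nrow(x$matrix), "respondents,", x$items,
      "items, threshold '", x$threshold, "'\n", sep = "")
  cat("Score distribution:\n")
  print(table(score = x$score))
  invisible(x)
}

#' Declare an ACE predictor characterization
#'
#' A characterization fixes the model family (continuous cumulative score
#' CRCn, categorical cumulative score CRCat, or multiple individual risk
#' MIR), the item count (11, or 9 with the sexual items collapsed), the
#' exposure threshold, an optional quadratic score term (CRCn only), and an
#' optional score category scheme (CRCat only).
#'
#' @param family `"CRCn"`, `"CRCat"` or `"MIR"`.
#' @param items 11 or 9.
#' @param threshold `"once"` or `"more_than_once"`.
#' @param quadratic Add a mean-centered squared-score term (CRCn only).
#' @param scheme CRCat only: integer vector of consecutive category lower
#'   bounds starting at 0, the last category open-ended. `c(0, 1, 2, 3, 4)`
#'   means categories 0, 1, 2, 3 and "4+". NULL (default) uses one category
#'   per observed score value (reference 0), with an automatic top collapse
#'   applied by the workflow only when cell counts fall below threshold.
#' @return An object of class `"predictor_spec"`.
#' @export
#' @examples
#' predictor_spec("CRCat", items = 11, threshold = "once", scheme = c(0, 1, 2, 3, 4))
predictor_spec <- function(family = c("CRCn", "CRCat", "MIR"), items = 11,
                           threshold = "once", quadratic = FALSE,
                           scheme = NULL) {
  family <- match.arg(family)
  items <- match_items(items)
  threshold <- match_threshold(threshold)
  if (quadratic && family != "CRCn")
    stop("`quadratic` is only available for family 'CRCn'", call. = FALSE)
  if (!is.null(scheme)) {
    if (family != "CRCat")
      stop("`scheme` is only available for family 'CRCat'", call. = FALSE)
    scheme <- as.integer(scheme)
    if (scheme[1] != 0L || any(diff(scheme) != 1L))
      stop("`scheme` must be consecutive integers starting at 0", call. = FALSE)
  }
  structure(list(family = family, items = items, threshold = threshold,
                 quadratic = isTRUE(quadratic), scheme = scheme),
            class = "predictor_spec")
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat(spec_label(x), "\n")
  invisible(x)
}

#' Human-readable label of a predictor characterization
#' @param spec A [predictor_spec()], or the string `"baseline"`.
#' @return A single string such as `"CRCn, 11 items, 'once' + quadratic"`.
#' @export
spec_label <- function(spec) {
  if (identical(spec, "baseline") || is.null(spec)) return("Baseline (covariates only)")
  paste0(spec$family, ", ", spec$items, " items, '",
         sub("_", " ", spec$threshold, fixed = TRUE), "'",
         if (spec$quadratic) " + quadratic" else "",
         if (!is.null(spec$scheme))
           paste0(", categories 0-", max(spec$scheme), "+") else "")
}

score_categories <- function(score, scheme) {
  top <- max(scheme)
  s <- pmin(score, top)
  labels <- c(as.character(scheme[-length(scheme)]), paste0(top, "+"))
  # when the top category is the max observed score exactly, label it plainly
  if (max(score) <= top) labels[length(labels)] <- as.character(top)
  factor(labels[s + 1L], levels = labels)
}

#' Build the logistic design matrix for a characterization
#'
#' Assembles outcome vector, intercept, reference-cell-coded covariate
#' dummies (identical across characterizations for a given dataset -- the
#' source of the "partially non-nested" structure) and the ACE predictor
#' columns implied by the spec: one score column (plus a mean-centered
#' squared-score column if quadratic) for CRCn; one dummy per non-reference
#' score category for CRCat; one column per exposure indicator for MIR.
#' `spec = NULL` (or `"baseline"`) builds the covariate-only design.
#'
#' @param spec A [predictor_spec()], or NULL/"baseline" for the
#'   covariate-only model.
#' @param data Screened response table.
#' @param outcome Outcome column name (0/1).
#' @param covariates Covariate column names (coerced to factors; first level
#'   is the reference cell).
#' @return An object of class `"ace_design"`: list with `y`, `x` (full-rank
#'   model matrix), `n`, `k`, `spec`, `ace_cols` (indices of the ACE
#'   predictor columns), `score` (CR families), and bookkeeping fields.
#' @export
build_design <- function(spec, data, outcome = "outcome",
                         covariates = ace_covariates()) {
  if (identical(spec, "baseline")) spec <- NULL
  if (!is.null(spec)) stopifnot(inherits(spec, "predictor_spec"))
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found", call. = FALSE)
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome must be 0/1 with no missing values (screen first)",
         call. = FALSE)
  covdf <- data[covariates]
  if (anyNA(covdf))
    stop("covariates contain missing values (screen first)", call. = FALSE)
  covdf[] <- lapply(covdf, function(v) if (is.factor(v)) droplevels(v) else factor(v))
  x_cov <- stats::model.matrix(stats::reformulate(covariates), covdf)

  score <- NULL
  ace_block <- NULL
  if (!is.null(spec)) {
    expo <- code_exposures(data, spec$threshold)
    if (spec$items == 9L) expo <- collapse_to_nine(expo)
    score <- expo$score
    ace_block <- switch(spec$family,
      CRCn = {
        b <- cbind(ace_score = score)
        if (spec$quadratic)
          b <- cbind(b, ace_score_sq = (score - mean(score))^2)
        b
      },
      CRCat = {
        scheme <- spec$scheme %||% seq(0L, max(score))
        cat_f <- score_categories(score, scheme)
        empty <- levels(cat_f)[tabulate(cat_f, nbins = nlevels(cat_f)) == 0L]
        if (length(empty))
          stop("empty ACE score category(ies): ",
               paste(empty, collapse = ", "),
               "; supply a coarser `scheme`", call. = FALSE)
        m <- stats::model.matrix(~cat_f)[, -1, drop = FALSE]
        colnames(m) <- paste0("ace_", sub("^cat_f", "", colnames(m)))
        m
      },
      MIR = {
        m <- expo$matrix
        colnames(m) <- paste0("ace_", gsub(" ", "_", colnames(m)))
        m
      }
    )
  }
  x <- cbind(x_cov, ace_block)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(list(
    y = y, x = x, n = nrow(x), k = ncol(x),
    spec = spec, label = spec_label(spec),
    ace_cols = if (is.null(ace_block)) integer(0)
               else ncol(x_cov) + seq_len(ncol(ace_block)),
    score = score, outcome = outcome, covariates = covariates
  ), class = "ace_design")
}

#' @export
print.ace_design <- function(x, ...) {
  cat("Logistic design:", x$label, "\n")
  cat("  n =", x$n, " k =", x$k, " ACE columns =", length(x$ace_cols), "\n")
  invisible(x)
}
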