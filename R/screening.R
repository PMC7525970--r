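#' Screen respondent records
#'
#' Applies the inclusion rules used before any model is fitted, so that all
#' candidate models are estimated on the same rows:
#'
#' * rows with missing data on any covariate or on the outcome are dropped;
#' * rows with two or more missing ACE items are dropped;
#' * rows with exactly one missing ACE item are retained, with that item
#'   imputed to its unexposed level ("no" for items 1-5, "never" for items
#'   6-11).
#'
#' @param data Response table with item, covariate and outcome columns;
#'   missing values coded NA (see [read_ace_dataset()] for code mapping).
#' @param covariates Covariate column names.
#' @param outcome Outcome column name.
#' @return An object of class `"ace_screen"`: a list with `data` (the
#'   retained, imputed rows) and `log` (counts per rule: input, dropped for
#'   covariate/outcome missingness, dropped for >= 2 missing items, imputed,
#'   retained).
#' @export
#' @examples
#' cfg <- ace_sim_config(n = 300, missing_rate = 0.02, seed = 3)
#' s <- screen_responses(simulate_ace_data(cfg))
#' s$log
screen_responses <- function(data, covariates = ace_covariates(),
                             outcome = "outcome") {
  need <- c(ACE_ITEM_COLS, covariates, outcome)
  miss_cols <- setdiff(need, names(data))
  if (length(miss_cols))
    stop("missing required columns: ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  n_in <- nrow(data)

  cov_block <- data[c(covariates, outcome)]
  bad_cov <- Reduce(`|`, lapply(cov_block, is.na))
  item_na <- rowSums(is.na(data[ACE_ITEM_COLS]))
  bad_items <- item_na >= 2L

  drop <- bad_cov | bad_items
  impute <- !drop & item_na == 1L

  kept <- data[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) {
    dominant <- if (sum(bad_cov) >= sum(bad_items))
      "missing covariate/outcome" else ">= 2 missing ACE items"
    stop("no rows survive screening; dominant exclusion rule: ", dominant,
         call. = FALSE)
  }
  # impute the single missing item to its unexposed level
  for (j in seq_along(ACE_ITEM_COLS)) {
    col <- ACE_ITEM_COLS[j]
    na_here <- is.na(kept[[col]])
    if (any(na_here)) {
      fill <- if (j %in% ACE_YESNO) "no" else "never"
      if (is.factor(kept[[col]])) {
        if (!fill %in% levels(kept[[col]]))
          levels(kept[[col]]) <- c(levels(kept[[col]]), fill)
      }
      kept[[col]][na_here] <- fill
    }
  }
  rownames(kept) <- NULL
  structure(list(
    data = kept,
    log = list(
      n_input = n_in,
      n_dropped_covariate_or_outcome = sum(bad_cov),
      n_dropped_two_plus_missing_items = sum(bad_items & !bad_cov),
      n_imputed = sum(impute),
      n_retained = nrow(kept)
    )
  ), class = "ace_screen")
}

#' @export
print.ace_screen <- function(x, ...) {
  l <- x$log
  cat("Screening:", l$n_input, "rows in;",
      l$n_dropped_covariate_or_outcome, "dropped (missing covariate/outcome);",
      l$n_dropped_two_plus_missing_items, "dropped (>= 2 missing items);",
      l$n_imputed, "single-item imputations;",
      l$n_retained, "retained.\n")
  invisible(x)
}

#' Cross-tabulation cell-count check for the ACE score
#'
#' Cross-tabulates the ACE score against the outcome and against each
#' covariate, flags every cell below `min_count`, and -- when any flag is
#' raised -- proposes the minimal top-category collapse (merging the highest
#' score values into one open-ended category) that restores compliance.
#' Report-only: nothing is modified.
#'
#' @param score Integer ACE score per respondent.
#' @param outcome 0/1 outcome vector.
#' @param covariates Optional data frame of covariate factors to include in
#'   the check.
#' @param min_count Minimum acceptable cell count (default 20).
#' @return An object of class `"cell_count_report"` with `flags` (data frame
#'   of offending cells) and `proposed_scheme` (integer vector of category
#'   lower bounds, top category open-ended; NULL when no collapse is needed
#'   or none suffices).
#' @export
check_cell_counts <- function(score, outcome, covariates = NULL,
                              min_count = 20) {
  stopifnot(length(score) == length(outcome))
  tabs <- list(outcome = table(score = score, level = outcome))
  if (!is.null(covariates)) {
    for (nm in names(covariates))
      tabs[[nm]] <- table(score = score, level = covariates[[nm]])
  }
  flag_cells <- function(tb, label) {
    idx <- which(tb < min_count, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(
      table = label,
      score = rownames(tb)[idx[, 1]],
      level = colnames(tb)[idx[, 2]],
      count = tb[idx],
      stringsAsFactors = FALSE
    )
  }
  flags <- do.call(rbind, Filter(Negate(is.null),
    Map(flag_cells, tabs, names(tabs))))
  if (is.null(flags))
    flags <- data.frame(table = character(), score = character(),
                        level = character(), count = integer(),
                        stringsAsFactors = FALSE)
  rownames(flags) <- NULL

  proposed <- NULL
  if (nrow(flags) > 0) {
    smax <- max(score)
    # recompute tables under a candidate collapse and test all cells
    check_top <- function(top) {
      s2 <- pmin(score, top)
      ok <- all(table(s2, outcome) >= min_count)
      if (ok && !is.null(covariates)) {
        for (nm in names(covariates)) {
          if (any(table(s2, covariates[[nm]]) < min_count)) { ok <- FALSE; break }
        }
      }
      ok
    }
    for (top in rev(seq_len(smax - 1L))) {
      if (check_top(top)) { proposed <- 0:top; break }
    }
  }
  structure(list(flags = flags, proposed_scheme = proposed,
                 min_count = min_count),
            class = "cell_count_report")
}

#' @export
print.cell_count_report <- function(x, ...) {
  if (!nrow(x$flags)) {
    cat("All score cross-tab cells have at least", x$min_count, "cases.\n")
  } else {
    cat(nrow(x$flags), "cells below", x$min_count, "cases:\n")
    print(utils::head(x$flags, 10))
    if (!is.null(x$proposed_scheme)) {
      top <- max(x$proposed_scheme)
      cat("Proposed top-category collapse: scores >=", top,
          "merged into '", top, "+'\n", sep = "")
    } else {
      cat("No top-category collapse restores compliance.\n")
    }
  }
  invisible(x)
}
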