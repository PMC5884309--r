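# Which pole of each GDS item is apathetic. Four items are apathetic when
# answered "yes"; the two positively phrased items ("find life very
# exciting", "full of energy") are reverse-scored.
gds_item_polarity <- function() {
  c(stay_home = "yes", avoid_gatherings = "yes", dropped_activities = "yes",
    life_exciting = "no", hard_new_projects = "yes", full_of_energy = "no")
}

#' Apathy score from six GDS items
#'
#' Counts apathetic responses over the six Geriatric Depression Scale items
#' used to measure apathy: "prefer to stay at home", "avoid social
#' gatherings", "dropped activities and interests", "find life very
#' exciting", "hard to start new projects" and "full of energy". Each item
#' scores one point when answered at its apathetic pole ("yes" for the
#' first, second, third and fifth; "no" for the two positively phrased
#' items), giving an integer in `[0, 6]`.
#'
#' @param items named list or vector with entries `stay_home`,
#'   `avoid_gatherings`, `dropped_activities`, `life_exciting`,
#'   `hard_new_projects`, `full_of_energy`, each `"yes"` or `"no"`. All six
#'   must be present; there is no imputation.
#' @return integer score in `[0, 6]`.
#' @export
#' @examples
#' apathy_score(list(stay_home = "yes", avoid_gatherings = "no",
#'                   dropped_activities = "no", life_exciting = "yes",
#'                   hard_new_projects = "no", full_of_energy = "yes"))  # 1
apathy_score <- function(items) {
  pol <- gds_item_polarity()
  items <- unlist(items)
  missing_items <- setdiff(names(pol), names(items))
  if (length(missing_items) > 0) {
    stop("missing GDS item(s): ", paste(missing_items, collapse = ", "))
  }
  resp <- tolower(as.character(items[names(pol)]))
  if (!all(resp %in% c("yes", "no"))) {
    stop("GDS responses must be 'yes' or 'no'")
  }
  sum(as.integer(resp == pol))
}

correlation_result <- function(r, n, n_controls, controlled_for) {
  df <- n - 2L - n_controls
  t_val <- r_to_t_df(r, df)
  structure(list(r = r, df = df, t = t_val,
                 p = 2 * stats::pt(-abs(t_val), df),
                 n = n, controlled_for = controlled_for),
            class = "correlation_result")
}

r_to_t_df <- function(r, df) {
  if (abs(r) >= 1) return(sign(r) * T_CAP)
  r * sqrt(df) / sqrt(1 - r^2)
}

#' @export
print.correlation_result <- function(x, ...) {
  ctl <- if (length(x$controlled_for)) {
    paste0(" | ", paste(x$controlled_for, collapse = ", "))
  } else ""
  cat(sprintf("r = %.4f%s (df = %d, t = %.3f, p = %.4g)\n",
              x$r, ctl, x$df, x$t, x$p))
  invisible(x)
}

#' Pearson correlation with t-based two-tailed p-value
#'
#' @param x,y numeric vectors of equal length (>= 4), each with nonzero
#'   variance.
#' @return a `correlation_result` with fields `r`, `df` (= n - 2), `t`,
#'   two-tailed `p` and `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input")
  }
  correlation_result(stats::cor(x, y), n, 0L, character(0))
}

#' Partial correlation via residualization
#'
#' The correlation between `x` and `y` after removing the least-squares
#' projection of each onto `[intercept, controls]`. Equivalent to the
#' recursive partial-correlation formula and generalizes to any number of
#' controls; degrees of freedom are `n - 2 - #controls`.
#'
#' @param x,y numeric vectors.
#' @param controls numeric vector, matrix or data.frame of control
#'   variables (binary covariates as 0/1 columns). May be `NULL` or empty,
#'   in which case the result equals [pearson()] exactly.
#' @return a `correlation_result`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (is.null(controls) || NCOL(controls) == 0 ||
      (is.matrix(controls) && ncol(controls) == 0)) {
    return(pearson(x, y))
  }
  C <- as.matrix(as.data.frame(controls))
  storage.mode(C) <- "double"
  n <- length(x)
  stopifnot(length(y) == n, nrow(C) == n)
  k <- ncol(C)
  if (n <= k + 3) stop("need n > #controls + 3 observations")
  X <- cbind(`(intercept)` = 1, C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("control design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero residual variance after controlling")
  }
  ctl_names <- colnames(C) %||% paste0("control_", seq_len(k))
  correlation_result(stats::cor(rx, ry), n, k, ctl_names)
}

#' Specificity table: sub-network metrics vs apathy under mutual control
#'
#' For every (target, control) pair of sub-networks and each metric
#' (efficiency and sum of weights), the partial correlation between the
#' target's metric and the apathy score controlling for the control
#' network's same metric — the test of whether each network explains
#' variance in apathy beyond the others. Also reports each network's
#' marginal correlation and (when covariates are supplied) the correlation
#' controlling for age plus the four vascular risk factors.
#'
#' @param metrics data.frame from [network_metrics()]: `subject_id` plus
#'   `<net>_eff` / `<net>_sum` columns for at least one sub-network.
#' @param apathy numeric vector of apathy scores, aligned with `metrics`
#'   rows.
#' @param covariates optional data.frame of nuisance covariates (e.g. age
#'   and 0/1 risk factors) for the covariate-adjusted rows.
#' @param alpha significance level for the `significant` flags
#'   (default 0.05).
#' @return data.frame with columns `network`, `control` (`"none"`,
#'   another network's name, or `"covariates"`), `metric` (`"efficiency"`
#'   or `"sum_of_weights"`), `r`, `df`, `p`, `significant`. With a single
#'   sub-network only marginal (and covariate) rows are produced.
#' @export
specificity_table <- function(metrics, apathy, covariates = NULL,
                              alpha = 0.05) {
  nets <- sub("_eff$", "", grep("_eff$", colnames(metrics), value = TRUE))
  if (length(nets) == 0) stop("metrics has no *_eff columns")
  stopifnot(length(apathy) == nrow(metrics))
  metric_col <- c(efficiency = "_eff", sum_of_weights = "_sum")
  rows <- list()
  add_row <- function(network, control, metric, res) {
    rows[[length(rows) + 1]] <<- data.frame(
      network = network, control = control, metric = metric,
      r = res$r, df = res$df, p = res$p,
      significant = res$p < alpha, stringsAsFactors = FALSE)
  }
  for (metric in names(metric_col)) {
    suffix <- metric_col[[metric]]
    for (net in nets) {
      x <- metrics[[paste0(net, suffix)]]
      add_row(net, "none", metric, pearson(x, apathy))
      for (ctl in setdiff(nets, net)) {
        z <- metrics[[paste0(ctl, suffix)]]
        add_row(net, ctl, metric,
                partial_correlation(x, apathy,
                                    stats::setNames(data.frame(z), ctl)))
      }
      if (!is.null(covariates)) {
        add_row(net, "covariates", metric,
                partial_correlation(x, apathy, covariates))
      }
    }
  }
  do.call(rbind, rows)
}
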