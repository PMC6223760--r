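# Target registration error, per-group summaries (mean/sd/min/max/
# repeatability) and the two implemented comparisons: classical one-way
# ANOVA and the Welch test of equal means.

#' Target registration error
#'
#' Euclidean distance (mm) between a target's registered (predicted)
#' position and its measured position, both in the reference frame — here,
#' the lesion centre mapped by the estimated registration versus the same
#' lesion localized with the tracked ultrasound probe.
#'
#' @param p_estimated,p_true numeric length-3 points (mm), same frame.
#' @return Distance in mm.
#' @examples
#' tre(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
tre <- function(p_estimated, p_true) {
  p_estimated <- as.numeric(p_estimated)
  p_true <- as.numeric(p_true)
  if (length(p_estimated) != 3L || length(p_true) != 3L) {
    slreg_error("slreg_invalid_input", "points must have length 3")
  }
  stopifnot_finite(p_estimated, "p_estimated")
  stopifnot_finite(p_true, "p_true")
  sqrt(sum((p_estimated - p_true)^2))
}

#' Summarize TRE trials per experimental group
#'
#' Groups trials by (method, axis, displacement) and reports, per group:
#' count, mean, sample standard deviation (n-1 denominator), minimum,
#' maximum and repeatability. Repeatability follows the convention of
#' reporting the standard deviation of the mean (standard error),
#' \eqn{sd/\sqrt{n}}.
#'
#' @param trials data frame with columns `method`, `axis`,
#'   `displacement_mm`, `tre_mm` (as returned by [run_experiment()]);
#'   every group must contain at least 2 trials.
#' @return Data frame of class `group_summary` with columns `method`,
#'   `axis`, `displacement_mm`, `n`, `mean`, `sd`, `min`, `max`,
#'   `repeatability` (all error columns in mm).
#' @export
summarize_groups <- function(trials) {
  need <- c("method", "axis", "displacement_mm", "tre_mm")
  if (!is.data.frame(trials) || !all(need %in% names(trials))) {
    slreg_error("slreg_invalid_input",
                "trials must have columns method, axis, displacement_mm, tre_mm")
  }
  if (nrow(trials) == 0L) {
    slreg_error("slreg_empty_group", "no trials to summarize")
  }
  key <- list(method = trials$method, axis = trials$axis,
              displacement_mm = trials$displacement_mm)
  agg <- aggregate(trials$tre_mm, by = key, FUN = function(x) {
    c(n = length(x), mean = mean(x), sd = sd(x),
      min = min(x), max = max(x))
  })
  stats <- as.data.frame(agg$x)
  if (any(stats$n < 2L)) {
    slreg_error("slreg_empty_group",
                "each (method, axis, displacement) group needs >= 2 trials")
  }
  out <- data.frame(method = agg$method, axis = agg$axis,
                    displacement_mm = agg$displacement_mm,
                    n = as.integer(stats$n), mean = stats$mean,
                    sd = stats$sd, min = stats$min, max = stats$max,
                    repeatability = stats$sd / sqrt(stats$n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$method, out$axis, out$displacement_mm), ]
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Format a group summary the way accuracy tables are printed
#'
#' Rounds mean/sd/min/max to one decimal and repeatability to two, the
#' conventional precision of phantom-accuracy tables.
#'
#' @param summary a `group_summary` from [summarize_groups()].
#' @return A plain data frame with rounded columns.
#' @export
format_tre_table <- function(summary) {
  if (!inherits(summary, "group_summary")) {
    slreg_error("slreg_invalid_input", "expected a group_summary")
  }
  out <- as.data.frame(summary)
  for (col in c("mean", "sd", "min", "max")) out[[col]] <- round(out[[col]], 1)
  out$repeatability <- round(out$repeatability, 2)
  out
}

new_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method),
            class = "slreg_test")
}

#' @export
print.slreg_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = (%s), p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical (equal-variance) one-way ANOVA over k groups: F is the ratio
#' of between- to within-group mean squares with (k-1, N-k) degrees of
#' freedom. Thin wrapper over [stats::oneway.test()] returning a uniform
#' test-result container.
#'
#' @param groups a list of numeric vectors (>= 2 groups, each n >= 2).
#' @return An object of class `slreg_test` with `statistic`, `df`
#'   (length 2) and `p_value`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))  # F = 1.5, df (1, 4)
#' @export
one_way_anova <- function(groups) {
  check_groups(groups, min_groups = 2L)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, function(x) sd(x) == 0, logical(1)))) {
    slreg_error("slreg_degenerate_data",
                "zero within-group variance; F is undefined")
  }
  ht <- oneway.test(y ~ g, var.equal = TRUE)
  new_test_result(ht$statistic, c(ht$parameter[["num df"]],
                                  ht$parameter[["denom df"]]),
                  ht$p.value, "One-way ANOVA")
}

#' Welch test of equal means
#'
#' Two-sample comparison without the equal-variance assumption: the Welch
#' t statistic with Welch-Satterthwaite (fractional) degrees of freedom.
#' Thin wrapper over [stats::t.test()] returning a uniform test-result
#' container.
#'
#' @param g1,g2 numeric vectors (each n >= 2; not both of zero variance).
#' @return An object of class `slreg_test` with `statistic` (t), `df`
#'   (fractional) and `p_value`.
#' @export
welch_test <- function(g1, g2) {
  check_groups(list(g1, g2), min_groups = 2L)
  if (sd(g1) == 0 && sd(g2) == 0) {
    slreg_error("slreg_degenerate_data",
                "both groups have zero variance; the test is undefined")
  }
  ht <- t.test(g1, g2, var.equal = FALSE)
  new_test_result(ht$statistic, ht$parameter, ht$p.value,
                  "Welch two-sample test")
}

check_groups <- function(groups, min_groups) {
  if (!is.list(groups) || length(groups) < min_groups) {
    slreg_error("slreg_invalid_input",
                sprintf("need at least %d groups", min_groups))
  }
  for (x in groups) {
    if (!is.numeric(x) || length(x) < 2L) {
      slreg_error("slreg_invalid_input",
                  "each group needs at least 2 numeric observations")
    }
    stopifnot_finite(x, "group values")
  }
  invisible(groups)
}

#' Plot TRE by experimental group
#'
#' Simple boxplot of per-trial TRE grouped by axis and displacement, one
#' panel row of boxes per registration method.
#'
#' @param trials a trial data frame (see [summarize_groups()]).
#' @param ... passed to [graphics::boxplot()].
#' @return Invisibly, the trials.
#' @export
plot_tre_groups <- function(trials, ...) {
  need <- c("method", "axis", "displacement_mm", "tre_mm")
  if (!is.data.frame(trials) || !all(need %in% names(trials))) {
    slreg_error("slreg_invalid_input",
                "trials must have columns method, axis, displacement_mm, tre_mm")
  }
  grp <- interaction(trials$method,
                     substr(trials$axis, 1, 4),
                     trials$displacement_mm, sep = " ")
  graphics::boxplot(trials$tre_mm ~ grp, las = 2,
                    xlab = "", ylab = "TRE (mm)", ...)
  invisible(trials)
}
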