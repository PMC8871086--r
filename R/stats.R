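#' Reduce a segmented ROI to percentage metrics
#'
#' FS% and CAS% are percentages of all ROI pixels in the foreground and
#' collagen masks; CDM% is the mean of the collagen density map times 100;
#' DV% is the mean directional variance over valid pixels times 100. When no
#' pixel has a defined directional variance, `dv_pct` is `NA` (undefined),
#' never 0.
#'
#' @param seg A `segmentation`.
#' @param density A `density_map` on the same frame.
#' @param variance A `variance_map` on the same frame.
#' @param roi_id,group Optional identifiers copied into the output row.
#' @return A one-row `data.frame` with columns `roi_id`, `group`, `fs_pct`,
#'   `cas_pct`, `cdm_pct`, `dv_pct`, `n_pixels`, `n_valid_dv`.
#' @export
summarize_roi <- function(seg, density, variance, roi_id = NA_character_,
                          group = NA_character_) {
  stopifnot(inherits(seg, "segmentation"), inherits(density, "density_map"),
            inherits(variance, "variance_map"))
  if (!same_frame(seg$cas, density) || !same_frame(seg$cas, variance$V))
    stop_fdv("segmentation, density and variance maps must share a frame",
             class = "fiberDV_dim_error")
  n <- length(seg$cas)
  n_valid <- sum(variance$valid)
  data.frame(
    roi_id = roi_id,
    group = group,
    fs_pct = 100 * sum(seg$fs) / n,
    cas_pct = 100 * sum(seg$cas) / n,
    cdm_pct = 100 * mean(density),
    dv_pct = if (n_valid > 0) 100 * mean(variance$V[variance$valid]) else NA_real_,
    n_pixels = n,
    n_valid_dv = n_valid,
    stringsAsFactors = FALSE
  )
}

group_summary <- function(groups) {
  list(means = vapply(groups, mean, numeric(1)),
       sds = vapply(groups, stats::sd, numeric(1)))
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Pooled-variance two-sided two-sample t-test, the classical Student form
#' (Welch's unequal-variance correction available via `var_equal = FALSE`).
#' Two identical constant groups return t = 0, p = 1 by convention; constant
#' groups with different means are a degenerate-variance error.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (classical Student, default TRUE)?
#' @param group_names Labels for the two groups.
#' @return A `group_comparison`: list with `group_names`, `means`, `sds`,
#'   `statistic` (t), `df`, `p_value`, `test`.
#' @export
student_t <- function(group_a, group_b, var_equal = TRUE,
                      group_names = c("A", "B")) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_fdv("each group needs >= 2 observations (got %d and %d)",
             length(group_a), length(group_b), class = "fiberDV_param_error")
  gs <- group_summary(list(group_a, group_b))
  scale2 <- mean(c(group_a, group_b)^2) + 1
  pooled <- (sum((group_a - gs$means[1])^2) + sum((group_b - gs$means[2])^2)) /
    (length(group_a) + length(group_b) - 2L)
  if (pooled <= 1e-24 * scale2) {
    if (abs(diff(gs$means)) <= sqrt(1e-24 * scale2)) {
      stat <- 0; p <- 1; df <- length(group_a) + length(group_b) - 2L
    } else {
      stop_fdv("degenerate variance: both groups constant but means differ (%g vs %g)",
               gs$means[1], gs$means[2], class = "fiberDV_degenerate_error")
    }
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
    stat <- unname(ht$statistic); p <- ht$p.value; df <- unname(ht$parameter)
  }
  structure(list(group_names = group_names, means = unname(gs$means),
                 sds = unname(gs$sds), statistic = stat, df = df,
                 p_value = p, test = if (var_equal) "student_t" else "welch_t"),
            class = "group_comparison")
}

#' One-way analysis of variance
#'
#' Standard fixed-effects decomposition, `F = MS_between / MS_within`, p from
#' the F distribution. All-constant groups with equal means return F = 0,
#' p = 1 by convention; all-constant groups with unequal means are a
#' degenerate-variance error.
#'
#' @param groups List (optionally named) of >= 2 numeric vectors, each of
#'   length >= 2.
#' @return A `group_comparison` with `statistic` = F, `df` = c(between,
#'   within), `test = "one_way_anova"`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_fdv("need a list of >= 2 groups", class = "fiberDV_param_error")
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop_fdv("each group needs >= 2 observations (sizes: %s)",
             paste(sizes, collapse = ", "), class = "fiberDV_param_error")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  gs <- group_summary(groups)
  y <- unlist(groups, use.names = FALSE)
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  if (all(vapply(groups, stats::var, numeric(1)) <= 1e-24 * (mean(y^2) + 1))) {
    if (max(gs$means) - min(gs$means) <= sqrt(1e-24 * (mean(y^2) + 1))) {
      stat <- 0; p <- 1
    } else {
      stop_fdv("degenerate variance: all groups constant but means differ",
               class = "fiberDV_degenerate_error")
    }
  } else {
    g <- factor(rep(nm, sizes), levels = nm)
    ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(group_names = nm, means = unname(gs$means),
                 sds = unname(gs$sds), statistic = stat,
                 df = c(df1, df2), p_value = p, test = "one_way_anova"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s: %s>\n", x$test,
              paste(sprintf("%s %.3f +/- %.3f", x$group_names, x$means, x$sds),
                    collapse = "; ")))
  cat(sprintf("  statistic = %.4f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

valid_metrics <- c("fs_pct", "cas_pct", "cdm_pct", "dv_pct")

#' Compare one ROI metric across tissue groups
#'
#' Two groups dispatch to the pooled [student_t()]; three or more to
#' [one_way_anova()]. Results carry mean and standard deviation per group
#' (the mean +/- SD reporting convention). No multiple-testing correction is
#' applied when several metrics are compared separately.
#'
#' @param metrics_by_group Named list of `data.frame`s of ROI metrics (rows
#'   from [summarize_roi()]), one entry per group.
#' @param metric One of `"fs_pct"`, `"cas_pct"`, `"cdm_pct"`, `"dv_pct"`.
#' @return A `group_comparison`.
#' @export
compare_regions <- function(metrics_by_group, metric) {
  if (!is.character(metric) || length(metric) != 1L || !(metric %in% valid_metrics))
    stop_fdv("unknown metric '%s'; valid metrics: %s",
             paste(metric, collapse = ","), paste(valid_metrics, collapse = ", "),
             class = "fiberDV_param_error")
  if (!is.list(metrics_by_group) || length(metrics_by_group) < 2L)
    stop_fdv("need metrics for >= 2 groups", class = "fiberDV_param_error")
  nm <- names(metrics_by_group)
  if (is.null(nm) || any(nm == ""))
    stop_fdv("metrics_by_group must be a named list (group labels)",
             class = "fiberDV_param_error")
  vals <- lapply(metrics_by_group, function(df) {
    v <- df[[metric]]
    v[!is.na(v)]
  })
  if (length(vals) == 2L) {
    out <- student_t(vals[[1]], vals[[2]], group_names = nm)
  } else {
    names(vals) <- nm
    out <- one_way_anova(vals)
  }
  out
}
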