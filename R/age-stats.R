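# Age association of a marker's z-scores: OLS regression of z on age plus a
# pooled-variance two-sample Student's t-test between the pediatric
# (age <= 18 y) and adult (age >= 19 y) groups.

#' Age-group statistics for a biomarker
#'
#' Fits a simple linear regression `z = a + b * age` (two-sided slope test)
#' and compares mean z between the pediatric and adult groups with a
#' pooled-variance, two-tailed Student's t-test. Ages are in years as
#' decimals (6 months = 0.5).
#'
#' @param ztbl Long z-score table from [metabolite_zscores()] carrying
#'   `age_years`.
#' @param marker Metabolite name to analyse.
#' @param pediatric_max Upper age bound of the pediatric group in years
#'   (default 18); older samples form the adult group.
#' @return An object of class `age_group_stats` with [tidy()], [glance()],
#'   [autoplot()] and print methods. If either age group has fewer than two
#'   members the t-test is reported as not estimable (`NA`).
#' @export
age_group_stats <- function(ztbl, marker, pediatric_max = 18) {
  check_columns(ztbl, c("sample_id", "metabolite", "z", "age_years"),
                "z-score table")
  d <- ztbl[ztbl$metabolite == marker & !is.na(ztbl$z) &
              !is.na(ztbl$age_years), , drop = FALSE]
  if (nrow(d) < 3) {
    abort(sprintf("need >= 3 profiles with age and z for marker '%s'", marker))
  }
  d$age_group <- ifelse(d$age_years <= pediatric_max, "pediatric", "adult")
  fit <- lm(z ~ age_years, data = d)
  n_ped <- sum(d$age_group == "pediatric")
  n_adu <- sum(d$age_group == "adult")
  ttest <- if (n_ped >= 2 && n_adu >= 2) {
    t.test(z ~ factor(age_group, levels = c("pediatric", "adult")),
           data = d, var.equal = TRUE, alternative = "two.sided")
  } else {
    NULL
  }
  structure(
    list(marker = marker, data = as_tibble(d), fit = fit, ttest = ttest,
         pediatric_max = pediatric_max),
    class = "age_group_stats"
  )
}

#' @export
print.age_group_stats <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Age-group statistics for %s (n = %d)\n", x$marker, g$n))
  cat(sprintf("  slope: %+.4f z/year (p = %.3g)\n",
              g$slope_per_year, g$regression_p))
  if (is.na(g$t_statistic)) {
    cat("  pediatric vs adult t-test: not estimable (a group has < 2 members)\n")
  } else {
    cat(sprintf("  pediatric (n = %d, mean z = %.2f) vs adult (n = %d, mean z = %.2f): t = %.3f, p = %.3g\n",
                g$n_pediatric, g$mean_z_pediatric, g$n_adult, g$mean_z_adult,
                g$t_statistic, g$ttest_p))
  }
  invisible(x)
}

#' @describeIn age_group_stats Regression coefficient table (term, estimate,
#'   std.error, statistic, p.value).
#' @param x An `age_group_stats` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.age_group_stats <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @describeIn age_group_stats One-row summary: slope, regression p, group
#'   means and t-test results.
#' @exportS3Method generics::glance
glance.age_group_stats <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  d <- x$data
  ped <- d$z[d$age_group == "pediatric"]
  adu <- d$z[d$age_group == "adult"]
  tibble(
    marker = x$marker,
    n = nrow(d),
    slope_per_year = sm["age_years", "Estimate"],
    regression_p = sm["age_years", "Pr(>|t|)"],
    n_pediatric = length(ped),
    n_adult = length(adu),
    mean_z_pediatric = if (length(ped)) mean(ped) else NA_real_,
    mean_z_adult = if (length(adu)) mean(adu) else NA_real_,
    t_statistic = if (is.null(x$ttest)) NA_real_ else unname(x$ttest$statistic),
    ttest_p = if (is.null(x$ttest)) NA_real_ else x$ttest$p.value
  )
}

#' @describeIn age_group_stats Scatter of z against age with the fitted
#'   regression line, the abnormality threshold (z = +2) and the
#'   pediatric/adult boundary.
#' @param object An `age_group_stats` object.
#' @exportS3Method ggplot2::autoplot
autoplot.age_group_stats <- function(object, ...) {
  d <- object$data
  ggplot(d, aes(x = .data$age_years, y = .data$z,
                colour = .data$age_group)) +
    geom_point(size = 2) +
    geom_smooth(aes(group = 1), method = "lm", formula = y ~ x,
                se = FALSE, colour = "grey30", linewidth = 0.6) +
    geom_hline(yintercept = 2, linetype = "dashed", colour = "red") +
    geom_vline(xintercept = object$pediatric_max + 1, linetype = "dashed",
               colour = "red") +
    labs(x = "Age (years)", y = sprintf("%s z-score", object$marker),
         colour = "Age group") +
    theme_minimal()
}

#' Scatter plot of marker z-scores by group
#'
#' Per-metabolite scatter of z-scores (one panel per marker), with the
#' abnormality thresholds at z = +2 and z = -2, in the style of a
#' case-versus-reference biomarker overview.
#'
#' @param ztbl Long z-score table from [metabolite_zscores()]; a `group`
#'   column (e.g. reference / pediatric case / adult case) maps to colour
#'   when present.
#' @param markers Metabolites to show (default the GABA-pathway markers
#'   present in the table).
#' @return A ggplot object.
#' @export
plot_marker_zscores <- function(ztbl, markers = NULL) {
  check_columns(ztbl, c("sample_id", "metabolite", "z"), "z-score table")
  markers <- markers %||% intersect(gaba_markers(), unique(ztbl$metabolite))
  d <- ztbl[ztbl$metabolite %in% markers & !is.na(ztbl$z), , drop = FALSE]
  aes_pt <- if ("group" %in% names(d)) {
    aes(x = .data$metabolite, y = .data$z, colour = .data$group)
  } else {
    aes(x = .data$metabolite, y = .data$z)
  }
  ggplot(d, aes_pt) +
    geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    geom_hline(yintercept = c(-2, 2), linetype = "dashed", colour = "red") +
    labs(x = NULL, y = "z-score", colour = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}
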