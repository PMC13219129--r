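#' RANO measurable-lesion rule
#'
#' A lesion is measurable when it is contrast-enhancing, visible on two or
#' more axial slices, and both perpendicular diameters strictly exceed
#' 10 mm.
#'
#' @param d1_mm,d2_mm Perpendicular diameters in mm.
#' @param axial_slices Number of axial slices on which the lesion is seen.
#' @param enhancing Logical contrast-enhancement flag.
#' @return Logical (vectorized).
#' @export
is_measurable <- function(d1_mm, d2_mm, axial_slices, enhancing = TRUE) {
  enhancing & axial_slices >= 2 & d1_mm > 10 & d2_mm > 10
}

#' Sum of perpendicular products of measurable enhancing lesions
#'
#' @param lesions Data frame with columns `d1_mm`, `d2_mm`,
#'   `axial_slices`, `enhancing` (see [make_lesion_records()]).
#' @return Total of `d1 * d2` (mm^2) over measurable lesions.
#' @export
sum_perpendicular_products <- function(lesions) {
  if (nrow(lesions) == 0L) return(0)
  m <- is_measurable(lesions$d1_mm, lesions$d2_mm, lesions$axial_slices,
                     lesions$enhancing %||% TRUE)
  sum(lesions$d1_mm[m] * lesions$d2_mm[m])
}

#' RANO progression classification
#'
#' Progression is declared when the follow-up sum of perpendicular products
#' reaches 125% or more of the baseline sum (a 25% or more increase,
#' regardless of steroid dose), or when a significant increase in
#' non-enhancing FLAIR/T2W lesions attributable to tumor is flagged.
#'
#' @param baseline,followup Lesion data frames (see
#'   [sum_perpendicular_products()]).
#' @param flair_increase Logical flag for significant non-enhancing
#'   FLAIR/T2W increase; `NA` when not assessed.
#' @return Logical progression flag.
#' @export
classify_progression <- function(baseline, followup, flair_increase = NA) {
  base_sum <- sum_perpendicular_products(baseline)
  fup_sum <- sum_perpendicular_products(followup)
  if (base_sum <= 0) {
    if (is.na(flair_increase)) {
      stopf("indeterminate: zero baseline lesion burden and no FLAIR assessment")
    }
    return(isTRUE(flair_increase))
  }
  isTRUE(flair_increase) || fup_sum >= 1.25 * base_sum
}

#' PFS in months between two dates
#'
#' Interval from the first post-radiotherapy MRI to the date of recurrence
#' or death, in months of 30.44 days (mean Gregorian month).
#'
#' @param baseline_date,end_date `Date`s (or strings coercible to Date).
#' @return Positive months.
#' @export
compute_pfs <- function(baseline_date, end_date) {
  d <- as.numeric(as.Date(end_date) - as.Date(baseline_date))
  if (any(d <= 0)) stopf("non-positive PFS interval")
  d / 30.44
}

#' Kaplan-Meier product-limit curve
#'
#' Right-censoring honored; the curve starts at 1, is non-increasing and
#' constant between event times.
#'
#' @param time_months Positive survival times.
#' @param event Binary event indicators (1 = event, 0 = censored).
#' @return Data frame: `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_curve <- function(time_months, event) {
  stopifnot(all(time_months > 0))
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' @param time_months,event Survival times and event flags.
#' @param group Two-level factor or vector.
#' @return List: `statistic` (chi-square, 1 df), `p_value`.
#' @export
logrank_test <- function(time_months, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stopf("log-rank test needs exactly 2 groups")
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ group)
  list(statistic = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit on a binary group
#'
#' Partial likelihood maximized by Newton iteration with Breslow tie
#' handling (Efron available). The hazard ratio is for the second factor
#' level relative to the first.
#'
#' @param time_months,event Survival times and event flags.
#' @param group Two-level factor or vector.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List: `hr`, `log_hr`, `se`, `p_value`, `fit` (the `coxph`
#'   object).
#' @export
cox_hr <- function(time_months, event, group, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stopf("Cox fit needs exactly 2 groups")
  ev_by_group <- tapply(event, group, sum)
  if (any(ev_by_group == 0)) {
    stopf("Cox fit cannot converge: no events in group '%s'",
          names(ev_by_group)[ev_by_group == 0][1])
  }
  fit <- survival::coxph(survival::Surv(time_months, event) ~ group,
                         ties = ties)
  s <- summary(fit)
  list(hr = unname(exp(stats::coef(fit)))[1],
       log_hr = unname(stats::coef(fit))[1],
       se = s$coefficients[1, "se(coef)"],
       p_value = s$coefficients[1, "Pr(>|z|)"],
       fit = fit)
}

#' Median split of predicted PFS
#'
#' The cutoff is the median predicted value; subjects at or below it form
#' the low group, above it the high group. For odd n with distinct values
#' this yields the (n+1)/2 / (n-1)/2 split (23 low / 22 high at n = 45),
#' assigning the median subject to the low group.
#'
#' @param predictions Predicted PFS values.
#' @return List: `low` and `high` (index vectors), `cutoff`, `group`
#'   (factor `"low"`/`"high"` per subject).
#' @export
stratify_by_median <- function(predictions) {
  if (length(unique(predictions)) < 2L) {
    stopf("degenerate split: all predictions equal")
  }
  cutoff <- stats::median(predictions)
  low <- which(predictions <= cutoff)
  high <- which(predictions > cutoff)
  grp <- factor(ifelse(predictions <= cutoff, "low", "high"),
                levels = c("high", "low"))
  list(low = low, high = high, cutoff = cutoff, group = grp)
}
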