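# Cohort-level statistics over per-hemisphere / per-lobe scaling results:
# ageing trends of the offset K, control-vs-AD contrasts (Cohen's d with
# pooled SD, two-sided Wilcoxon rank-sum), and bootstrap CIs for the mean.

#' Assign records to half-open age bins
#'
#' Bins are \code{[anchor + k*w, anchor + (k+1)*w)}, left-closed, so each
#' record falls in exactly one bin.  Wide cohorts typically use 10-year
#' bins; densely sampled young cohorts support 4-year bins.
#'
#' @param records data.frame with an \code{age} column (years).
#' @param width_years bin width (> 0).
#' @param anchor left edge of the first bin; defaults to the cohort
#'   minimum age.
#' @return the records with added columns \code{age_bin} (label
#'   \code{"[lo,hi)"}), \code{bin_lo}, \code{bin_hi}.
#' @export
age_bin <- function(records, width_years = 10, anchor = NULL) {
  stopifnot(is.data.frame(records), width_years > 0)
  if (nrow(records) == 0) {
    records$age_bin <- character(0)
    records$bin_lo <- numeric(0)
    records$bin_hi <- numeric(0)
    return(records)
  }
  if (is.null(anchor)) anchor <- min(records$age)
  k <- floor((records$age - anchor) / width_years)
  records$bin_lo <- anchor + k * width_years
  records$bin_hi <- records$bin_lo + width_years
  records$age_bin <- sprintf("[%g,%g)", records$bin_lo, records$bin_hi)
  records
}

#' Linear trend of the offset K with age
#'
#' OLS of K on age with the standard two-sided t-test on the slope.  In
#' healthy ageing the offset drifts down (negative slope); in AD it is
#' expected to be low and flat.
#'
#' @param records data.frame with columns \code{K} and \code{age}, at
#'   least 3 distinct ages.
#' @return list: \code{slope} (dex/year), \code{p_value},
#'   \code{intercept}, \code{n}.
#' @export
k_age_trend <- function(records) {
  stopifnot(is.data.frame(records), all(c("K", "age") %in% names(records)))
  if (length(unique(records$age)) < 3)
    stop("need >= 3 distinct ages for an age trend")
  fit <- stats::lm(K ~ age, data = records)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["age", "Estimate"]),
       p_value = unname(sm["age", "Pr(>|t|)"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       n = nrow(records))
}

#' Cohen's d with pooled standard deviation
#'
#' \eqn{d = (m_{Control} - m_{AD}) / s_p} with
#' \eqn{s_p = \sqrt{\frac{(n_C-1)s_C^2 + (n_A-1)s_A^2}{n_C + n_A - 2}}},
#' sample SDs using \eqn{n-1}.  Two identical constant groups give 0 by
#' convention; zero pooled SD with unequal means is an error.
#'
#' @param control_values,ad_values numeric vectors, each of length >= 2.
#' @return Cohen's d (positive when the control mean is larger).
#' @export
cohens_d <- function(control_values, ad_values) {
  n1 <- length(control_values); n2 <- length(ad_values)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- mean(control_values); m2 <- mean(ad_values)
  sp <- sqrt(((n1 - 1) * stats::var(control_values) +
              (n2 - 1) * stats::var(ad_values)) / (n1 + n2 - 2))
  if (sp == 0) {
    if (m1 == m2) return(0)
    stop("zero pooled SD with unequal means; Cohen's d undefined")
  }
  (m1 - m2) / sp
}

#' Percentile bootstrap 95\% CI for the mean
#'
#' \code{n_boot} resamples with replacement; the interval is the 2.5\% and
#' 97.5\% percentiles of the resampled means.  A seed is required — there
#' is no silent default entropy — and identical seed + input give a
#' bit-identical interval.  The caller's RNG state is left untouched.
#'
#' @param values numeric vector, length >= 2.
#' @param n_boot number of resamples (default 1000).
#' @param seed integer seed (required).
#' @return numeric vector \code{c(lo, hi)}.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 1000L, seed) {
  if (missing(seed)) stop("bootstrap_mean_ci requires an explicit seed")
  stopifnot(length(values) >= 2, n_boot >= 1)
  means <- with_seed(seed, {
    n <- length(values)
    vapply(seq_len(n_boot),
           function(i) mean(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  unname(stats::quantile(means, c(0.025, 0.975)))
}

#' Control-vs-AD contrast for one lobe (and optionally one age bin)
#'
#' Cohen's d (pooled SD) plus a two-sided Wilcoxon rank-sum p-value for K
#' between the control and AD groups.  The rank-sum test is
#' \code{stats::wilcox.test}: exact for small samples (n < 50 per group)
#' without ties, normal approximation with continuity correction otherwise.
#'
#' @param records cohort data.frame (columns \code{partition},
#'   \code{group}, \code{K}, optionally \code{age_bin}).
#' @param lobe partition name to contrast.
#' @param bin optional \code{age_bin} label to restrict to.
#' @return one-row data.frame: \code{lobe}, \code{bin}, \code{cohens_d},
#'   \code{p_ranksum}, \code{n_control}, \code{n_AD}, \code{available}.
#'   When either group is empty the contrast is marked unavailable with NA
#'   statistics.
#' @export
group_compare <- function(records, lobe, bin = NULL) {
  stopifnot(is.data.frame(records),
            all(c("partition", "group", "K") %in% names(records)))
  sel <- records$partition == lobe
  if (!is.null(bin)) sel <- sel & records$age_bin == bin
  ctrl <- records$K[sel & records$group == "control"]
  ad <- records$K[sel & records$group == "AD"]
  if (length(ctrl) == 0 || length(ad) == 0)
    return(data.frame(lobe = lobe, bin = bin %||% NA_character_,
                      cohens_d = NA_real_, p_ranksum = NA_real_,
                      n_control = length(ctrl), n_AD = length(ad),
                      available = FALSE, stringsAsFactors = FALSE))
  wt <- suppressWarnings(stats::wilcox.test(ctrl, ad,
                                            alternative = "two.sided"))
  data.frame(lobe = lobe, bin = bin %||% NA_character_,
             cohens_d = cohens_d(ctrl, ad),
             p_ranksum = wt$p.value,
             n_control = length(ctrl), n_AD = length(ad),
             available = TRUE, stringsAsFactors = FALSE)
}
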