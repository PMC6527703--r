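# Core of the scaling analysis: the topological area correction, the
# log-log scaling coordinates, the offset K at fixed slope 5/4, and the
# per-hemisphere exponent estimators.
#
# All logarithms here are base 10: x = log10(Ae), y = log10(At*sqrt(T)),
# and K is reported in dex.  Slope estimates are invariant to the base;
# offsets are not, so K values are only comparable between runs using the
# same convention.

PREDICTED_ALPHA <- 5 / 4

#' Filter partitions with unusable integrated curvature
#'
#' Partitions whose integrated Gaussian curvature is near zero (medial-wall
#' remnants, very small partitions) cannot receive an adequate topological
#' correction: the correction factor 4*pi/I_G blows up or changes sign.
#' Retention requires \code{I_G > epsilon} strictly.
#'
#' @param partitions data.frame with at least an \code{I_G} column.
#' @param epsilon retention threshold (steradians).  Default 1\% of the full
#'   closed-surface curvature \eqn{4\pi}.
#' @return list with \code{retained} and \code{excluded} data.frames; the
#'   excluded one carries a \code{reason} column.
#' @export
validity_filter <- function(partitions, epsilon = 0.01 * 4 * pi) {
  stopifnot(is.data.frame(partitions), "I_G" %in% names(partitions))
  keep <- partitions$I_G > epsilon
  excluded <- partitions[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "near-zero curvature"
  list(retained = partitions[keep, , drop = FALSE], excluded = excluded)
}

#' Topological correction: reconstruct whole-cortex equivalent areas
#'
#' Rescales each partition's areas by \eqn{c = 4\pi / I_G^P}, giving the
#' areas of the putative closed cortex that would share the partition's
#' thickness, gyrification index and average Gaussian curvatures.  The
#' gyrification index is preserved exactly, and the raw-to-corrected
#' displacement in the (x, y) plane is \eqn{(\log_{10} c, \log_{10} c)},
#' i.e. along a slope-1 contour of constant gyrification index.
#'
#' @param partitions data.frame with columns \code{A_t}, \code{A_e},
#'   \code{T}, \code{I_G} (other columns are passed through).
#' @return the input data.frame with added columns
#'   \code{correction_factor}, \code{A_e_prime}, \code{A_t_prime},
#'   \code{x_prime}, \code{y_prime}, \code{K}.
#' @export
correct_areas <- function(partitions) {
  stopifnot(is.data.frame(partitions),
            all(c("A_t", "A_e", "T", "I_G") %in% names(partitions)))
  if (any(partitions$I_G <= 0))
    stop("non-positive integrated curvature; partition must be excluded ",
         "(run validity_filter first)")
  if (any(partitions$A_t <= 0 | partitions$A_e <= 0 | partitions$T <= 0))
    stop("areas and thickness must be positive")
  cf <- 4 * pi / partitions$I_G
  out <- partitions
  out$correction_factor <- cf
  out$A_e_prime <- cf * partitions$A_e
  out$A_t_prime <- cf * partitions$A_t
  out$x_prime <- log10(out$A_e_prime)
  out$y_prime <- log10(out$A_t_prime * sqrt(out$T))
  out$K <- offset_k(out$A_e_prime, out$A_t_prime, out$T)
  out
}

#' Scaling offset K at the predicted slope 5/4
#'
#' \eqn{K = \log_{10}(A_t'\sqrt{T}) - \frac{5}{4}\log_{10}(A_e')}.  Applied
#' to corrected lobe values this is the lobe offset; applied to raw
#' whole-hemisphere values it is the hemisphere offset.  The slope is fixed
#' at exactly 5/4 (never a fitted exponent), so K isolates the offset from
#' the exponent.
#'
#' @param A_e_prime exposed area (mm^2).
#' @param A_t_prime total area (mm^2).
#' @param T average thickness (mm).
#' @return offset K (dimensionless, dex); vectorised.
#' @export
offset_k <- function(A_e_prime, A_t_prime, T) {
  if (any(A_e_prime <= 0 | A_t_prime <= 0 | T <= 0))
    stop("offset_k requires strictly positive areas and thickness")
  log10(A_t_prime * sqrt(T)) - PREDICTED_ALPHA * log10(A_e_prime)
}

#' Ordinary least-squares slope
#'
#' @param x,y numeric vectors (log10 coordinates), at least two distinct x.
#' @return list with \code{slope} and \code{intercept}.
#' @export
ols_slope <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (diff(range(x)) == 0) stop("all x equal; slope undefined")
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  list(slope = slope, intercept = my - slope * mx)
}

#' Covariance-corrected slope across partitions of one hemisphere
#'
#' Errors-in-variables correction for the dispersion that the shared
#' correction term \eqn{\log I_G^P} injects into both coordinates:
#' \deqn{\gamma = \frac{\sigma_{11}^2 - \sigma_{22}^2}
#'                     {2\sigma_{12}^2 - \sigma_{\log I_G}^2}, \qquad
#'       \alpha = \frac{1}{\gamma + \sqrt{1 + \gamma^2}}.}
#' Here \eqn{\sigma_{11}^2,\sigma_{22}^2,\sigma_{12}^2} are the sample
#' (co)variances of \eqn{x' = \log_{10} A_e'} and
#' \eqn{y' = \log_{10}(A_t'\sqrt{T})} across the hemisphere's partitions.
#' With \eqn{\sigma^2_{\log I_G} = 0} this reduces to a standardised
#' major-axis-style estimator; on exactly collinear data it returns the
#' generating slope exactly.  The formula is applied as stated for
#' anti-correlated data too; a negative denominator is flagged in the
#' diagnostics of \code{fit_hemisphere}.
#'
#' @param sigma11_sq variance of x'.
#' @param sigma22_sq variance of y'.
#' @param sigma12_sq covariance of x' and y'.
#' @param sigma2_logIG variance of the log10 correction term (default 0).
#' @return the corrected exponent (positive branch).
#' @export
corrected_slope <- function(sigma11_sq, sigma22_sq, sigma12_sq,
                            sigma2_logIG = 0) {
  denom <- 2 * sigma12_sq - sigma2_logIG
  if (abs(denom) < 1e-12)
    stop("degenerate covariance; corrected estimator undefined")
  gamma <- (sigma11_sq - sigma22_sq) / denom
  1 / (gamma + sqrt(1 + gamma^2))
}

#' Estimate the variance of the log10 correction term from replicates
#'
#' Sample variance of \code{log10(I_G)} across repeated measurements of the
#' same partitions, for use as \code{sigma2_logIG} in the corrected
#' estimator.
#'
#' @param I_G_replicates numeric vector of repeated I_G measurements.
#' @return sample variance of log10(I_G).
#' @export
estimate_sigma2_logIG <- function(I_G_replicates) {
  if (any(I_G_replicates <= 0)) stop("I_G replicates must be positive")
  stats::var(log10(I_G_replicates))
}

#' Per-hemisphere scaling exponent across its lobes
#'
#' Fits \eqn{y' = \alpha x' + b} across the (typically four) corrected
#' lobes of one hemisphere, yielding a lobe-based exponent for that single
#' cortex.  Method \code{"ols"} is ordinary least squares; method
#' \code{"corrected"} feeds the sample covariances to
#' \code{\link{corrected_slope}}.
#'
#' @param corrected data.frame from \code{\link{correct_areas}} (needs
#'   \code{x_prime}, \code{y_prime}); at least 3 rows.
#' @param method "ols" (default) or "corrected".
#' @param sigma2_logIG variance of the log correction term for the
#'   corrected method (default 0).
#' @return list of class \code{hemisphere_fit}: \code{alpha},
#'   \code{intercept}, \code{method}, \code{n_partitions}, covariance
#'   diagnostics \code{sigma11_sq}, \code{sigma22_sq}, \code{sigma12_sq},
#'   \code{sigma2_logIG}, \code{gamma}, and
#'   \code{denominator_negative} flag.
#' @export
fit_hemisphere <- function(corrected, method = c("ols", "corrected"),
                           sigma2_logIG = 0) {
  method <- match.arg(method)
  stopifnot(is.data.frame(corrected),
            all(c("x_prime", "y_prime") %in% names(corrected)))
  if (nrow(corrected) < 3) {
    missing_lobes <- setdiff(lobe_names,
                             as.character(corrected$partition %||% character()))
    stop("need >= 3 valid lobes to fit a hemisphere; missing/excluded: ",
         paste(missing_lobes, collapse = ", "))
  }
  x <- corrected$x_prime; y <- corrected$y_prime
  s11 <- stats::var(x); s22 <- stats::var(y); s12 <- stats::cov(x, y)
  denom <- 2 * s12 - sigma2_logIG
  if (method == "ols") {
    f <- ols_slope(x, y)
    alpha <- f$slope; intercept <- f$intercept
    gamma <- NA_real_
  } else {
    alpha <- corrected_slope(s11, s22, s12, sigma2_logIG)
    gamma <- (s11 - s22) / denom
    intercept <- mean(y) - alpha * mean(x)
  }
  structure(list(alpha = alpha, intercept = intercept, method = method,
                 n_partitions = nrow(corrected),
                 sigma11_sq = s11, sigma22_sq = s22, sigma12_sq = s12,
                 sigma2_logIG = sigma2_logIG, gamma = gamma,
                 denominator_negative = denom < 0),
            class = "hemisphere_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hemisphere_fit <- function(x, ...) {
  cat(sprintf("hemisphere_fit (%s): alpha = %.6f over %d partitions\n",
              x$method, x$alpha, x$n_partitions))
  invisible(x)
}

#' Group-level scaling exponent across whole hemispheres
#'
#' OLS of \eqn{y = \log_{10}(A_t\sqrt{T})} on \eqn{x = \log_{10}(A_e)}
#' across a cohort of whole (uncorrected) hemispheres — the group-based
#' exponent, as opposed to the within-cortex lobe-based one.
#'
#' @param x,y numeric vectors, one entry per hemisphere; at least 3.
#' @return list of class \code{group_fit}: \code{alpha}, \code{intercept},
#'   \code{ci95} (95\% confidence bounds on the slope), \code{n}.
#' @export
fit_group <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need >= 3 hemispheres for a group fit")
  if (diff(range(x)) == 0) stop("all x equal; slope undefined")
  fit <- stats::lm(y ~ x)
  ci <- suppressWarnings(stats::confint(fit, "x", level = 0.95))
  structure(list(alpha = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 ci95 = unname(ci[1, ]), n = length(x)),
            class = "group_fit")
}

#' Fractal dimension implied by the scaling exponent
#'
#' Under \eqn{A_t \propto A_e^\alpha} at fixed thickness, and with the
#' exposed area growing as the square of the linear scale
#' (\eqn{A_e \propto L^2}), the total surface behaves as
#' \eqn{A_t \propto L^{2\alpha}} — a self-similar surface of dimension
#' \eqn{2\alpha}.  At the predicted \eqn{\alpha = 5/4} the cortical ribbon
#' has fractal dimension 2.5.
#'
#' @param alpha scaling exponent (> 0).
#' @return implied fractal dimension \code{2 * alpha}.
#' @export
implied_fractal_dimension <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  2 * alpha
}
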