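# Synthetic surfaces and cohorts with known ground truth.  The generators
# provide every input the pipeline needs: analytic meshes for the curvature
# primitives, lobe-level tables that satisfy At*sqrt(T) = k*Ae^alpha exactly
# by construction, and ageing/Alzheimer cohorts for the group statistics.

# run expr with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Icosphere: subdivided icosahedron projected onto a sphere
#'
#' Closed genus-0 test mesh; its angle deficits sum to exactly \eqn{4\pi}
#' at every subdivision level while its area converges to \eqn{4\pi r^2}
#' from below (inscribed polyhedron).
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 =
#'   icosahedron, 12 vertices / 20 faces).
#' @return a \code{triangulated_surface}.
#' @export
make_icosphere <- function(radius = 1, subdivisions = 0L) {
  stopifnot(radius > 0, subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    nv <- nrow(v)
    midkey <- new.env(hash = TRUE)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- midkey[[key]]
      if (!is.null(idx)) return(idx)
      newv[[length(newv) + 1L]] <<- (v[i, ] + v[j, ]) / 2
      idx <- nv + length(newv)
      midkey[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(t - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  v <- v / row_norm(v) * radius
  triangulated_surface(v, f,
                       name = sprintf("icosphere_r%g_s%d", radius, subdivisions))
}

#' Torus mesh (genus 1)
#'
#' Control mesh for the Gauss-Bonnet checks: the Euler characteristic is 0,
#' so the angle deficits sum to 0 regardless of resolution.
#'
#' @param major_radius distance from torus centre to tube centre (mm).
#' @param minor_radius tube radius (mm), must be smaller than the major one.
#' @param n_major,n_minor grid resolution around each circle.
#' @return a closed \code{triangulated_surface} with \eqn{\chi = 0}.
#' @export
make_torus <- function(major_radius = 2, minor_radius = 0.7,
                       n_major = 24L, n_minor = 12L) {
  stopifnot(major_radius > minor_radius, minor_radius > 0,
            n_major >= 3, n_minor >= 3)
  u <- 2 * pi * (seq_len(n_major) - 1L) / n_major
  w <- 2 * pi * (seq_len(n_minor) - 1L) / n_minor
  g <- expand.grid(u = u, w = w)
  v <- cbind((major_radius + minor_radius * cos(g$w)) * cos(g$u),
             (major_radius + minor_radius * cos(g$w)) * sin(g$u),
             minor_radius * sin(g$w))
  idx <- function(i, j)  # wrap both directions; 1-based
    ((j - 1L) %% n_minor) * n_major + ((i - 1L) %% n_major) + 1L
  f <- matrix(0L, 2L * n_major * n_minor, 3L)
  r <- 1L
  for (j in seq_len(n_minor)) for (i in seq_len(n_major)) {
    a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    f[r, ] <- c(a, b, c); f[r + 1L, ] <- c(a, c, d)
    r <- r + 2L
  }
  triangulated_surface(v, f, name = "torus")
}

#' Gyrified sphere: a sphere with sinusoidal radial bumps
#'
#' Emulates a folded (pial) surface with controllable gyrification.  Each
#' unit-sphere direction \eqn{(\theta,\varphi)} is displaced radially to
#' \eqn{r\,(1 + a\,\sin(f\theta)\sin(f\varphi))}; an integer frequency keeps
#' the displacement continuous across the azimuthal seam, and amplitude
#' \eqn{a < 1} keeps the radius positive (no self-intersection in this
#' family).  The mesh stays closed genus 0, so its integrated curvature is
#' still \eqn{4\pi}, while its area (hence its gyrification index against
#' its convex hull) grows with the amplitude.
#'
#' @param radius base sphere radius (mm).
#' @param bump_amplitude relative bump height \eqn{a}, in \[0, 1).
#' @param bump_frequency integer angular frequency \eqn{f}.
#' @param subdivisions icosphere subdivision level of the support mesh.
#' @param thickness_mean constant cortical thickness assigned to every
#'   vertex (mm).
#' @return list with \code{surface} (a \code{triangulated_surface}) and
#'   \code{thickness} (a \code{vertex_field}).
#' @export
make_gyrified_sphere <- function(radius = 50, bump_amplitude = 0.15,
                                 bump_frequency = 8L, subdivisions = 4L,
                                 thickness_mean = 2.5) {
  if (bump_amplitude < 0 || bump_amplitude >= 1)
    stop("bump_amplitude must be in [0, 1)")
  if (bump_frequency != round(bump_frequency))
    stop("bump_frequency must be an integer")
  base <- make_icosphere(radius = 1, subdivisions = subdivisions)
  v <- base$vertices
  theta <- acos(pmin(1, pmax(-1, v[, 3])))   # polar angle
  phi <- atan2(v[, 2], v[, 1])               # azimuth
  r <- radius * (1 + bump_amplitude * sin(bump_frequency * theta) *
                   sin(bump_frequency * phi))
  s <- triangulated_surface(v * r, base$triangles,
                            name = sprintf("gyrified_a%g_f%d", bump_amplitude,
                                           bump_frequency))
  list(surface = s,
       thickness = vertex_field(rep(thickness_mean, nrow(v)), s,
                                role = "thickness"))
}

#' Octant labels: deterministic 8-way partition by coordinate signs
#'
#' Label ids 0-7 encode the sign octant (bit 4 for x < 0, bit 2 for y < 0,
#' bit 1 for z < 0), so the all-positive octant is label 0.  A vertex with a
#' coordinate exactly 0 is assigned the octant with the lower label id,
#' i.e. the zero is treated as positive.
#'
#' @param surface a \code{triangulated_surface}.
#' @return a \code{label_field} over the vertices with a label table naming
#'   each octant.
#' @export
octant_labels <- function(surface) {
  v <- surface$vertices
  lab <- 4L * (v[, 1] < 0) + 2L * (v[, 2] < 0) + 1L * (v[, 3] < 0)
  signs <- expand.grid(z = c("+", "-"), y = c("+", "-"), x = c("+", "-"))
  tab <- data.frame(label_id = 0:7,
                    region = paste0("octant_", signs$x, signs$y, signs$z),
                    stringsAsFactors = FALSE)
  label_field(lab, label_table = tab, surface = surface)
}

lobe_names <- c("frontal", "parietal", "temporal", "occipital")

#' Specification of a synthetic lobe-table cohort
#'
#' Encodes the generative model used throughout validation: each subject's
#' hemisphere carries a true offset \eqn{K = K_0 + s_{age}\,age}, and its
#' four lobes carry corrected exposed areas around a hemisphere-scale mean,
#' with total areas set so that
#' \eqn{\log_{10}(A_t'\sqrt{T}) = K + \alpha \log_{10}(A_e')} holds exactly
#' up to the configured noise.  Raw (uncorrected) lobe rows are emitted by
#' splitting each quantity with per-lobe curvature fractions of \eqn{4\pi},
#' so the topological correction inverts the split exactly.
#'
#' @param n_subjects number of subjects (each contributes both hemispheres).
#' @param alpha_gen generating scaling exponent.
#' @param K0 offset at age 0 (dex, i.e. log10 units).
#' @param K_age_slope offset drift per year of age (dex/year).
#' @param age_range two ages (years); subject ages drawn uniformly.
#' @param noise_sd_y sd of Gaussian noise added to y = log10(At'*sqrt(T))
#'   per lobe (dex).
#' @param noise_sd_logIG optional sd of log10 noise on the integrated
#'   curvature split, to exercise the corrected slope estimator.
#' @param lobe_curvature_fractions fractions of 4*pi carried by
#'   frontal/parietal/temporal/occipital; must sum to 1.
#' @param lobe_gi_multipliers per-lobe multipliers on the corrected exposed
#'   area; since At' follows the scaling law, these also spread the lobes'
#'   gyrification indices.
#' @param Ae_mean cohort mean corrected exposed area (mm^2).
#' @param subject_sd_x sd of the subject-level log10 size jitter (dex).
#' @param T_mean,T_sd mean and sd of lobe thickness (mm).
#' @param seed integer seed; all draws flow from this one stream.
#' @return a list of class \code{lobe_table_spec}.
#' @export
lobe_table_spec <- function(n_subjects = 50L,
                            alpha_gen = 1.25,
                            K0 = -0.56,
                            K_age_slope = -0.001,
                            age_range = c(20, 80),
                            noise_sd_y = 0.01,
                            noise_sd_logIG = 0,
                            lobe_curvature_fractions =
                              c(frontal = 0.35, parietal = 0.25,
                                temporal = 0.25, occipital = 0.15),
                            lobe_gi_multipliers =
                              c(frontal = 1.25, parietal = 1.0,
                                temporal = 0.95, occipital = 0.70),
                            Ae_mean = 40000,
                            subject_sd_x = 0.04,
                            T_mean = 2.5, T_sd = 0.2,
                            seed = 1L) {
  f <- unname(lobe_curvature_fractions)
  if (length(f) != 4L || any(f <= 0) || abs(sum(f) - 1) > 1e-12)
    stop("lobe_curvature_fractions must be 4 positive values summing to 1")
  if (length(lobe_gi_multipliers) != 4L || any(lobe_gi_multipliers <= 0))
    stop("lobe_gi_multipliers must be 4 positive values")
  stopifnot(n_subjects >= 1, alpha_gen > 0, length(age_range) == 2,
            age_range[1] <= age_range[2], noise_sd_y >= 0,
            noise_sd_logIG >= 0, Ae_mean > 0, T_mean > 0, T_sd >= 0,
            subject_sd_x >= 0)
  structure(list(
    n_subjects = as.integer(n_subjects), alpha_gen = alpha_gen, K0 = K0,
    K_age_slope = K_age_slope, age_range = as.numeric(age_range),
    noise_sd_y = noise_sd_y, noise_sd_logIG = noise_sd_logIG,
    lobe_curvature_fractions = stats::setNames(f, lobe_names),
    lobe_gi_multipliers = stats::setNames(unname(lobe_gi_multipliers), lobe_names),
    Ae_mean = Ae_mean, subject_sd_x = subject_sd_x,
    T_mean = T_mean, T_sd = T_sd, seed = as.integer(seed)),
    class = "lobe_table_spec")
}

# one subject x hemisphere block of four raw lobe rows + its truth row;
# K_offset overrides the age model when not NA (used for the AD group)
simulate_block <- function(spec, subject, hemisphere, age, K_true,
                           lobe_deltas = rep(0, 4)) {
  f <- spec$lobe_curvature_fractions
  mult <- spec$lobe_gi_multipliers
  size_jitter <- 10^stats::rnorm(1, 0, spec$subject_sd_x)
  Ae_prime <- spec$Ae_mean * size_jitter * mult
  T_lobe <- pmax(0.1, stats::rnorm(4, spec$T_mean, spec$T_sd))
  eps_y <- stats::rnorm(4, 0, spec$noise_sd_y)
  y_prime <- K_true + lobe_deltas + spec$alpha_gen * log10(Ae_prime) + eps_y
  At_prime <- 10^y_prime / sqrt(T_lobe)
  IG_noise <- if (spec$noise_sd_logIG > 0)
    10^stats::rnorm(4, 0, spec$noise_sd_logIG) else rep(1, 4)
  data.frame(
    subject = subject, hemisphere = hemisphere, age = age,
    partition = lobe_names,
    A_t = f * At_prime, A_e = f * Ae_prime, T = T_lobe,
    I_G = f * 4 * pi * IG_noise,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate raw per-lobe morphology tables with known truth
#'
#' Generates, for every subject and hemisphere, four raw lobe rows
#' (\code{A_t}, \code{A_e}, \code{T}, \code{I_G}) built by inverting the
#' topological correction, so that \code{correct_areas()} restores the
#' generating corrected values exactly and, at zero noise, the fitted
#' per-hemisphere slope equals \code{alpha_gen} to machine precision.
#'
#' @param spec a \code{lobe_table_spec}.
#' @return list with \code{raw} (data.frame: subject, hemisphere, age,
#'   partition, A_t, A_e, T, I_G) and \code{truth} (data.frame: subject,
#'   hemisphere, age, alpha_gen, K_true).
#' @export
simulate_lobe_table <- function(spec = lobe_table_spec()) {
  stopifnot(inherits(spec, "lobe_table_spec"))
  with_seed(spec$seed, {
    raw <- vector("list", spec$n_subjects * 2L)
    truth <- vector("list", spec$n_subjects * 2L)
    k <- 0L
    for (s in seq_len(spec$n_subjects)) {
      age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
      for (h in c("left", "right")) {
        k <- k + 1L
        K_true <- spec$K0 + spec$K_age_slope * age
        raw[[k]] <- simulate_block(spec, sprintf("sub%04d", s), h, age, K_true)
        truth[[k]] <- data.frame(subject = sprintf("sub%04d", s),
                                 hemisphere = h, age = age,
                                 alpha_gen = spec$alpha_gen, K_true = K_true,
                                 stringsAsFactors = FALSE)
      }
    }
    list(raw = do.call(rbind, raw), truth = do.call(rbind, truth))
  })
}

#' Specification of a synthetic ageing/Alzheimer cohort
#'
#' Extends \code{lobe_table_spec} with a control/patient mix.  Controls
#' follow the ageing offset drift \eqn{K_0 + s_{age}\,age}; Alzheimer (AD)
#' subjects sit at a constant low offset \code{ad_k_level} with per-lobe
#' shifts whose magnitudes default to the ordering temporal > frontal
#' \eqn{\approx} parietal > occipital, i.e. the temporal lobe is most
#' affected and the occipital least.
#'
#' @param ... arguments forwarded to \code{lobe_table_spec}; this cohort
#'   defaults to ages 60-90 and a K noise of 0.02 dex.
#' @param control_fraction fraction of subjects in the control group.
#' @param ad_k_level constant offset level of the AD group (dex).
#' @param ad_lobe_deltas named per-lobe shifts added to \code{ad_k_level}
#'   (dex, negative = lower offset).
#' @return list of class \code{cohort_spec} (also a \code{lobe_table_spec}).
#' @export
cohort_spec <- function(...,
                        control_fraction = 0.5,
                        ad_k_level = -0.655,
                        ad_lobe_deltas = c(frontal = -0.018,
                                           parietal = -0.016,
                                           temporal = -0.030,
                                           occipital = -0.004)) {
  dots <- list(...)
  if (is.null(dots$age_range)) dots$age_range <- c(60, 90)
  if (is.null(dots$noise_sd_y)) dots$noise_sd_y <- 0.02
  if (is.null(dots$n_subjects)) dots$n_subjects <- 100L
  base <- do.call(lobe_table_spec, dots)
  if (control_fraction < 0 || control_fraction > 1)
    stop("control_fraction must be in [0, 1]")
  stopifnot(length(ad_lobe_deltas) == 4L,
            all(lobe_names %in% names(ad_lobe_deltas)))
  base$control_fraction <- control_fraction
  base$ad_k_level <- ad_k_level
  base$ad_lobe_deltas <- ad_lobe_deltas[lobe_names]
  class(base) <- c("cohort_spec", "lobe_table_spec")
  base
}

#' Simulate a control/AD cohort of corrected lobe records
#'
#' Raw lobe tables are generated per group (controls with the ageing drift,
#' AD at a constant low offset with per-lobe shifts) and then pushed through
#' the package's own pipeline: \code{correct_areas()} reconstructs the
#' whole-cortex equivalents and \code{fit_hemisphere()} supplies each
#' hemisphere's lobe-based slope.
#'
#' @param spec a \code{cohort_spec}.
#' @return data.frame of cohort records: subject, hemisphere, partition,
#'   age, sex, group, K, alpha, A_e_prime, A_t_prime, T.
#' @export
simulate_ad_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- with_seed(spec$seed, {
    out <- vector("list", spec$n_subjects * 2L)
    k <- 0L
    n_control <- round(spec$control_fraction * spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
      sex <- sample(c("F", "M"), 1)
      group <- if (s <= n_control) "control" else "AD"
      for (h in c("left", "right")) {
        k <- k + 1L
        if (group == "control") {
          K_true <- spec$K0 + spec$K_age_slope * age
          deltas <- rep(0, 4)
        } else {
          K_true <- spec$ad_k_level
          deltas <- unname(spec$ad_lobe_deltas)
        }
        blk <- simulate_block(spec, sprintf("sub%04d", s), h, age, K_true,
                              lobe_deltas = deltas)
        blk$sex <- sex
        blk$group <- group
        out[[k]] <- blk
      }
    }
    do.call(rbind, out)
  })
  corrected <- correct_areas(rows)
  # per-hemisphere lobe-based slope, repeated across that hemisphere's lobes
  key <- paste(corrected$subject, corrected$hemisphere)
  alpha <- vapply(split(corrected, key), function(d)
    fit_hemisphere(d, method = "ols")$alpha, numeric(1))
  corrected$alpha <- alpha[key]
  data.frame(subject = corrected$subject, hemisphere = corrected$hemisphere,
             partition = corrected$partition, age = corrected$age,
             sex = corrected$sex, group = corrected$group,
             K = corrected$K, alpha = corrected$alpha,
             A_e_prime = corrected$A_e_prime,
             A_t_prime = corrected$A_t_prime, T = corrected$T,
             stringsAsFactors = FALSE, row.names = NULL)
}
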