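# Phantom-cohort generator.
#
# Each subject volume is built as
#   y(v) = baseline(v) + beta_age(v) * age_i + delta * atrophy(v) * patient_i
#          + eps,   eps ~ N(0, noise_sd^2),
# i.e. exactly the statistical structure the age-correction method assumes:
# a smooth baseline grey-matter map, a (possibly regional) linear age slope,
# a spatially localised disease offset, and additive Gaussian noise (no
# noise model is prescribed by the method; Gaussian is the conventional
# choice).  Ground truth is returned so every downstream module has a
# recovery oracle.  All randomness flows from the single spec seed.

#' Describe a voxel region
#'
#' @param type `"sphere"` or `"box"`.
#' @param center Sphere center, 0-based voxel coordinates (i, j, k).
#' @param radius Sphere radius in voxels (voxel included iff its center is
#'   within `radius` of `center`).
#' @param lower,upper Box corners, inclusive, 0-based.
#' @return A `region_spec` list.
#' @export
region_spec <- function(type = c("sphere", "box"), center = NULL,
                        radius = NULL, lower = NULL, upper = NULL) {
  type <- match.arg(type)
  if (type == "sphere" && (is.null(center) || is.null(radius)))
    stop_spec_error("sphere region needs center and radius")
  if (type == "box" && (is.null(lower) || is.null(upper)))
    stop_spec_error("box region needs lower and upper")
  structure(list(type = type, center = center, radius = radius,
                 lower = lower, upper = upper), class = "region_spec")
}

region_mask <- function(region, grid) {
  idx <- arrayInd(seq_len(prod(grid)), grid) - 1L   # 0-based coords
  inside <- if (region$type == "sphere") {
    if (any(region$center < 0) || any(region$center > grid - 1L))
      stop_spec_error("sphere center outside grid")
    rowSums((t(t(idx) - region$center))^2) <= region$radius^2
  } else {
    if (any(region$lower < 0) || any(region$upper > grid - 1L) ||
        any(region$lower > region$upper))
      stop_spec_error("box region outside grid or inverted")
    apply(t(t(idx) >= region$lower) & t(t(idx) <= region$upper), 1, all)
  }
  array(inside, dim = grid)
}

#' Specify a phantom cohort
#'
#' Defaults describe a desk-scale cohort: a 16^3 grid of 1 mm voxels, 25
#' subjects per group, ages uniform on 60-90 years, baseline grey-matter
#' level 0.5 with smooth spatial variation, a linear age slope of -0.003
#' grey-matter units per year, and noise SD 0.02.
#'
#' @param grid Grid shape, default `c(16, 16, 16)`.
#' @param n_controls,n_patients Group sizes (>= 3 each).
#' @param age_range Control age interval (years), default 60-90.
#' @param age_shift_patients Years added to patient ages (the
#'   age-disease coupling; negative = patients younger). Default 0.
#' @param match_patient_ages Draw patient ages by resampling control ages
#'   (matched-cohort design: group age distributions identical by
#'   construction, not by luck). Requires `n_patients <= n_controls`;
#'   `age_shift_patients` still applies afterwards. Default `FALSE`.
#' @param baseline Mean grey-matter level, default 0.5.
#' @param baseline_roughness SD of the random field smoothed into the
#'   baseline map, default 0.05.
#' @param baseline_fwhm Smoothing FWHM (mm) for the baseline map, default 6.
#' @param beta_age Age slope in grey-matter units per year, default -0.003.
#' @param beta_region Optional [region_spec()] restricting the slope; `NULL`
#'   (default) means the slope is constant over the whole grid.
#' @param beta_smooth_fwhm FWHM (mm) used to smooth a regional slope's edge
#'   into a smooth field, default 2.
#' @param atrophy_delta Disease offset in grey-matter units (negative =
#'   atrophy), default 0.
#' @param atrophy_region [region_spec()] of the diseased region (required
#'   when `atrophy_delta != 0`).
#' @param noise_sd Additive noise SD, default 0.02.
#' @param voxel_size_mm Per-axis voxel size, default 1 mm isotropic.
#' @param seed Integer seed; same seed, bit-identical cohort.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(16L, 16L, 16L), n_controls = 25L,
                         n_patients = 25L, age_range = c(60, 90),
                         age_shift_patients = 0, match_patient_ages = FALSE,
                         baseline = 0.5,
                         baseline_roughness = 0.05, baseline_fwhm = 6,
                         beta_age = -0.003, beta_region = NULL,
                         beta_smooth_fwhm = 2, atrophy_delta = 0,
                         atrophy_region = NULL, noise_sd = 0.02,
                         voxel_size_mm = c(1, 1, 1), seed = 1L) {
  if (noise_sd < 0) stop_spec_error("noise_sd must be >= 0")
  if (n_controls < 3L || n_patients < 3L)
    stop_spec_error("need >= 3 subjects per group")
  if (age_range[1] >= age_range[2] || age_range[1] <= 0)
    stop_spec_error("age_range must be an increasing positive interval")
  if (atrophy_delta != 0 && is.null(atrophy_region))
    stop_spec_error("atrophy_delta != 0 needs an atrophy_region")
  if (match_patient_ages && n_patients > n_controls)
    stop_spec_error("match_patient_ages needs n_patients <= n_controls")
  spec <- list(grid = as.integer(grid), n_controls = as.integer(n_controls),
               n_patients = as.integer(n_patients), age_range = age_range,
               age_shift_patients = age_shift_patients,
               match_patient_ages = match_patient_ages, baseline = baseline,
               baseline_roughness = baseline_roughness,
               baseline_fwhm = baseline_fwhm, beta_age = beta_age,
               beta_region = beta_region, beta_smooth_fwhm = beta_smooth_fwhm,
               atrophy_delta = atrophy_delta, atrophy_region = atrophy_region,
               noise_sd = noise_sd, voxel_size_mm = voxel_size_mm,
               seed = as.integer(seed))
  # validate regions against the grid now rather than at generation time
  if (!is.null(beta_region)) region_mask(beta_region, spec$grid)
  if (!is.null(atrophy_region)) region_mask(atrophy_region, spec$grid)
  structure(spec, class = "phantom_spec")
}

#' The age-confounded classification scenario
#'
#' The situation the correction exists for, at the operating point the
#' method was reported in: age and disease effects are equally directed
#' (both lower grey matter) and the groups are age-MATCHED by construction
#' (patient ages resample control ages, as in a matched cohort design), so
#' the confound
#' acts purely through within-group age variance — older controls drift
#' toward the atrophy pattern, younger patients away from it.  The age
#' slope (-0.005 grey-matter units per year, the steep end of focal
#' healthy-ageing decline) is active in a smooth spherical region of radius
#' 6 voxels; the disease offset of -0.05 units (roughly a decade of that
#' decline) sits in a concentric sphere of radius 3 inside it.  The noise
#' SD of 0.06 was calibrated once so that uncorrected split-half accuracy
#' lands near 80%, the regime the method's reported accuracies live in;
#' see the methods vignette.
#'
#' @param seed Integer seed.
#' @param age_shift_patients Years added to patient ages; default 0
#'   (age-matched, as in the classification cohort the method was
#'   evaluated on).
#' @param n_controls,n_patients Group sizes, default 30 each.
#' @param ... Further overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
confounded_phantom_spec <- function(seed = 1L, age_shift_patients = 0,
                                    n_controls = 30L, n_patients = 30L, ...) {
  center <- c(7L, 7L, 7L)
  phantom_spec(
    n_controls = n_controls, n_patients = n_patients,
    age_shift_patients = age_shift_patients, match_patient_ages = TRUE,
    beta_age = -0.005, noise_sd = 0.06,
    beta_region = region_spec("sphere", center = center, radius = 6),
    atrophy_delta = -0.05,
    atrophy_region = region_spec("sphere", center = center, radius = 3),
    seed = seed, ...)
}

#' The age-shifted mass-univariate scenario
#'
#' Phantom for the three VBM regimes: a patient group shifted in age
#' against a larger control pool (young patients vs older controls, or the
#' reverse).  The disease offset of -0.03 grey-matter units equals exactly
#' one decade of the modeled ageing decline (-0.003 per year), so with
#' patients 10 years younger the two effects cancel in the group mean —
#' the planted atrophy is invisible without age correction.  With patients
#' 10 years older, ageing masquerades as disease throughout the slope
#' region.  Group sizes default to 79 controls vs 25 patients, mirroring a
#' patient subgroup against a full control pool.
#'
#' @param age_shift_patients Years added to patient ages; -10 = young
#'   patients (default), +10 = old patients.
#' @param seed Integer seed.
#' @param n_controls,n_patients Group sizes.
#' @param ... Further overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
vbm_scenario_spec <- function(age_shift_patients = -10, seed = 1L,
                              n_controls = 79L, n_patients = 25L, ...) {
  center <- c(7L, 7L, 7L)
  phantom_spec(
    n_controls = n_controls, n_patients = n_patients,
    age_shift_patients = age_shift_patients,
    beta_age = -0.003, noise_sd = 0.02,
    beta_region = region_spec("sphere", center = center, radius = 6),
    atrophy_delta = -0.03,
    atrophy_region = region_spec("sphere", center = center, radius = 3),
    seed = seed, ...)
}

#' Generate a phantom cohort
#'
#' @param spec A [phantom_spec()].
#' @return List: `stack` (`volume_stack`, controls first then patients),
#'   `cohort` (data.frame subject_id, group, age, sex), and `truth` (list
#'   with `baseline_field`, `beta_field`, `atrophy_mask`, `delta`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  nv <- prod(grid)
  n <- spec$n_controls + spec$n_patients
  is_patient <- rep(c(0, 1), c(spec$n_controls, spec$n_patients))

  with_seed(spec$seed, {
    baseline_field <- spec$baseline +
      smooth_volume(array(stats::rnorm(nv, 0, spec$baseline_roughness), grid),
                    spec$baseline_fwhm, spec$voxel_size_mm)
    beta_field <- if (is.null(spec$beta_region)) {
      array(spec$beta_age, dim = grid)
    } else {
      ind <- region_mask(spec$beta_region, grid) * 1
      if (spec$beta_smooth_fwhm > 0)
        ind <- smooth_volume(ind, spec$beta_smooth_fwhm, spec$voxel_size_mm)
      spec$beta_age * ind
    }
    atrophy_mask <- if (is.null(spec$atrophy_region)) {
      array(FALSE, dim = grid)
    } else region_mask(spec$atrophy_region, grid)

    control_ages <- stats::runif(spec$n_controls, spec$age_range[1],
                                 spec$age_range[2])
    patient_ages <- if (isTRUE(spec$match_patient_ages)) {
      sample(control_ages, spec$n_patients)
    } else {
      stats::runif(spec$n_patients, spec$age_range[1], spec$age_range[2])
    }
    ages <- c(control_ages, patient_ages + spec$age_shift_patients)
    sex <- stats::rbinom(n, 1L, 0.5)

    Y <- as.vector(baseline_field) +
      outer(as.vector(beta_field), ages) +
      spec$atrophy_delta * as.vector(atrophy_mask) %o% is_patient +
      matrix(stats::rnorm(nv * n, 0, spec$noise_sd), nv, n)

    stack <- volume_stack(array(Y, dim = c(grid, n)),
                          subject_ids = sprintf("sub%03d", seq_len(n)))
    cohort <- data.frame(
      subject_id = stack$subject_ids,
      group = rep(c("control", "patient"),
                  c(spec$n_controls, spec$n_patients)),
      age = ages, sex = sex, stringsAsFactors = FALSE)
    list(stack = stack, cohort = cohort,
         truth = list(baseline_field = baseline_field,
                      beta_field = beta_field,
                      atrophy_mask = atrophy_mask,
                      delta = spec$atrophy_delta, spec = spec))
  })
}

#' Generate a pair of tissue-probability templates
#'
#' Smooth probability maps in [0, 1] whose outermost rim lies below 0.2 in
#' template A, so the default 0.2 mask threshold excludes the grid boundary.
#' With `sphere` given, both templates are instead 0.9 inside the sphere and
#' 0.05 outside, so the mask size has a closed-form voxel count.
#'
#' @param grid Grid shape, default `c(16, 16, 16)`.
#' @param seed Integer seed.
#' @param rim Rim width in voxels, default 1.
#' @param sphere Optional [region_spec()] sphere for analytic masks.
#' @return List of two 3-D arrays `a` and `b`.
#' @export
generate_templates <- function(grid = c(16L, 16L, 16L), seed = 1L, rim = 1L,
                               sphere = NULL) {
  grid <- as.integer(grid)
  if (!is.null(sphere)) {
    ind <- region_mask(sphere, grid)
    a <- array(0.05, dim = grid); a[ind] <- 0.9
    return(list(a = a, b = a))
  }
  with_seed(seed, {
    mk <- function() {
      f <- smooth_volume(array(stats::rnorm(prod(grid), 0, 1), grid), 6)
      pmin(pmax(0.6 + 2 * f, 0.3), 1)
    }
    a <- mk(); b <- mk()
  })
  rim_mask <- array(TRUE, dim = grid)
  keep <- lapply(grid, function(L) seq(rim + 1L, L - rim))
  rim_mask[keep[[1]], keep[[2]], keep[[3]]] <- FALSE
  a[rim_mask] <- 0.05
  list(a = a, b = b)
}
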