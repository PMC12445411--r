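#  Cohort simulator: generates per-subject layer/slice/territory MBF values
#  and hemodynamics with the statistical structure reported for healthy
#  adults — higher absolute MBF in women, an age-related decline of stress
#  (but not rest) MBF, a rest endo-to-epi gradient above 1 with a stress
#  gradient near or below 1, and systolically depressed mid-slice values.
#
#  Generative form: truncated-normal base MBF per state and sex with an
#  additive age effect on the stress mean, multiplicative slice and territory
#  factors (normalized to segment-count-weighted mean 1 so global means equal
#  the specified values), and the wall split into layers by the endo/epi
#  ratio g: endo = wall * 2g/(1+g), epi = wall * 2/(1+g).

slice_weights <- c(basal = 6, mid = 6, apical = 4) / 16
territory_weights <- c(lad = 6, lcx = 5, rca = 5) / 16

#' Cohort simulation parameters
#'
#' Defaults are anchored to the printed summary tables of a two-centre
#' healthy cohort (n = 138, 54 female / 84 male, ages 19-79): global rest MBF
#' 0.68 (F) / 0.56 (M) and stress MBF 2.41 / 2.12 mL/min/g, per-slice rest
#' gradients 1.08/1.09/1.16 and stress gradients 0.98/0.92/1.03
#' (basal/mid/apical), and a stress-only age slope of -0.014 mL/min/g per
#' year that reproduces the reported stress-MBF/age rank correlation of about
#' -0.47 under a uniform age distribution.
#'
#' @param n_subjects cohort size (>= 2).
#' @param sex_ratio fraction of female subjects (deterministic count,
#'   `round(n * sex_ratio)`).
#' @param age_range years, uniform sampling range.
#' @param mbf_mean,mbf_sd per-state, per-sex global wall MBF mean and
#'   *residual* SD (mL/min/g); the printed cohort SDs additionally contain
#'   the age-slope contribution.
#' @param age_slope_stress,age_slope_rest additive MBF change per year of
#'   age, applied to the state mean (centred at the midpoint of `age_range`).
#' @param layer_ratio_rest,layer_ratio_stress endo/epi ratio per slice
#'   (length 3, `basal, mid, apical`; scalars are recycled).
#' @param slice_effects list with `rest` and `stress` length-3 multiplicative
#'   slice factors (normalized internally to weighted mean 1).
#' @param territory_effects list with `rest` and `stress` length-3 factors
#'   for `lad, lcx, rca` (normalized likewise).
#' @param slice_noise_sd,territory_noise_sd relative (multiplicative)
#'   Gaussian noise SD on slice and territory wall MBF.
#' @param ratio_noise_subject,ratio_noise_slice per-state SD (named
#'   `rest`/`stress`) of the subject-level and slice-level additive noise on
#'   the endo/epi ratio.
#' @param hemodynamics list of per-sex means and SDs for heart rate (bpm) and
#'   systolic blood pressure (mmHg) at rest and stress.
#' @param seed default RNG seed for [make_cohort()].
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 138,
                        sex_ratio = 54 / 138,
                        age_range = c(19, 79),
                        mbf_mean = list(rest = c(female = 0.68, male = 0.56),
                                        stress = c(female = 2.41, male = 2.12)),
                        mbf_sd = list(rest = c(female = 0.13, male = 0.17),
                                      stress = c(female = 0.40, male = 0.47)),
                        age_slope_stress = -0.014,
                        age_slope_rest = 0,
                        layer_ratio_rest = c(basal = 1.08, mid = 1.09, apical = 1.16),
                        layer_ratio_stress = c(basal = 0.98, mid = 0.92, apical = 1.03),
                        slice_effects = list(rest = c(basal = 1.00, mid = 1.00, apical = 0.92),
                                             stress = c(basal = 1.04, mid = 0.95, apical = 0.93)),
                        territory_effects = list(rest = c(lad = 1.07, lcx = 0.97, rca = 0.93),
                                                 stress = c(lad = 1.05, lcx = 1.00, rca = 0.94)),
                        slice_noise_sd = 0.05,
                        territory_noise_sd = 0.05,
                        ratio_noise_subject = c(rest = 0.06, stress = 0.08),
                        ratio_noise_slice = c(rest = 0.04, stress = 0.06),
                        hemodynamics = list(
                          hr_rest = c(female = 65, male = 63), hr_rest_sd = 9,
                          sbp_rest = c(female = 112, male = 120), sbp_rest_sd = 15,
                          hr_stress = c(female = 95, male = 86), hr_stress_sd = 14,
                          sbp_stress = c(female = 116, male = 125), sbp_stress_sd = 15),
                        seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop_tp("n_subjects must be >= 2: cohort statistics are undefined otherwise")
  }
  if (sex_ratio < 0 || sex_ratio > 1) stop_tp("sex_ratio must be in [0, 1]")
  if (length(age_range) != 2 || diff(age_range) < 0 || any(age_range <= 0)) {
    stop_tp("age_range must be increasing and positive")
  }
  for (st in c("rest", "stress")) {
    if (any(mbf_sd[[st]] < 0)) stop_tp("mbf_sd must be >= 0")
    if (any(mbf_mean[[st]] <= 0)) stop_tp("mbf_mean must be > 0")
    if (any(slice_effects[[st]] <= 0) || any(territory_effects[[st]] <= 0)) {
      stop_tp("slice and territory factors must be > 0")
    }
  }
  if (any(c(slice_noise_sd, territory_noise_sd,
            ratio_noise_subject, ratio_noise_slice) < 0)) {
    stop_tp("noise SDs must be >= 0")
  }
  ratio <- list(rest = rep_len(as.numeric(layer_ratio_rest), 3L),
                stress = rep_len(as.numeric(layer_ratio_stress), 3L))
  if (any(unlist(ratio) <= 0)) stop_tp("layer ratios must be > 0")
  structure(list(n_subjects = as.integer(n_subjects), sex_ratio = sex_ratio,
                 age_range = as.numeric(age_range),
                 mbf_mean = mbf_mean, mbf_sd = mbf_sd,
                 age_slope_stress = age_slope_stress,
                 age_slope_rest = age_slope_rest,
                 layer_ratio = ratio,
                 slice_effects = lapply(slice_effects, function(e)
                   stats::setNames(rep_len(as.numeric(e), 3L), names(slice_weights))),
                 territory_effects = lapply(territory_effects, function(e)
                   stats::setNames(rep_len(as.numeric(e), 3L), names(territory_weights))),
                 slice_noise_sd = slice_noise_sd,
                 territory_noise_sd = territory_noise_sd,
                 ratio_noise_subject = ratio_noise_subject,
                 ratio_noise_slice = ratio_noise_slice,
                 hemodynamics = hemodynamics, seed = seed),
            class = "cohort_spec")
}

#' Simulate a cohort of subject records
#'
#' Draws one wide row per subject: demographics, hemodynamics and wall, endo
#' and epi MBF for the global LV, the three slices and the three coronary
#' territories, at rest and stress. Columns are named
#' `{rmbf|smbf}_{wall|endo|epi}_{global|basal|mid|apical|lad|lcx|rca}`.
#' Reproducible bit-for-bit for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return a tibble of `n_subjects` rows with `qc_excluded = FALSE`.
#' @export
make_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_seed(seed, {
    n_f <- round(n * spec$sex_ratio)
    sex <- factor(rep(c("female", "male"), c(n_f, n - n_f)),
                  levels = c("female", "male"))
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    age_c <- age - mean(spec$age_range)
    hd <- spec$hemodynamics
    hemo <- function(mean_by_sex, sdv) {
      rnorm_trunc(n, unname(mean_by_sex[as.character(sex)]), sdv, lower = 1)
    }
    hr_rest <- hemo(hd$hr_rest, hd$hr_rest_sd)
    sbp_rest <- hemo(hd$sbp_rest, hd$sbp_rest_sd)
    hr_stress <- hemo(hd$hr_stress, hd$hr_stress_sd)
    sbp_stress <- hemo(hd$sbp_stress, hd$sbp_stress_sd)

    out <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      sex = sex, age = age,
      hr_rest = hr_rest, sbp_rest = sbp_rest,
      hr_stress = hr_stress, sbp_stress = sbp_stress,
      qc_excluded = FALSE)

    for (state in c("rest", "stress")) {
      pre <- if (state == "rest") "rmbf" else "smbf"
      slope <- if (state == "rest") spec$age_slope_rest else spec$age_slope_stress
      mu <- unname(spec$mbf_mean[[state]][as.character(sex)]) + slope * age_c
      sdv <- unname(spec$mbf_sd[[state]][as.character(sex)])
      base <- rnorm_trunc(n, mu, sdv, lower = 0.01)
      eff <- spec$slice_effects[[state]]
      eff <- eff / sum(slice_weights * eff)
      g_subj <- stats::rnorm(n, 0, spec$ratio_noise_subject[[state]])
      wall_s <- endo_s <- epi_s <- matrix(0, n, 3,
                                          dimnames = list(NULL, names(slice_weights)))
      for (sl in names(slice_weights)) {
        w <- base * eff[[sl]] *
          (1 + stats::rnorm(n, 0, spec$slice_noise_sd))
        w <- pmax(w, 0.01)
        g <- spec$layer_ratio[[state]][[match(sl, names(slice_weights))]] +
          g_subj + stats::rnorm(n, 0, spec$ratio_noise_slice[[state]])
        g <- pmax(g, 0.05)
        wall_s[, sl] <- w
        endo_s[, sl] <- w * 2 * g / (1 + g)
        epi_s[, sl] <- w * 2 / (1 + g)
        out[[paste(pre, "wall", sl, sep = "_")]] <- wall_s[, sl]
        out[[paste(pre, "endo", sl, sep = "_")]] <- endo_s[, sl]
        out[[paste(pre, "epi", sl, sep = "_")]] <- epi_s[, sl]
      }
      wall_g <- drop(wall_s %*% slice_weights)
      endo_g <- drop(endo_s %*% slice_weights)
      epi_g <- drop(epi_s %*% slice_weights)
      out[[paste(pre, "wall", "global", sep = "_")]] <- wall_g
      out[[paste(pre, "endo", "global", sep = "_")]] <- endo_g
      out[[paste(pre, "epi", "global", sep = "_")]] <- epi_g
      g_glob <- endo_g / epi_g
      teff <- spec$territory_effects[[state]]
      teff <- teff / sum(territory_weights * teff)
      for (tr in names(territory_weights)) {
        w <- wall_g * teff[[tr]] * (1 + stats::rnorm(n, 0, spec$territory_noise_sd))
        w <- pmax(w, 0.01)
        out[[paste(pre, "wall", tr, sep = "_")]] <- w
        out[[paste(pre, "endo", tr, sep = "_")]] <- w * 2 * g_glob / (1 + g_glob)
        out[[paste(pre, "epi", tr, sep = "_")]] <- w * 2 / (1 + g_glob)
      }
    }
    out
  })
}

#' Pivot a cohort table to long format
#'
#' One row per subject x state x layer x region, suitable for CSV export.
#'
#' @param cohort a [make_cohort()] or [cohort_metrics()] tibble.
#' @return long tibble with columns `subject_id, sex, age, state, layer,
#'   region, mbf`.
#' @export
cohort_long <- function(cohort) {
  mbf_cols <- grep("^(rmbf|smbf)_(wall|endo|epi)_", names(cohort), value = TRUE)
  long <- tidyr::pivot_longer(
    cohort[c("subject_id", "sex", "age", mbf_cols)],
    cols = tidyr::all_of(mbf_cols),
    names_to = c("state", "layer", "region"), names_sep = "_",
    values_to = "mbf")
  long$state <- ifelse(long$state == "rmbf", "rest", "stress")
  long
}
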