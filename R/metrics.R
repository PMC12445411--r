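#  Scalar perfusion metrics: regional pixel means, myocardial perfusion
#  reserve (MPR), endo-to-epi transmural gradients, rate-pressure product
#  and its corrections, and the per-subject pipeline composing geometry,
#  parcellation and metrics.

#' Mean MBF over a pixel mask
#'
#' Arithmetic mean of map values over the masked pixels. Background (`NA`)
#' pixels inside the mask are dropped; an all-`NA` or empty mask signals a
#' parcellation failure and is an error.
#'
#' @param map a [perfusion_map()].
#' @param mask logical matrix of the same dimensions.
#' @return mean MBF (mL/min/g).
#' @export
region_mean_mbf <- function(map, mask) {
  stopifnot(inherits(map, "perfusion_map"))
  if (!is.logical(mask) || !identical(dim(mask), dim(map$values))) {
    stop_tp("mask must be a logical matrix matching the map grid")
  }
  if (!any(mask)) stop_tp("empty region mask (parcellation failure?)")
  v <- map$values[mask]
  if (all(is.na(v))) stop_tp("region mask covers only background pixels")
  mean(v, na.rm = TRUE)
}

#' Myocardial perfusion reserve
#'
#' `MPR = sMBF / rMBF`; applied per layer it gives `MPR_ENDO` and `MPR_EPI`.
#' A non-positive rest MBF is an error; denominators below 1e-9 mL/min/g
#' yield `NA` (missing, never infinity).
#'
#' @param smbf stress MBF (mL/min/g).
#' @param rmbf rest MBF (mL/min/g).
#' @return dimensionless reserve, vectorised.
#' @export
mpr <- function(smbf, rmbf) guarded_ratio(smbf, rmbf, "MPR (rest MBF must be > 0)")

#' Transmural endo-to-epi gradient
#'
#' `GRAD = MBF_ENDO / MBF_EPI`, the same formula at stress (sGRAD) and rest
#' (rGRAD). Values above 1 mean the endocardium is better perfused than the
#' epicardium.
#'
#' @param endo_mbf,epi_mbf layer mean MBF (mL/min/g).
#' @return dimensionless ratio, vectorised.
#' @export
transmural_gradient <- function(endo_mbf, epi_mbf) {
  guarded_ratio(endo_mbf, epi_mbf, "gradient (epicardial MBF must be > 0)")
}

#' Rate-pressure product
#'
#' `RPP = HR x systolic BP`, a workload surrogate (mmHg * bpm).
#'
#' @param hr heart rate (bpm), > 0.
#' @param sbp systolic blood pressure (mmHg), > 0.
#' @return RPP in mmHg * bpm, vectorised.
#' @export
rate_pressure_product <- function(hr, sbp) {
  if (any(hr <= 0, na.rm = TRUE) || any(sbp <= 0, na.rm = TRUE)) {
    stop_tp("heart rate and systolic blood pressure must be > 0")
  }
  hr * sbp
}

#' RPP-corrected rest MBF
#'
#' Rest MBF normalized by the individual workload: `rMBF_c = rMBF / (RPP /
#' 10000)`. At the reference workload RPP = 10000 the value is unchanged.
#'
#' @param rmbf rest MBF (mL/min/g).
#' @param rpp rate-pressure product (mmHg * bpm), > 0.
#' @return corrected rest MBF (mL/min/g), vectorised.
#' @export
rpp_corrected_rmbf <- function(rmbf, rpp) {
  guarded_ratio(rmbf * 10000, rpp, "RPP correction (RPP must be > 0)")
}

#' RPP-corrected MPR
#'
#' `MPR_c = sMBF / rMBF_c`, which satisfies `MPR_c = MPR x RPP / 10000`
#' identically.
#'
#' @param smbf stress MBF (mL/min/g).
#' @param rmbf_c RPP-corrected rest MBF, > 0.
#' @return dimensionless, vectorised.
#' @export
rpp_corrected_mpr <- function(smbf, rmbf_c) {
  guarded_ratio(smbf, rmbf_c, "corrected MPR (corrected rest MBF must be > 0)")
}

#' Slice-specific metric from segment values
#'
#' The unweighted mean of a per-segment metric over the segments belonging
#' to one slice (6 basal, 6 mid or 4 apical values).
#'
#' @param segment_values numeric vector named by segment ID (`"1"`..`"16"`).
#' @param slice `"basal"`, `"mid"` or `"apical"`.
#' @return scalar metric.
#' @export
slice_metric <- function(segment_values, slice) {
  ids <- slice_segments(slice)
  key <- as.character(ids)
  missing_ids <- setdiff(key, names(segment_values))
  if (length(missing_ids) > 0) {
    stop_tp("missing segment value(s) for slice %s: %s", slice,
            paste(missing_ids, collapse = ", "))
  }
  mean(as.numeric(segment_values[key]))
}

regions_all <- c("global", "basal", "mid", "apical", "lad", "lcx", "rca")

#' Derive all ratio metrics for a cohort table
#'
#' Adds, per subject row: RPP at rest and stress, RPP-corrected rest MBF and
#' MPR (global LV level), and for every region (global, slices, territories)
#' the whole-wall and layer MPRs and the stress/rest transmural gradients.
#' Missing MBF columns are skipped silently so the function works on partial
#' tables.
#'
#' @param cohort a wide tibble as produced by [make_cohort()] or by binding
#'   [subject_pipeline()] rows.
#' @return the input with derived metric columns appended.
#' @export
cohort_metrics <- function(cohort) {
  df <- cohort
  if (all(c("hr_rest", "sbp_rest") %in% names(df))) {
    df$rpp_rest <- rate_pressure_product(df$hr_rest, df$sbp_rest)
    df$rpp_stress <- rate_pressure_product(df$hr_stress, df$sbp_stress)
    if ("rmbf_wall_global" %in% names(df)) {
      df$rmbf_c <- rpp_corrected_rmbf(df$rmbf_wall_global, df$rpp_rest)
      df$mpr_c <- rpp_corrected_mpr(df$smbf_wall_global, df$rmbf_c)
    }
  }
  for (rg in regions_all) {
    suffix <- if (rg == "global") "" else paste0("_", rg)
    wall_r <- paste0("rmbf_wall_", rg); wall_s <- paste0("smbf_wall_", rg)
    if (all(c(wall_r, wall_s) %in% names(df))) {
      df[[paste0("mpr", if (rg == "global") "_global" else suffix)]] <-
        safe_ratio(df[[wall_s]], df[[wall_r]])
    }
    for (ly in c("endo", "epi")) {
      r <- paste0("rmbf_", ly, "_", rg); s <- paste0("smbf_", ly, "_", rg)
      if (all(c(r, s) %in% names(df))) {
        df[[paste0("mpr_", ly, "_", rg)]] <- safe_ratio(df[[s]], df[[r]])
      }
    }
    se <- paste0("smbf_endo_", rg); sp <- paste0("smbf_epi_", rg)
    re <- paste0("rmbf_endo_", rg); rp <- paste0("rmbf_epi_", rg)
    if (all(c(se, sp) %in% names(df))) {
      df[[paste0("sgrad_", rg)]] <- safe_ratio(df[[se]], df[[sp]])
    }
    if (all(c(re, rp) %in% names(df))) {
      df[[paste0("rgrad_", rg)]] <- safe_ratio(df[[re]], df[[rp]])
    }
  }
  df
}

#' Full per-subject analysis pipeline
#'
#' Runs the geometric decomposition, AHA parcellation and all metric
#' computations for one subject: three short-axis slices at stress and rest.
#' Maps are resampled to `target_spacing`, layers are split by the
#' midventricular line, segments are anchored at the RV insertion, and MBF
#' means are computed per segment, per slice, per coronary territory and
#' globally — over pixels for territories/global (pooled across slices) and
#' as segment-mean averages for slice-specific values.
#'
#' @param maps nested list `maps$stress$basal`, ... : six [perfusion_map()]s.
#' @param contours list `contours$basal`, `contours$mid`, `contours$apical`
#'   of [contour_set()]s (shared between states; stress and rest maps of a
#'   slice must be on the same grid).
#' @param hemodynamics list with `hr_rest`, `sbp_rest`, `hr_stress`,
#'   `sbp_stress`.
#' @param demographics list with `subject_id`, `sex` (`"female"`/`"male"`),
#'   `age`.
#' @param target_spacing interpolation target in mm (default 1).
#' @param n_rays rays for the midline (default 360).
#' @return object of class `subject_record`: `$metrics` (one wide tibble row
#'   compatible with [cohort_metrics()]), `$segments` (per-segment layer
#'   means by state) and `$derived` (named list of the headline scalars).
#' @export
subject_pipeline <- function(maps, contours, hemodynamics, demographics,
                             target_spacing = 1.0, n_rays = 360) {
  slices <- c("basal", "mid", "apical")
  states <- c("stress", "rest")
  for (st in states) {
    if (!all(slices %in% names(maps[[st]] %||% list()))) {
      stop_tp("maps$%s must contain basal, mid and apical slices", st)
    }
  }
  if (!all(slices %in% names(contours))) {
    stop_tp("contours must contain basal, mid and apical contour sets")
  }

  seg_rows <- list()
  pooled <- list()   # pooled pixel values: pooled[[state]][[layer or territory]]
  for (state in states) pooled[[state]] <- list()

  for (sl in slices) {
    cs <- contours[[sl]]
    ref_map <- tryCatch(interpolate_map(maps[[states[1]]][[sl]], target_spacing),
                        error = function(e) {
                          stop_tp("slice %s (%s): %s", sl, states[1], conditionMessage(e))
                        })
    midline <- compute_midline(cs, n_rays = n_rays)
    masks <- assign_layers(ref_map, cs, midline)
    segs <- build_segments(masks, cs, sl)
    for (state in states) {
      m <- interpolate_map(maps[[state]][[sl]], target_spacing)
      if (!identical(dim(m$values), dim(ref_map$values))) {
        stop_tp("slice %s: stress and rest maps are on different grids", sl)
      }
      for (id in slice_segments(sl)) {
        smask <- segment_mask(segs, id)
        seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
          state = state, slice = sl, segment = id,
          territory = territory_of(id),
          wall = region_mean_mbf(m, smask),
          endo = region_mean_mbf(m, smask & masks$endo_layer),
          epi = region_mean_mbf(m, smask & masks$epi_layer))
      }
      add_pool <- function(key, mask) {
        pooled[[state]][[key]] <<- c(pooled[[state]][[key]],
                                     m$values[mask & !is.na(m$values)])
      }
      add_pool("wall_global", masks$myocardium)
      add_pool("endo_global", masks$endo_layer)
      add_pool("epi_global", masks$epi_layer)
      for (tr in c("LAD", "LCX", "RCA")) {
        ids <- as.integer(names(which(territory_of_segments() == tr)))
        tmask <- segment_mask(segs, ids)
        add_pool(paste0("wall_", tolower(tr)), tmask)
        add_pool(paste0("endo_", tolower(tr)), tmask & masks$endo_layer)
        add_pool(paste0("epi_", tolower(tr)), tmask & masks$epi_layer)
      }
    }
  }
  segments <- dplyr::bind_rows(seg_rows)

  row <- tibble::tibble(
    subject_id = demographics$subject_id %||% "subject",
    sex = factor(demographics$sex %||% NA_character_,
                 levels = c("female", "male")),
    age = as.numeric(demographics$age %||% NA_real_),
    hr_rest = hemodynamics$hr_rest, sbp_rest = hemodynamics$sbp_rest,
    hr_stress = hemodynamics$hr_stress, sbp_stress = hemodynamics$sbp_stress,
    qc_excluded = FALSE)

  for (state in states) {
    pre <- if (state == "rest") "rmbf" else "smbf"
    for (key in names(pooled[[state]])) {
      row[[paste(pre, key, sep = "_")]] <- mean(pooled[[state]][[key]])
    }
    # slice-specific values: unweighted mean over the slice's segment means
    seg_st <- segments[segments$state == state, ]
    for (sl in slices) {
      for (ly in c("wall", "endo", "epi")) {
        vals <- stats::setNames(seg_st[[ly]][seg_st$slice == sl],
                                as.character(seg_st$segment[seg_st$slice == sl]))
        row[[paste(pre, ly, sl, sep = "_")]] <- slice_metric(vals, sl)
      }
    }
  }
  metrics <- cohort_metrics(row)

  # slice-specific ratio metrics from per-segment ratios (mean of the
  # segment-level gradients/MPRs over the slice's segments)
  seg_w <- tidyr::pivot_wider(segments, names_from = state,
                              values_from = c("wall", "endo", "epi"))
  seg_w$sgrad <- transmural_gradient(seg_w$endo_stress, seg_w$epi_stress)
  seg_w$rgrad <- transmural_gradient(seg_w$endo_rest, seg_w$epi_rest)
  seg_w$mpr_endo <- mpr(seg_w$endo_stress, seg_w$endo_rest)
  seg_w$mpr_epi <- mpr(seg_w$epi_stress, seg_w$epi_rest)
  for (sl in slices) {
    for (mt in c("sgrad", "rgrad", "mpr_endo", "mpr_epi")) {
      vals <- stats::setNames(seg_w[[mt]][seg_w$slice == sl],
                              as.character(seg_w$segment[seg_w$slice == sl]))
      metrics[[paste(mt, sl, "seg", sep = "_")]] <- slice_metric(vals, sl)
    }
  }

  derived <- list(
    mpr = metrics$mpr_global, mpr_endo = metrics$mpr_endo_global,
    mpr_epi = metrics$mpr_epi_global,
    sgrad = metrics$sgrad_global, rgrad = metrics$rgrad_global,
    rpp_rest = metrics$rpp_rest, rpp_stress = metrics$rpp_stress,
    rmbf_c = metrics$rmbf_c, mpr_c = metrics$mpr_c)
  structure(list(metrics = metrics, segments = segments, derived = derived),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  d <- x$derived
  cat(sprintf(paste0("<subject_record> %s: MPR %.2f (ENDO %.2f / EPI %.2f), ",
                     "sGRAD %.3f, rGRAD %.3f\n"),
              x$metrics$subject_id, d$mpr, d$mpr_endo, d$mpr_epi,
              d$sgrad, d$rgrad))
  invisible(x)
}
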