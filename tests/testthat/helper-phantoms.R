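# Shared fixtures: all built in code at test time.

# concentric-circle phantom covering a (2*epi + margin) mm square grid
circle_phantom <- function(spacing = 0.5, r_endo = 20, r_epi = 30,
                           endo_value = 1.1, epi_value = 1.0,
                           profile = "step", noise_sd = 0, seed = NULL,
                           margin = 8) {
  n <- ceiling((2 * r_epi + margin) / spacing)
  make_phantom(phantom_spec(grid_shape = c(n, n), pixel_spacing = spacing,
                            endo_radius = r_endo, epi_radius = r_epi,
                            endo_value = endo_value, epi_value = epi_value,
                            profile = profile, noise_sd = noise_sd,
                            seed = seed))
}

# six maps + contours for one synthetic subject built from phantom specs:
# fn(state) must return a phantom spec shared by the three slices
phantom_subject <- function(stress_spec, rest_spec,
                            hemodynamics = list(hr_rest = 60, sbp_rest = 120,
                                                hr_stress = 90, sbp_stress = 120),
                            demographics = list(subject_id = "T01",
                                                sex = "female", age = 40)) {
  slices <- c("basal", "mid", "apical")
  maps <- list(stress = list(), rest = list())
  contours <- list()
  for (sl in slices) {
    phs <- make_phantom(stress_spec, slice = sl, state = "stress")
    phr <- make_phantom(rest_spec, slice = sl, state = "rest")
    maps$stress[[sl]] <- phs$map
    maps$rest[[sl]] <- phr$map
    contours[[sl]] <- phs$contours
  }
  list(maps = maps, contours = contours, hemodynamics = hemodynamics,
       demographics = demographics)
}

# distance of midline vertices from a point
midline_radii <- function(midline, center = attr(midline, "center")) {
  sqrt(rowSums(sweep(unclass(midline), 2, center)^2))
}
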