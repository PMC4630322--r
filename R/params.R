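#' Load the model parameter file
#'
#' All printed model constants ship as a versioned flat JSON file
#' (\code{inst/extdata/params.json}). Values can be overridden from a user
#' file or an override list; unknown keys are rejected.
#'
#' @param path Optional JSON file of overrides (flat key-value).
#' @param overrides Optional named list of overrides applied last.
#' @return Named list of model constants (class \code{"ava_params"}).
#' @export
load_params <- function(path = NULL, overrides = list()) {
  base <- jsonlite::read_json(system.file("extdata", "params.json",
                                          package = "avasim"),
                              simplifyVector = TRUE)
  apply_over <- function(p, ov, src) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter keys in ", src, ": ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
    p
  }
  if (!is.null(path))
    base <- apply_over(base, jsonlite::read_json(path, simplifyVector = TRUE),
                       path)
  if (length(overrides))
    base <- apply_over(base, overrides, "overrides")
  structure(base, class = "ava_params")
}

#' Build module parameter objects from a flat parameter list
#'
#' Expands a \code{\link{load_params}} list into the typed parameter objects
#' the modules consume.
#'
#' @param p An \code{"ava_params"} list.
#' @return List with \code{physiology}, \code{boundary}, \code{diffusion},
#'   \code{rates}, \code{stoichiometry}, \code{health}, \code{mitosis},
#'   \code{springs}, \code{chemotaxis} entries.
#' @export
expand_params <- function(p = load_params()) {
  list(
    physiology = physiological_constants(
      hgb_molecular_weight = p$hgb_molecular_weight,
      hgb_blood_concentration_range = c(p$hgb_blood_concentration_low,
                                        p$hgb_blood_concentration_high),
      large_vessel_hgb_molar = p$large_vessel_hgb_molar,
      tissue_hematocrit_ratio = p$tissue_hematocrit_ratio,
      oxyphoric_power = p$oxyphoric_power,
      blood_saturation = p$blood_saturation,
      hill_coefficient = p$hill_coefficient,
      p50 = p$p50_mmHg,
      solubility_alpha = p$solubility_alpha,
      hill_hgb = p$hill_hgb),
    boundary = boundary_conditions(oxygen = p$oxygen_boundary,
                                   glucose = p$glucose_boundary),
    diffusion = c(oxygen = p$diffusion_oxygen, glucose = p$diffusion_glucose,
                  waste = p$diffusion_waste,
                  growth_factor = p$diffusion_growth_factor,
                  growth_inhibitor = p$diffusion_growth_inhibitor),
    rates = metabolic_rate_table(rbind(
      proliferating = c(p$rate_proliferating_oxygen, p$rate_proliferating_glucose,
                        p$rate_proliferating_waste, p$rate_proliferating_growth_factor,
                        p$rate_proliferating_growth_inhibitor),
      quiescent = c(p$rate_quiescent_oxygen, p$rate_quiescent_glucose,
                    p$rate_quiescent_waste, p$rate_quiescent_growth_factor,
                    p$rate_quiescent_growth_inhibitor),
      necrotic = c(0, 0, 0, 0, p$rate_necrotic_growth_inhibitor))),
    stoichiometry = atp_stoichiometry(p$oxygen_per_glucose_aerobic,
                                      p$atp_per_glucose_aerobic,
                                      p$atp_per_glucose_anaerobic,
                                      p$atp_per_waste),
    health = health_params(p$h_p, p$h_q, p$health_decay,
                           p$necrosis_threshold, p$proliferation_threshold),
    mitosis = mitosis_params(p$r_mitosis, p$sigma_mitosis, p$hayflick_limit,
                             p$mutation_increment_prob),
    springs = spring_constants(p$k_pp, p$k_pq, p$k_qq, p$spring_cutoff),
    chemotaxis = chemotaxis_weights(p$chemo_alpha, p$chemo_beta, p$chemo_gamma)
  )
}
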