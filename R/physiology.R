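#' Physiological constants for boundary-value derivation
#'
#' Bundle of the blood-physiology constants used to derive the oxygen
#' Dirichlet boundary value: hemoglobin molecular weight and blood
#' concentration, the tissue-to-large-vessel hematocrit ratio, the oxyphoric
#' power of tetra-hemoglobin, arteriolar blood saturation, and the Hill
#' saturation parameters (coefficient, P50, oxygen solubility).
#'
#' @param hgb_molecular_weight Hemoglobin molecular weight (g/mol).
#' @param hgb_blood_concentration_range Adult female blood hemoglobin (g/L),
#'   length-2 numeric range.
#' @param large_vessel_hgb_molar Hemoglobin molarity in large vessels (mM).
#' @param tissue_hematocrit_ratio Breast-tissue to large-vessel hematocrit
#'   ratio, in (0, 1].
#' @param oxyphoric_power Oxygen molecules carried per saturated hemoglobin.
#' @param blood_saturation Arteriolar hemoglobin saturation fraction in [0, 1].
#' @param hill_coefficient Hill cooperativity coefficient (dimensionless).
#' @param p50 Oxygen partial pressure at 50\% hemoglobin saturation (mmHg).
#' @param solubility_alpha Oxygen solubility (mmol/L/mmHg).
#' @param hill_hgb Tetra-hemoglobin concentration entering the Hill saturation
#'   term (mM). The default is the tissue blood-oxygen value the saturation
#'   relation is printed with.
#' @return An object of class \code{"ava_physiology"} (a named list).
#' @export
physiological_constants <- function(hgb_molecular_weight = 64450,
                                    hgb_blood_concentration_range = c(122, 150),
                                    large_vessel_hgb_molar = 0.002,
                                    tissue_hematocrit_ratio = 0.8,
                                    oxyphoric_power = 4,
                                    blood_saturation = 0.75,
                                    hill_coefficient = 2.73,
                                    p50 = 26,
                                    solubility_alpha = 1.39e-3,
                                    hill_hgb = 0.0048) {
  vals <- list(
    hgb_molecular_weight = hgb_molecular_weight,
    hgb_blood_concentration_range = hgb_blood_concentration_range,
    large_vessel_hgb_molar = large_vessel_hgb_molar,
    tissue_hematocrit_ratio = tissue_hematocrit_ratio,
    oxyphoric_power = oxyphoric_power,
    blood_saturation = blood_saturation,
    hill_coefficient = hill_coefficient,
    p50 = p50,
    solubility_alpha = solubility_alpha,
    hill_hgb = hill_hgb
  )
  if (!all(vapply(vals, function(v) all(is.finite(v)) && all(v > 0), logical(1))))
    stop("all physiological constants must be strictly positive and finite")
  if (tissue_hematocrit_ratio > 1)
    stop("tissue_hematocrit_ratio must lie in (0, 1]")
  if (blood_saturation > 1)
    stop("blood_saturation must lie in (0, 1]")
  structure(vals, class = "ava_physiology")
}

#' Convert a hemoglobin mass concentration to molarity
#'
#' g/L divided by the molecular weight (g/mol). The result is carried on the
#' model's concentration scale ("model-mM"), on which all the blood-oxygen
#' constants are quoted: 122 g/L gives 0.0019, consistent with the 0.002
#' large-vessel hemoglobin value. (Strictly the quotient is mol/L; the
#' model's literature labels this scale mM and all face values are kept on
#' it.)
#'
#' @param concentration_g_per_l Mass concentration (g/L); vectorised.
#' @param mw Molecular weight (g/mol).
#' @return Molar concentration (model-mM).
#' @examples
#' hgb_mass_to_molar(122, 64450)  # 0.0019 at printed precision
#' @export
hgb_mass_to_molar <- function(concentration_g_per_l, mw) {
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0)
    stop("molecular weight must be a single positive number")
  if (any(concentration_g_per_l < 0))
    stop("mass concentration must be non-negative")
  concentration_g_per_l / mw
}

#' Hemoglobin molarity in tissue-level blood
#'
#' Scales the large-vessel hemoglobin molarity by the tissue hematocrit ratio.
#'
#' @param large_vessel_hgb Large-vessel hemoglobin molarity (mM).
#' @param hematocrit_ratio Tissue-to-large-vessel hematocrit ratio in (0, 1].
#' @return Tissue hemoglobin molarity (mM).
#' @export
tissue_hgb <- function(large_vessel_hgb, hematocrit_ratio) {
  if (any(hematocrit_ratio <= 0) || any(hematocrit_ratio > 1))
    stop("hematocrit_ratio must lie in (0, 1]")
  large_vessel_hgb * hematocrit_ratio
}

#' Hemoglobin-bound oxygen concentration in tissue blood
#'
#' Product of hemoglobin molarity, oxyphoric power (O2 per hemoglobin) and
#' saturation fraction.
#'
#' @param hgb_molar Hemoglobin molarity (mM).
#' @param oxyphoric_power O2 molecules per saturated hemoglobin.
#' @param saturation Saturation fraction in [0, 1].
#' @return Blood oxygen concentration (mM).
#' @export
blood_oxygen <- function(hgb_molar, oxyphoric_power, saturation) {
  if (any(saturation < 0) || any(saturation > 1))
    stop("saturation must lie in [0, 1]")
  hgb_molar * oxyphoric_power * saturation
}

#' Hill saturation relation: blood oxygen from plasma oxygen
#'
#' Total blood oxygen as the dissolved plasma concentration plus the
#' hemoglobin-bound fraction under Hill-type cooperative binding:
#' \deqn{C_B = C_P + \frac{[HB]\, P_{O_2}}{1 + (\alpha P_{50}/C_P)^h}}
#'
#' @param c_plasma Plasma oxygen concentration (mM), strictly positive.
#' @param consts A \code{\link{physiological_constants}} object.
#' @return Blood oxygen concentration (mM).
#' @seealso \code{\link{invert_hill}}
#' @export
hill_blood_from_plasma <- function(c_plasma, consts = physiological_constants()) {
  if (any(c_plasma <= 0)) stop("plasma oxygen concentration must be strictly positive")
  sat <- 1 / (1 + (consts$solubility_alpha * consts$p50 / c_plasma)^consts$hill_coefficient)
  c_plasma + consts$hill_hgb * consts$oxyphoric_power * sat
}

#' Invert the Hill relation numerically
#'
#' Bisection solve of \code{\link{hill_blood_from_plasma}} for the plasma
#' concentration producing a target blood concentration. The forward map is
#' checked for strict monotonicity on a log-spaced grid before inverting.
#'
#' @param c_blood_target Target blood oxygen concentration (mM).
#' @param consts A \code{\link{physiological_constants}} object.
#' @param tol Absolute tolerance on the recovered blood value.
#' @param interval Search interval for the plasma concentration (mM).
#' @return Plasma oxygen concentration (mM).
#' @export
invert_hill <- function(c_blood_target, consts = physiological_constants(),
                        tol = 1e-9, interval = c(1e-12, 10)) {
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 200))
  fwd <- hill_blood_from_plasma(grid, consts)
  if (any(diff(fwd) <= 0))
    stop("forward Hill map is not strictly increasing on the search interval")
  lo <- fwd[1]; hi <- fwd[length(fwd)]
  if (c_blood_target < lo || c_blood_target > hi)
    stop(sprintf("target %.6g outside attainable blood-oxygen range [%.6g, %.6g]",
                 c_blood_target, lo, hi))
  f <- function(x) hill_blood_from_plasma(x, consts) - c_blood_target
  a <- interval[1]; b <- interval[2]
  for (i in seq_len(200)) {
    m <- (a + b) / 2
    if (abs(f(m)) < tol && (b - a) < tol * max(m, 1)) break
    if (sign(f(m)) == sign(f(a))) a <- m else b <- m
  }
  m
}

#' Round half away from zero
#'
#' Rounding convention used when comparing derived quantities against values
#' printed at fixed decimal precision (base R rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Dirichlet boundary and initial concentrations per species
#'
#' Oxygen and glucose are supplied by the host tissue at fixed extracellular
#' concentrations; waste, growth factors and growth inhibitors are assumed to
#' be cleared by circulation, so their boundary values are exactly zero.
#' Initial interior values default to the boundary values.
#'
#' @param oxygen,glucose,waste,growth_factor,growth_inhibitor Boundary
#'   concentrations (model-mM).
#' @param initial Optional named numeric vector of initial interior values;
#'   defaults to the boundary values.
#' @return An object of class \code{"ava_boundary"}: list with numeric
#'   vectors \code{boundary} and \code{initial}, named by species.
#' @export
boundary_conditions <- function(oxygen = 0.00053, glucose = 0.005,
                                waste = 0, growth_factor = 0,
                                growth_inhibitor = 0, initial = NULL) {
  b <- c(oxygen = oxygen, glucose = glucose, waste = waste,
         growth_factor = growth_factor, growth_inhibitor = growth_inhibitor)
  if (any(b < 0)) stop("boundary concentrations must be non-negative")
  if (any(b[c("waste", "growth_factor", "growth_inhibitor")] != 0))
    stop("waste, growth-factor and inhibitor boundary values must be zero (cleared by circulation)")
  if (is.null(initial)) {
    ini <- b
  } else {
    ini <- b
    if (is.null(names(initial)) || !all(names(initial) %in% names(b)))
      stop("initial overrides must be named by species")
    ini[names(initial)] <- initial
    if (any(ini < 0)) stop("initial concentrations must be non-negative")
  }
  structure(list(boundary = b, initial = ini), class = "ava_boundary")
}

#' @export
print.ava_physiology <- function(x, ...) {
  cat("Physiological constants for boundary derivation\n")
  for (nm in names(x)) cat(sprintf("  %-32s %s\n", nm, paste(format(x[[nm]]), collapse = "-")))
  invisible(x)
}

#' @export
print.ava_boundary <- function(x, ...) {
  cat("Dirichlet boundary concentrations (model-mM):\n")
  print(x$boundary)
  if (!identical(unname(x$initial), unname(x$boundary))) {
    cat("Initial interior values:\n")
    print(x$initial)
  }
  invisible(x)
}
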