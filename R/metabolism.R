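#' Species identifiers
#'
#' The five biochemical species, in their stable model ordering.
#' @return Character vector of species names.
#' @export
species_ids <- function() {
  c("oxygen", "glucose", "waste", "growth_factor", "growth_inhibitor")
}

#' Cell states
#' @return Character vector of the three cell states.
#' @export
cell_states <- function() c("proliferating", "quiescent", "necrotic")

#' Per-state metabolic demand/production rates
#'
#' Maximum consumption (oxygen, glucose) and production (waste, growth factor,
#' growth inhibitor) rates per unit cell volume for each cell state.
#' Oxygen/glucose/waste in mM/h/cm^3; growth factor and inhibitor in %/h/cm^3,
#' treated as ordinary concentration rates. The necrotic row is zero except
#' for inhibitor release (2).
#'
#' @param rates Optional 3x5 numeric matrix (rows: proliferating, quiescent,
#'   necrotic; columns: the five species) overriding the defaults.
#' @return A matrix of class \code{"ava_rates"} with state rownames and
#'   species colnames.
#' @export
metabolic_rate_table <- function(rates = NULL) {
  if (is.null(rates)) {
    rates <- rbind(
      proliferating = c(108, 162, 240, 1,   0),
      quiescent     = c(50,  80,  110, 0.5, 1),
      necrotic      = c(0,   0,   0,   0,   2)
    )
    colnames(rates) <- species_ids()
  }
  rates <- as.matrix(rates)
  if (!identical(dim(rates), c(3L, 5L)))
    stop("rate table must be 3 states x 5 species")
  rownames(rates) <- cell_states()
  colnames(rates) <- species_ids()
  if (any(rates < 0)) stop("metabolic rates must be non-negative")
  if (any(rates["necrotic", species_ids()[1:4]] != 0))
    stop("necrotic cells neither consume nutrients nor produce waste/growth factor")
  structure(rates, class = c("ava_rates", class(rates)))
}

#' ATP stoichiometry of the two-pathway glucose metabolism
#'
#' Aerobic oxidation uses 6 O2 per glucose and yields 30 ATP per glucose;
#' glucose beyond the oxygen-limited aerobic share is fermented anaerobically
#' at 2 ATP per glucose (the Warburg split). One unit of waste accompanies
#' every 3.5 units of ATP.
#'
#' @param oxygen_per_glucose_aerobic,atp_per_glucose_aerobic,
#'   atp_per_glucose_anaerobic,atp_per_waste Stoichiometric coefficients.
#' @return A named list of class \code{"ava_stoichiometry"}.
#' @export
atp_stoichiometry <- function(oxygen_per_glucose_aerobic = 6,
                              atp_per_glucose_aerobic = 30,
                              atp_per_glucose_anaerobic = 2,
                              atp_per_waste = 3.5) {
  s <- list(oxygen_per_glucose_aerobic = oxygen_per_glucose_aerobic,
            atp_per_glucose_aerobic = atp_per_glucose_aerobic,
            atp_per_glucose_anaerobic = atp_per_glucose_anaerobic,
            atp_per_waste = atp_per_waste)
  if (!all(unlist(s) > 0)) stop("stoichiometric coefficients must be positive")
  if (atp_per_glucose_aerobic <= atp_per_glucose_anaerobic)
    stop("aerobic ATP yield must exceed the anaerobic yield")
  structure(s, class = "ava_stoichiometry")
}

#' ATP yield of a cell from supplied oxygen and glucose
#'
#' Splits the supplied glucose between the aerobic pathway (limited by the
#' supplied oxygen at 6 O2 per glucose, 30 ATP per glucose) and the anaerobic
#' pathway (2 ATP per glucose). Inputs are rates per unit cell volume, already
#' capped at the state's demand. Vectorised over cells.
#'
#' @param oxygen_supplied,glucose_supplied Supplied rates (mM/h/cm^3), >= 0.
#' @param stoich An \code{\link{atp_stoichiometry}} object.
#' @param round_digits If non-NULL, the aerobic glucose share is rounded (half
#'   away from zero) to this many decimals before computing the anaerobic
#'   remainder, matching hand-worked arithmetic at printed precision; the
#'   aerobic ATP itself uses the unrounded share.
#' @return A list of class \code{"ava_atp_yield"} with numeric vectors
#'   \code{glucose_aerobic}, \code{glucose_anaerobic}, \code{e1_aerobic},
#'   \code{e2_anaerobic} and \code{total}.
#' @examples
#' atp_yield(108, 162)        # fully supplied proliferating cell: total 828
#' atp_yield(50, 80, round_digits = 1)  # quiescent worked example: total 393.4
#' @export
atp_yield <- function(oxygen_supplied, glucose_supplied,
                      stoich = atp_stoichiometry(), round_digits = NULL) {
  if (any(oxygen_supplied < 0) || any(glucose_supplied < 0))
    stop("supplied rates must be non-negative")
  oxygen_supplied <- unname(oxygen_supplied)
  glucose_supplied <- unname(glucose_supplied)
  ga <- pmin(glucose_supplied, oxygen_supplied / stoich$oxygen_per_glucose_aerobic)
  e1 <- stoich$atp_per_glucose_aerobic * ga
  ga_split <- if (is.null(round_digits)) ga else round_half_up(ga, round_digits)
  gan <- pmax(glucose_supplied - ga_split, 0)
  e2 <- stoich$atp_per_glucose_anaerobic * gan
  structure(list(glucose_aerobic = ga, glucose_anaerobic = gan,
                 e1_aerobic = e1, e2_anaerobic = e2, total = e1 + e2),
            class = "ava_atp_yield")
}

#' Health-function parameters
#'
#' The health level h of a cell is its ATP balance normalized by the quiescent
#' maintenance production H_Q. A fully supplied quiescent cell is in exact
#' energy balance (production H_Q, decay D = 1 per hour); a fully supplied
#' proliferating cell produces H_P and gains health. Cells above 1.5 become
#' proliferating, below 0.5 irreversibly necrotic; mitosis requires the target
#' h >= H_P/H_Q.
#'
#' @param h_p Full proliferating ATP production (mM/h/cm^3).
#' @param h_q Full quiescent ATP production (mM/h/cm^3).
#' @param decay Normalized energy decay rate (1/h).
#' @param necrosis_threshold,proliferation_threshold State-change thresholds
#'   on h.
#' @return Named list of class \code{"ava_health"}; includes the mitosis
#'   target \code{h_mitosis = h_p/h_q}.
#' @export
health_params <- function(h_p = 828, h_q = 393.4, decay = 1,
                          necrosis_threshold = 0.5,
                          proliferation_threshold = 1.5) {
  if (h_p <= h_q) stop("proliferating ATP production must exceed quiescent production")
  if (necrosis_threshold >= proliferation_threshold)
    stop("necrosis threshold must lie below the proliferation threshold")
  structure(list(h_p = h_p, h_q = h_q, decay = decay,
                 necrosis_threshold = necrosis_threshold,
                 proliferation_threshold = proliferation_threshold,
                 h_mitosis = h_p / h_q),
            class = "ava_health")
}

#' Fraction of demand a cell can realize from the local field
#'
#' Table demand is a maximum; realized uptake scales linearly with the local
#' concentration relative to the boundary (host-supply) level, clamped to
#' [0, 1].
#'
#' @param field_value Local concentration (model-mM); vectorised.
#' @param boundary_value Boundary concentration (model-mM), > 0.
#' @return Fraction in [0, 1].
#' @export
demand_scaling <- function(field_value, boundary_value) {
  if (any(boundary_value <= 0))
    stop("demand scaling needs a positive boundary concentration for the consumed species")
  pmin(pmax(field_value / boundary_value, 0), 1)
}

#' One health-function update
#'
#' h_new = h_prev + (E1 + E2)/H_Q - D * dt. Vectorised over cells.
#'
#' @param h_prev Previous health levels.
#' @param yield An \code{\link{atp_yield}} result (its ATP rates are per
#'   hour; the produced amount over \code{dt} is rate * dt).
#' @param dt Time step (h).
#' @param hs A \code{\link{health_params}} object.
#' @return Updated health levels.
#' @export
health_update <- function(h_prev, yield, dt = 1, hs = health_params()) {
  if (dt <= 0) stop("dt must be positive")
  h_prev + (yield$e1_aerobic + yield$e2_anaerobic) * dt / hs$h_q - hs$decay * dt
}

#' Classify cell state from health level
#'
#' h above the proliferation threshold gives a proliferating cell, below the
#' necrosis threshold an (irreversibly) necrotic one, otherwise quiescent.
#' Cells already necrotic never revert.
#'
#' @param h Health levels (vectorised).
#' @param hs A \code{\link{health_params}} object.
#' @param current Optional current states; any \code{"necrotic"} entry is
#'   preserved regardless of h.
#' @return Character vector of states.
#' @export
classify_state <- function(h, hs = health_params(), current = NULL) {
  st <- ifelse(h > hs$proliferation_threshold, "proliferating",
        ifelse(h < hs$necrosis_threshold, "necrotic", "quiescent"))
  if (!is.null(current)) st[current == "necrotic"] <- "necrotic"
  st
}

#' Waste production implied by an ATP production rate
#'
#' One unit of waste per 3.5 units of ATP. Used as a consistency check
#' against the per-state waste rows of the rate table (which the simulator
#' uses directly); the two agree within a few percent.
#'
#' @param total_atp_rate ATP production rate (mM/h/cm^3), >= 0.
#' @param stoich An \code{\link{atp_stoichiometry}} object.
#' @return Waste production rate (mM/h/cm^3).
#' @export
waste_from_atp <- function(total_atp_rate, stoich = atp_stoichiometry()) {
  if (any(total_atp_rate < 0)) stop("ATP rate must be non-negative")
  total_atp_rate / stoich$atp_per_waste
}

#' @export
print.ava_atp_yield <- function(x, ...) {
  cat(sprintf("ATP yield: aerobic E1 = %s, anaerobic E2 = %s, total = %s (mM/h/cm^3)\n",
              format(x$e1_aerobic), format(x$e2_anaerobic), format(x$total)))
  invisible(x)
}
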