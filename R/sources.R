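#' Assemble per-species source terms from the cell population
#'
#' Each living cell consumes oxygen and glucose at its state's table demand
#' scaled by local availability (\code{\link{demand_scaling}}), metabolizes
#' the realized supply through the two-pathway ATP stoichiometry, and
#' produces waste and signaling factors scaled by its realized metabolic
#' activity (ATP as a fraction of the state's fully-supplied production).
#' Necrotic cells neither consume nor metabolize but release growth inhibitor
#' at the (unscaled) table rate. Each cell's total rate is distributed
#' conservatively over the grid nodes surrounding it (cloud-in-cell weights,
#' restricted and renormalized to interior nodes); consumption enters
#' negative, production positive.
#'
#' @param cells The population.
#' @param grid The domain grid.
#' @param fields Named list of species fields (for availability scaling).
#' @param rates A \code{\link{metabolic_rate_table}}.
#' @param stoich An \code{\link{atp_stoichiometry}}.
#' @param coupling Dimensionless factor converting per-cell-volume rates to
#'   grid source amplitude (see the package vignette); 1 leaves the table
#'   totals unscaled.
#' @return List of class \code{"ava_sources"}: \code{sources} (named list of
#'   source arrays, model-mM per hour), \code{uptake} (data frame of realized
#'   per-cell oxygen/glucose supply), \code{yield} (the population
#'   \code{\link{atp_yield}}), \code{activity} (per-cell metabolic activity
#'   fractions).
#' @export
deposit_sources <- function(cells, grid, fields, rates = metabolic_rate_table(),
                            stoich = atp_stoichiometry(), coupling = 1) {
  n <- nrow(cells)
  zero_sources <- stats::setNames(
    lapply(species_ids(), function(s) array(0, dim = grid$n)), species_ids())
  if (n == 0L) {
    return(structure(list(sources = zero_sources,
                          uptake = data.frame(oxygen = numeric(), glucose = numeric()),
                          yield = atp_yield(numeric(), numeric(), stoich),
                          activity = numeric()),
                     class = "ava_sources"))
  }
  pos <- cell_positions(cells)
  # errors if any cell is outside the domain
  frac <- .pos_to_frac(pos, grid)

  c_o <- sample_concentration(fields$oxygen, pos, grid)
  c_g <- sample_concentration(fields$glucose, pos, grid)
  sc_o <- demand_scaling(c_o, fields$oxygen$boundary_value)
  sc_g <- demand_scaling(c_g, fields$glucose$boundary_value)

  st <- cells$state
  demand_o <- rates[st, "oxygen"]
  demand_g <- rates[st, "glucose"]
  supplied_o <- demand_o * sc_o
  supplied_g <- demand_g * sc_g
  yield <- atp_yield(supplied_o, supplied_g, stoich)

  full <- atp_yield(rates[st, "oxygen"], rates[st, "glucose"], stoich)$total
  activity <- ifelse(full > 0, yield$total / full, 0)

  amounts <- cbind(
    oxygen = -supplied_o,
    glucose = -supplied_g,
    waste = rates[st, "waste"] * activity,
    growth_factor = rates[st, "growth_factor"] * activity,
    growth_inhibitor = ifelse(st == "necrotic",
                              rates[st, "growth_inhibitor"],
                              rates[st, "growth_inhibitor"] * activity)
  )

  cw <- .cic_weights(frac, grid)
  sources <- zero_sources
  for (sp in species_ids()) {
    amt <- amounts[, sp] * coupling
    live <- amt != 0
    if (!any(live)) next
    contrib <- as.numeric(cw$w[live, , drop = FALSE] * amt[live])
    at <- as.numeric(cw$idx[live, , drop = FALSE])
    acc <- tapply(contrib, at, sum)
    src <- sources[[sp]]
    src[as.integer(names(acc))] <- as.numeric(acc)
    sources[[sp]] <- src
  }
  structure(list(sources = sources,
                 uptake = data.frame(oxygen = supplied_o, glucose = supplied_g),
                 yield = yield, activity = activity),
            class = "ava_sources")
}

#' Competitive nutrient uptake over one time step
#'
#' The engine's coupled uptake model for the consumed species (oxygen,
#' glucose). Each cell's demand, spread over its cloud-in-cell nodes,
#' contributes to a nodal uptake intensity
#' \eqn{\lambda = \sum_{cells} w \cdot demand \cdot coupling \cdot g / C_b},
#' where \eqn{g} is the cell-footprint to node-volume ratio (disk area over
#' node area in 2-D, sphere over node volume in 3-D) that makes the coupling
#' independent of grid resolution; over a step the node concentration decays
#' as \eqn{C e^{-\lambda dt}} and the cells share the drained mass in
#' proportion to their demand, each realizing supply from the time-averaged
#' concentration \eqn{\bar C = C (1 - e^{-\lambda dt})/(\lambda dt)}. This
#' is exact for a static configuration, unconditionally stable, and never
#' overdraws a node (unlike explicit linear deposition, which alternates
#' between starvation and full supply when \eqn{\lambda dt \gtrsim 1}).
#'
#' @inheritParams deposit_sources
#' @param dt Time step (h).
#' @return List: \code{sinks} (oxygen/glucose source arrays for
#'   \code{\link{diffusion_step}}, non-positive), \code{uptake} (per-cell
#'   realized supply rates), \code{yield} (population
#'   \code{\link{atp_yield}}), \code{activity} (ATP fraction of the state's
#'   full production).
#' @export
nutrient_uptake <- function(cells, grid, fields, rates = metabolic_rate_table(),
                            stoich = atp_stoichiometry(), coupling = 1,
                            dt = 1) {
  n <- nrow(cells)
  sinks <- list(oxygen = array(0, dim = grid$n), glucose = array(0, dim = grid$n))
  if (n == 0L)
    return(list(sinks = sinks,
                uptake = data.frame(oxygen = numeric(), glucose = numeric()),
                yield = atp_yield(numeric(), numeric(), stoich),
                activity = numeric()))
  pos <- cell_positions(cells)
  frac <- .pos_to_frac(pos, grid)
  cw <- .cic_weights(frac, grid)
  st <- cells$state
  geom <- .cell_node_ratio(cells$radius, grid)
  supplied <- list()
  for (sp in c("oxygen", "glucose")) {
    bv <- fields[[sp]]$boundary_value
    if (bv <= 0) stop("consumed species needs a positive boundary concentration")
    demand <- unname(rates[st, sp])
    lam <- array(0, dim = grid$n)
    contrib <- as.numeric(cw$w * (demand * coupling * geom / bv))
    acc <- rowsum(contrib, group = as.integer(cw$idx))
    lam[as.integer(rownames(acc))] <- acc
    Cnow <- fields[[sp]]$values
    lt <- lam * dt
    decay <- exp(-lt)
    cbar <- ifelse(lt > 1e-12, Cnow * (1 - decay) / lt, Cnow)
    sink <- -Cnow * (1 - decay) / dt
    sink[!grid$interior] <- 0
    sinks[[sp]] <- sink
    # per-cell availability from the time-averaged concentration at its nodes
    s_cell <- rowSums(cw$w * matrix(cbar[as.integer(cw$idx)], n)) / bv
    supplied[[sp]] <- demand * pmin(pmax(s_cell, 0), 1)
  }
  yield <- atp_yield(supplied$oxygen, supplied$glucose, stoich)
  full <- atp_yield(unname(rates[st, "oxygen"]), unname(rates[st, "glucose"]),
                    stoich)$total
  activity <- ifelse(full > 0, yield$total / full, 0)
  list(sinks = sinks,
       uptake = data.frame(oxygen = supplied$oxygen, glucose = supplied$glucose),
       yield = yield, activity = activity)
}

# cell footprint (disk/sphere) to node cell volume ratio: makes the source
# coupling independent of grid resolution
.cell_node_ratio <- function(radius, grid) {
  vol <- if (grid$dim == 2L) pi * radius^2 else 4 / 3 * pi * radius^3
  vol / prod(grid$spacing)
}

#' Production source terms from realized metabolic activity
#'
#' Waste, growth-factor and inhibitor deposition for the engine: table rates
#' scaled by each cell's metabolic activity (necrotic inhibitor release
#' unscaled) and by the cell-footprint to node-volume ratio, spread by
#' cloud-in-cell weights.
#'
#' @inheritParams deposit_sources
#' @param activity Per-cell metabolic activity fractions.
#' @return Named list of source arrays (waste, growth_factor,
#'   growth_inhibitor).
#' @export
production_sources <- function(cells, grid, activity,
                               rates = metabolic_rate_table(), coupling = 1) {
  out <- list(waste = array(0, dim = grid$n),
              growth_factor = array(0, dim = grid$n),
              growth_inhibitor = array(0, dim = grid$n))
  n <- nrow(cells)
  if (n == 0L) return(out)
  pos <- cell_positions(cells)
  cw <- .cic_weights(.pos_to_frac(pos, grid), grid)
  st <- cells$state
  geom <- .cell_node_ratio(cells$radius, grid)
  amounts <- geom * cbind(
    waste = unname(rates[st, "waste"]) * activity,
    growth_factor = unname(rates[st, "growth_factor"]) * activity,
    growth_inhibitor = ifelse(st == "necrotic",
                              unname(rates[st, "growth_inhibitor"]),
                              unname(rates[st, "growth_inhibitor"]) * activity)
  )
  for (sp in colnames(amounts)) {
    amt <- amounts[, sp] * coupling
    if (!any(amt != 0)) next
    contrib <- as.numeric(cw$w * amt)
    acc <- rowsum(contrib, group = as.integer(cw$idx))
    src <- out[[sp]]
    src[as.integer(rownames(acc))] <- acc
    out[[sp]] <- src
  }
  out
}

# cloud-in-cell deposition weights, renormalized onto interior nodes
.cic_weights <- function(frac, grid) {
  np <- nrow(frac)
  K <- 2^grid$dim
  i0 <- pmin(pmax(floor(frac), 0), matrix(grid$n - 2, np, grid$dim, byrow = TRUE))
  tt <- frac - i0
  idx <- matrix(0L, np, K)
  w <- matrix(0, np, K)
  for (corner in 0:(K - 1)) {
    bits <- as.integer(intToBits(corner))[seq_len(grid$dim)]
    idx[, corner + 1] <- 1 + (i0 + matrix(bits, np, grid$dim, byrow = TRUE)) %*% grid$strides
    wc <- rep(1, np)
    for (a in seq_len(grid$dim))
      wc <- wc * if (bits[a] == 1L) tt[, a] else 1 - tt[, a]
    w[, corner + 1] <- wc
  }
  ok <- matrix(grid$interior[idx], np, K)
  w <- w * ok
  s <- rowSums(w)
  pos <- s > 0
  w[pos, ] <- w[pos, , drop = FALSE] / s[pos]
  # cells whose whole stencil sits in the Dirichlet rim deposit nothing
  list(idx = idx, w = w)
}
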