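#' Simulation configuration
#'
#' Flat key-value configuration with every key defaulted; unknown keys are
#' rejected. Time is measured in iterations of \code{dt} hours (metabolic and
#' diffusion rates are per hour).
#'
#' @param dim Domain dimensionality (2 or 3).
#' @param grid_n Nodes per axis.
#' @param extent Domain extent (cm).
#' @param dt Hours per iteration.
#' @param iterations Number of iterations.
#' @param snapshot_interval Iterations between retained snapshots.
#' @param seed RNG seed recorded in every output.
#' @param oxygen_boundary,glucose_boundary Dirichlet boundary concentrations
#'   (model-mM).
#' @param uptake_coupling Dimensionless cell-to-grid source coupling (see
#'   vignette).
#' @param cell_radius Cell radius (cm).
#' @param mobility Overdamped mobility (displacement per force per hour).
#' @param chemo_alpha,chemo_beta,chemo_gamma Chemotaxis weights.
#' @param k_pp,k_pq,k_qq,spring_cutoff Adhesion spring constants and cutoff.
#' @param r_mitosis,sigma_mitosis,hayflick_limit,mutation_increment_prob
#'   Mitosis parameters.
#' @param mitosis_gate Require the health target h >= H_P/H_Q before the
#'   stochastic division draw (\code{FALSE} gives probability-only mode).
#' @param stem_enabled Include the roaming cancer stem cell.
#' @param stem_period Iterations between stem-cell spawns.
#' @param dissolution_delay Iterations before a necrotic cell dissolves.
#' @param diffusion_method \code{"implicit"} (default) or \code{"explicit"}.
#' @param domain_radius Radius of the circular biological domain (cm); nodes
#'   beyond it are Dirichlet boundary (NULL: inscribed radius).
#' @param overlap_max_iter Projection sweep cap per iteration (residual
#'   overlaps carry to the next iteration).
#' @param log_file Optional path for a timestamped per-iteration population
#'   ledger log.
#' @param out_dir Output directory for CSV/JSON artifacts (NULL: in-memory
#'   only).
#' @return Object of class \code{"ava_config"} (named list).
#' @export
simulation_config <- function(dim = 2L, grid_n = 100L, extent = 0.2, dt = 1,
                              iterations = 300L, snapshot_interval = 10L,
                              seed = 1L,
                              oxygen_boundary = 0.00053, glucose_boundary = 0.005,
                              uptake_coupling = 2e-5,
                              cell_radius = 0.001, mobility = 0.1,
                              chemo_alpha = 1, chemo_beta = 1, chemo_gamma = 0.5,
                              k_pp = 1, k_pq = 0.5, k_qq = 0.25, spring_cutoff = 1.2,
                              r_mitosis = 0.0315, sigma_mitosis = 0.01,
                              hayflick_limit = 60L, mutation_increment_prob = 0.05,
                              mitosis_gate = TRUE,
                              stem_enabled = TRUE, stem_period = 70L,
                              dissolution_delay = 100,
                              diffusion_method = "implicit",
                              domain_radius = 0.05,
                              overlap_max_iter = 25L,
                              log_file = NULL,
                              out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$dim %in% c(2L, 3L), cfg$grid_n >= 5, cfg$extent > 0,
            cfg$dt > 0, cfg$iterations >= 0, cfg$snapshot_interval >= 1,
            cfg$uptake_coupling > 0, cfg$cell_radius > 0)
  structure(cfg, class = "ava_config")
}

#' Load a configuration from a flat JSON file
#'
#' Every key defaults to \code{\link{simulation_config}}'s value; unknown
#' keys are rejected.
#'
#' @param path JSON file of key-value overrides.
#' @return An \code{"ava_config"}.
#' @export
load_config <- function(path) {
  overrides <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(simulation_config, overrides)
}

#' @export
print.ava_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d-D, %d^%d grid over %g cm, dt = %g h, %d iterations, seed %d\n",
              x$dim, x$grid_n, x$dim, x$extent, x$dt, x$iterations, x$seed))
  invisible(x)
}

# chemotaxis force on proliferating cells, saturated so one iteration moves
# a cell at most one radius
.chemotaxis_force <- function(cells, fields, grid, cfg, weights) {
  pos <- cell_positions(cells)
  F <- matrix(0, nrow(cells), ncol(pos))
  prolif <- which(cells$state == "proliferating")
  if (!length(prolif)) return(F)
  m <- chemotaxis_vector(pos[prolif, , drop = FALSE], fields, weights, grid)
  m_ref <- (weights$alpha * fields$oxygen$boundary_value +
              weights$beta * fields$glucose$boundary_value) / grid$radius
  mag <- sqrt(rowSums(m^2))
  f_max <- cfg$cell_radius / (cfg$mobility * cfg$dt)
  scale <- ifelse(mag > 0, f_max * tanh(mag / m_ref) / mag, 0)
  F[prolif, ] <- m * scale
  F
}

#' Run the multiscale tumor growth simulation
#'
#' Executes the per-iteration operator sequence: (1) source deposition from
#' the cells, (2) diffusion of all five species, (3) per-cell uptake, ATP
#' yield and health update, (4) state classification, (5) mitosis attempts,
#' (6) the stem-cell step, (7) necrotic dissolution, (8) adhesion +
#' chemotaxis forces, motion integration and overlap resolution, (9)
#' bookkeeping and snapshots. Fully deterministic for a given seed. The run
#' starts from one founder proliferating cell at the domain center and (if
#' enabled) one stem cell at a uniformly random location.
#'
#' @param config An \code{\link{simulation_config}}.
#' @return Object of class \code{"ava_run"}: config, the domain grid, final
#'   \code{cells} and \code{fields}, the per-iteration population
#'   \code{series}, retained \code{snapshots}, event iterations
#'   (\code{first_quiescent}, \code{first_necrotic}) and the per-iteration
#'   birth/death \code{ledger}.
#' @export
run_simulation <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  grid <- make_grid(rep(cfg$grid_n, cfg$dim), cfg$extent,
                    radius = cfg$domain_radius)
  bc <- boundary_conditions(oxygen = cfg$oxygen_boundary,
                            glucose = cfg$glucose_boundary)
  fields <- initialize_fields(grid, bc)
  rates <- metabolic_rate_table()
  stoich <- atp_stoichiometry()
  hs <- health_params()
  mit <- mitosis_params(r = cfg$r_mitosis, sigma = cfg$sigma_mitosis,
                        hayflick_limit = cfg$hayflick_limit,
                        mutation_increment_prob = cfg$mutation_increment_prob)
  springs <- spring_constants(cfg$k_pp, cfg$k_pq, cfg$k_qq, cfg$spring_cutoff)
  weights <- chemotaxis_weights(cfg$chemo_alpha, cfg$chemo_beta, cfg$chemo_gamma)

  solvers <- NULL
  if (cfg$diffusion_method == "implicit")
    solvers <- lapply(fields, function(f)
      make_diffusion_solver(grid, f$diffusion_constant, cfg$dt))

  center <- grid$center
  cells <- make_cells(x = center[1], y = center[2],
                      z = if (cfg$dim == 3) center[3] else NULL,
                      radius = cfg$cell_radius, state = "proliferating",
                      health = 2)
  next_id <- 2L
  stem <- NULL
  if (cfg$stem_enabled) {
    repeat {   # uniform location inside the circular domain
      cand <- stats::runif(cfg$dim, 0, grid$extent)
      if (sqrt(sum((cand - center)^2)) < grid$radius - cfg$cell_radius) break
    }
    stem <- stem_cell(cand, spawn_period = cfg$stem_period)
  }

  if (!is.null(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  snapshots <- list()
  take_snapshot <- function(it) {
    snapshots[[as.character(it)]] <<- cells
    if (!is.null(cfg$out_dir))
      write_cells_csv(cells, file.path(cfg$out_dir, sprintf("cells_t%04d.csv", it)), it)
  }
  take_snapshot(0L)

  nits <- cfg$iterations
  series <- data.frame(iteration = seq_len(nits),
                       proliferating = integer(nits), quiescent = integer(nits),
                       necrotic = integer(nits))
  ledger <- data.frame(iteration = seq_len(nits), births = integer(nits),
                       spawns = integer(nits), removed = integer(nits),
                       n_before = integer(nits), n_after = integer(nits))
  first_quiescent <- NA_integer_
  first_necrotic <- NA_integer_

  for (it in seq_len(nits)) {
    n_before <- nrow(cells)

    # (1) sources from cells (competitive uptake + metabolic production),
    # (2) diffusion
    src <- nutrient_uptake(cells, grid, fields, rates, stoich,
                           coupling = cfg$uptake_coupling, dt = cfg$dt)
    prod <- production_sources(cells, grid, src$activity, rates,
                               coupling = cfg$uptake_coupling)
    sources <- c(src$sinks, prod)
    for (sp in species_ids())
      fields[[sp]] <- diffusion_step(fields[[sp]], sources[[sp]], cfg$dt,
                                     grid, method = cfg$diffusion_method,
                                     solver = solvers[[sp]])

    # (3) health update (necrotic cells frozen), (4) classification
    if (nrow(cells)) {
      living <- cells$state != "necrotic"
      h_new <- health_update(cells$health, src$yield, cfg$dt, hs)
      cells$health[living] <- h_new[living]
      new_state <- classify_state(cells$health, hs, current = cells$state)
      newly_necrotic <- new_state == "necrotic" & cells$state != "necrotic"
      cells$necrosis_time[newly_necrotic] <- it
      cells$state <- new_state
    }

    # (5) mitosis
    births <- 0L
    if (nrow(cells)) {
      pos <- cell_positions(cells)
      c_gf <- sample_concentration(fields$growth_factor, pos, grid)
      c_gi <- sample_concentration(fields$growth_inhibitor, pos, grid)
      if (!cfg$mitosis_gate) {
        gate_hs <- hs; gate_hs$h_mitosis <- -Inf
      } else gate_hs <- hs
      res <- attempt_mitosis(cells, c_gf, c_gi, mit, gate_hs, next_id)
      cells <- res$cells; births <- res$births; next_id <- res$next_id
    }

    # (6) stem cell
    spawns <- 0L
    if (!is.null(stem)) {
      sres <- stem_cell_step(stem, it, grid, step_length = 2 * cfg$cell_radius,
                             cell_radius = cfg$cell_radius)
      stem <- sres$stem
      if (!is.null(sres$spawn)) {
        sres$spawn$id <- next_id
        next_id <- next_id + 1L
        cells <- rbind(cells, sres$spawn)
        class(cells) <- c("ava_cells", "data.frame")
        spawns <- 1L
      }
    }

    # (7) dissolution
    dres <- dissolve_necrotic(cells, it, cfg$dissolution_delay)
    cells <- dres$cells

    # (8) mechanics
    if (nrow(cells) > 0) {
      Fad <- adhesion_forces(cells, springs)
      Fch <- .chemotaxis_force(cells, fields, grid, cfg, weights)
      cells <- integrate_motion(cells, Fad + Fch, cfg$dt, cfg$mobility, grid,
                                resolve = FALSE)
      cells <- suppressWarnings(
        resolve_overlaps(cells, grid, max_iter = cfg$overlap_max_iter))
    }

    # (9) bookkeeping
    tab <- table(factor(cells$state, levels = cell_states()))
    series$proliferating[it] <- tab[["proliferating"]]
    series$quiescent[it] <- tab[["quiescent"]]
    series$necrotic[it] <- tab[["necrotic"]]
    ledger[it, c("births", "spawns", "removed", "n_before", "n_after")] <-
      c(births, spawns, dres$removed, n_before, nrow(cells))
    if (is.na(first_quiescent) && tab[["quiescent"]] > 0) first_quiescent <- it
    if (is.na(first_necrotic) && tab[["necrotic"]] > 0) first_necrotic <- it
    if (!is.null(cfg$log_file))
      cat(file = cfg$log_file, append = TRUE,
          sprintf("%s INFO iter=%d cells=%d proliferating=%d quiescent=%d necrotic=%d births=%d spawns=%d removed=%d\n",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), it, nrow(cells),
                  tab[["proliferating"]], tab[["quiescent"]], tab[["necrotic"]],
                  births, spawns, dres$removed))
    if (it %% cfg$snapshot_interval == 0L || it == nits) take_snapshot(it)
    if (nrow(cells) == 0L) {
      series <- series[seq_len(it), ]; ledger <- ledger[seq_len(it), ]
      break
    }
  }

  run <- structure(list(config = cfg, grid = grid, cells = cells,
                        fields = fields, series = series, snapshots = snapshots,
                        ledger = ledger,
                        first_quiescent = first_quiescent,
                        first_necrotic = first_necrotic,
                        stem = stem),
                   class = "ava_run")
  if (!is.null(cfg$out_dir)) {
    write_population_csv(series, file.path(cfg$out_dir, "population.csv"))
    manifest <- list(seed = cfg$seed, iterations = nrow(series),
                     config = unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                     final_cells = nrow(cells),
                     first_quiescent = first_quiescent,
                     first_necrotic = first_necrotic)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  run
}

#' @export
print.ava_run <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("Tumor simulation run: %d iterations, %d cells at end\n",
              n, nrow(x$cells)))
  if (n) {
    last <- x$series[n, ]
    cat(sprintf("  final counts: proliferating %d, quiescent %d, necrotic %d\n",
                last$proliferating, last$quiescent, last$necrotic))
  }
  cat(sprintf("  first quiescent cell at iteration %s; first necrotic at %s\n",
              format(x$first_quiescent), format(x$first_necrotic)))
  invisible(x)
}

#' @export
plot.ava_run <- function(x, which = c("population", "snapshot"), ...) {
  which <- match.arg(which)
  if (which == "population") {
    s <- x$series
    living <- s$proliferating + s$quiescent
    graphics::matplot(s$iteration, cbind(s$proliferating, s$quiescent,
                                         s$necrotic, living),
                      type = "l", lty = 1, lwd = 2,
                      col = c("blue", "darkgreen", "black", "red"),
                      xlab = "iteration", ylab = "cells",
                      main = "Tumor cell populations", ...)
    graphics::legend("topleft", c("proliferating", "quiescent", "necrotic", "living"),
                     col = c("blue", "darkgreen", "black", "red"), lty = 1, lwd = 2,
                     bty = "n")
  } else {
    plot_snapshot(x$cells, x$grid, ...)
  }
  invisible(x)
}

#' Plot a cell snapshot
#'
#' Cells drawn as circles colored by state (blue proliferating, green
#' quiescent, black necrotic).
#'
#' @param cells The population (2-D; 3-D populations are projected on x-y).
#' @param grid Optional grid for the domain outline.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, the population.
#' @export
plot_snapshot <- function(cells, grid = NULL, ...) {
  cols <- c(proliferating = "blue", quiescent = "darkgreen", necrotic = "black")
  lim <- if (!is.null(grid)) c(0, max(grid$extent)) else range(c(cells$x, cells$y))
  plot(NA, xlim = lim, ylim = lim, asp = 1, xlab = "x (cm)", ylab = "y (cm)", ...)
  if (!is.null(grid) && grid$shape == "circle") {
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(grid$center[1] + grid$radius * cos(th),
                    grid$center[2] + grid$radius * sin(th), col = "grey")
  }
  if (nrow(cells))
    graphics::symbols(cells$x, cells$y, circles = cells$radius, inches = FALSE,
                      add = TRUE, fg = cols[cells$state], bg = cols[cells$state])
  invisible(cells)
}

#' Recompute the printed metabolic and boundary constants
#'
#' Re-derives, from the rate table, stoichiometry and blood physiology, the
#' hand-worked reference values: ATP production of fully supplied
#' proliferating and quiescent cells (aerobic/anaerobic split and totals),
#' the proliferation energy margin, the hemoglobin conversions, the tissue
#' blood-oxygen value, and the summed sigmoid asymptotes of the reference
#' population fits. Each row compares the recomputed value with the reference
#' at its printed precision (half-away-from-zero rounding).
#'
#' @return Data frame with columns \code{quantity}, \code{computed},
#'   \code{reference}, \code{pass}.
#' @export
validate_constants <- function() {
  rates <- metabolic_rate_table()
  stoich <- atp_stoichiometry()
  yp <- atp_yield(rates["proliferating", "oxygen"], rates["proliferating", "glucose"], stoich)
  yq <- atp_yield(rates["quiescent", "oxygen"], rates["quiescent", "glucose"], stoich,
                  round_digits = 1)
  consts <- physiological_constants()
  hgb_lo <- hgb_mass_to_molar(consts$hgb_blood_concentration_range[1],
                              consts$hgb_molecular_weight)
  hgb_hi <- hgb_mass_to_molar(consts$hgb_blood_concentration_range[2],
                              consts$hgb_molecular_weight)
  t_hgb <- tissue_hgb(consts$large_vessel_hgb_molar, consts$tissue_hematocrit_ratio)
  c_b <- blood_oxygen(t_hgb, consts$oxyphoric_power, consts$blood_saturation)
  total_asym <- total_living_asymptote(9.5322e6, 3.9289e6)
  rows <- list(
    list("proliferating aerobic ATP",    yp$e1_aerobic,               540,      0),
    list("proliferating total ATP",      yp$total,                    828,      0),
    list("quiescent aerobic ATP",        yq$e1_aerobic,               250,      0),
    list("quiescent anaerobic ATP",      yq$e2_anaerobic,             143.4,    1),
    list("quiescent residual glucose",   yq$glucose_anaerobic,        71.7,     1),
    list("quiescent total ATP",          yq$total,                    393.4,    1),
    list("proliferation energy margin",  yp$total - yq$total,         434.6,    1),
    list("hemoglobin 122 g/L as mM",     hgb_lo,                      0.0019,   4),
    list("hemoglobin 150 g/L as mM",     hgb_hi,                      0.0023,   4),
    list("tissue hemoglobin (mM)",       t_hgb,                       0.0016,   4),
    list("blood oxygen (mM)",            c_b,                         0.0048,   4),
    list("total living asymptote",       total_asym,                  1.3461e7, -3)
  )
  out <- data.frame(
    quantity = vapply(rows, `[[`, character(1), 1),
    computed = vapply(rows, `[[`, numeric(1), 2),
    reference = vapply(rows, `[[`, numeric(1), 3)
  )
  digits <- vapply(rows, `[[`, numeric(1), 4)
  out$pass <- round_half_up(out$computed, digits) == out$reference
  out
}
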