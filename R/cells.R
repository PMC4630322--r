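#' Create a cell population table
#'
#' Cells are rows of a data frame: continuous position (cm), radius, state,
#' health level, generation count (mitoses since the founder), mutation count
#' and, for necrotic cells, the iteration at which necrosis occurred.
#'
#' @param x,y,z Coordinates (cm); \code{z} omitted for 2-D populations.
#' @param radius Cell radius (cm); default 10 micron (20 micron diameter).
#' @param state Cell states (see \code{\link{cell_states}}).
#' @param health Health levels.
#' @param generation Mitosis counts since the founder.
#' @param mutations Accumulated phenotype mutation counts.
#' @param necrosis_time Iteration of necrosis (NA while alive).
#' @param id Unique integer ids; assigned sequentially if NULL.
#' @return A data frame of class \code{"ava_cells"}.
#' @export
make_cells <- function(x = numeric(), y = numeric(), z = NULL,
                       radius = 0.001, state = "proliferating",
                       health = 1, generation = 0L, mutations = 0L,
                       necrosis_time = NA_integer_, id = NULL) {
  n <- length(x)
  if (is.null(id)) id <- seq_len(n)
  df <- data.frame(id = as.integer(id), x = x, y = y)
  if (!is.null(z)) df$z <- z
  df$radius <- rep_len(radius, n)
  df$state <- rep_len(state, n)
  df$health <- rep_len(health, n)
  df$generation <- rep_len(as.integer(generation), n)
  df$mutations <- rep_len(as.integer(mutations), n)
  df$necrosis_time <- rep_len(as.integer(necrosis_time), n)
  stopifnot(all(df$radius > 0), all(df$generation >= 0), all(df$mutations >= 0),
            all(df$state %in% cell_states()))
  class(df) <- c("ava_cells", "data.frame")
  df
}

#' Position matrix of a cell population
#' @param cells An \code{"ava_cells"} data frame.
#' @return Numeric matrix (cells x dim).
#' @export
cell_positions <- function(cells) {
  cols <- intersect(c("x", "y", "z"), names(cells))
  as.matrix(as.data.frame(cells)[, cols, drop = FALSE])
}

.set_positions <- function(cells, pos) {
  cols <- intersect(c("x", "y", "z"), names(cells))
  for (k in seq_along(cols)) cells[[cols[k]]] <- pos[, k]
  cells
}

#' Mitosis parameters
#'
#' @param r Base per-iteration mitosis probability of a normal tissue cell.
#' @param sigma Standard deviation of the Gaussian noise on the probability.
#' @param hayflick_limit Maximum generation count that may still divide.
#' @param mutation_increment_prob Probability per daughter of gaining one
#'   phenotype mutation at division.
#' @return Named list of class \code{"ava_mitosis"}.
#' @export
mitosis_params <- function(r = 0.0315, sigma = 0.01, hayflick_limit = 60L,
                           mutation_increment_prob = 0.05) {
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)")
  if (sigma < 0) stop("sigma must be non-negative")
  if (hayflick_limit < 1) stop("hayflick_limit must be a positive integer")
  structure(list(r = r, sigma = sigma, hayflick_limit = as.integer(hayflick_limit),
                 mutation_increment_prob = mutation_increment_prob),
            class = "ava_mitosis")
}

#' Mean mitosis probability scale
#'
#' M = r (1 + mu) (1 + C_GF - C_GI), floored at zero so inhibitor-dominated
#' environments suppress division rather than produce negative probabilities.
#'
#' @param r Base mitosis probability.
#' @param mu Mutation counts (vectorised).
#' @param c_gf,c_gi Local growth-factor / growth-inhibitor concentrations.
#' @return Probability scale M >= 0.
#' @export
mitosis_mean <- function(r, mu, c_gf, c_gi) {
  if (any(c_gf < 0) || any(c_gi < 0)) stop("concentrations must be non-negative")
  pmax(r * (1 + mu) * (1 + c_gf - c_gi), 0)
}

#' Per-iteration mitosis probability
#'
#' (h - 1) M plus Gaussian noise, clamped to [0, 1]; exactly zero at or
#' beyond the Hayflick limit regardless of health.
#'
#' @param h Health levels (vectorised).
#' @param M Probability scales from \code{\link{mitosis_mean}}.
#' @param N Generation counts.
#' @param sigma Noise standard deviation.
#' @param hayflick_limit Generation cutoff.
#' @param eps Optional pre-drawn noise (for reproducibility in tests); drawn
#'   from the current RNG stream if NULL.
#' @return Probabilities in [0, 1].
#' @export
mitosis_probability <- function(h, M, N, sigma = 0, hayflick_limit = 60L, eps = NULL) {
  k <- max(length(h), length(M), length(N))
  if (is.null(eps)) eps <- if (sigma > 0) stats::rnorm(k, 0, sigma) else numeric(k)
  p <- pmin(pmax((h - 1) * M + eps, 0), 1)
  p[rep_len(N, k) >= hayflick_limit] <- 0
  p
}

#' Attempt mitosis across the population
#'
#' Proliferating cells whose health has reached the mitosis target
#' h >= H_P/H_Q draw a Bernoulli division with probability
#' \code{\link{mitosis_probability}}. A dividing mother is replaced by two
#' daughters at her position (separated next by the mechanics step), each
#' with half her health and generation N + 1; each daughter independently
#' gains a mutation with the configured probability.
#'
#' @param cells The population.
#' @param c_gf,c_gi Growth-factor and inhibitor concentrations at each cell.
#' @param params A \code{\link{mitosis_params}} object.
#' @param hs A \code{\link{health_params}} object (mitosis target).
#' @param next_id First id to assign to daughters.
#' @return List: \code{cells} (updated population), \code{births} (number of
#'   divisions), \code{next_id}.
#' @export
attempt_mitosis <- function(cells, c_gf, c_gi, params = mitosis_params(),
                            hs = health_params(), next_id = NULL) {
  n <- nrow(cells)
  if (is.null(next_id)) next_id <- if (n) max(cells$id) + 1L else 1L
  eligible <- cells$state == "proliferating" & cells$health >= hs$h_mitosis &
    cells$generation < params$hayflick_limit
  if (!any(eligible))
    return(list(cells = cells, births = 0L, next_id = next_id))
  idx <- which(eligible)
  M <- mitosis_mean(params$r, cells$mutations[idx], c_gf[idx], c_gi[idx])
  p <- mitosis_probability(cells$health[idx], M, cells$generation[idx],
                           params$sigma, params$hayflick_limit)
  divide <- idx[stats::runif(length(idx)) < p]
  if (!length(divide))
    return(list(cells = cells, births = 0L, next_id = next_id))
  mothers <- cells[divide, , drop = FALSE]
  daughters <- mothers[rep(seq_len(nrow(mothers)), each = 2L), , drop = FALSE]
  daughters$id <- seq.int(next_id, length.out = nrow(daughters))
  daughters$health <- daughters$health / 2
  daughters$generation <- daughters$generation + 1L
  daughters$mutations <- daughters$mutations +
    as.integer(stats::runif(nrow(daughters)) < params$mutation_increment_prob)
  out <- rbind(cells[-divide, , drop = FALSE], daughters)
  rownames(out) <- NULL
  class(out) <- class(cells)
  list(cells = out, births = length(divide),
       next_id = next_id + nrow(daughters))
}

#' Create a cancer stem cell
#'
#' A free-roaming emitter: it random-walks through the domain and every
#' \code{spawn_period} iterations deposits one fresh proliferating cancer
#' cell at its current position. Stem cells are exempt from metabolism and
#' necrosis.
#'
#' @param position Numeric coordinate vector (cm).
#' @param spawn_period Iterations between spawns.
#' @param last_spawn Iteration of the previous spawn.
#' @return List of class \code{"ava_stem"}.
#' @export
stem_cell <- function(position, spawn_period = 70L, last_spawn = 0L) {
  if (spawn_period < 1) stop("spawn_period must be positive")
  structure(list(position = as.numeric(position),
                 spawn_period = as.integer(spawn_period),
                 last_spawn = as.integer(last_spawn)),
            class = "ava_stem")
}

# reflect a point radially back inside the circular domain (or clamp for rect)
.reflect_inside <- function(p, grid, margin = 0) {
  if (grid$shape == "circle") {
    v <- p - grid$center
    r <- sqrt(sum(v^2))
    rmax <- grid$radius - margin
    if (r > rmax && r > 0) p <- grid$center + v / r * (2 * rmax - r)
    # fold again if the reflection overshot through the center
    v <- p - grid$center
    r <- sqrt(sum(v^2))
    if (r > rmax && r > 0) p <- grid$center + v / r * rmax
  }
  pmin(pmax(p, margin), grid$extent - margin)
}

#' One stem-cell iteration
#'
#' Takes one uniform-direction random-walk step of one cell diameter,
#' reflected at the domain boundary; when \code{spawn_period} iterations have
#' elapsed since the last spawn, emits one proliferating cell (h = 1, N = 0,
#' mu = 0) at the stem position.
#'
#' @param stem An \code{\link{stem_cell}} object.
#' @param iteration Current iteration number.
#' @param grid The domain grid.
#' @param step_length Walk step (cm); default one cell diameter.
#' @param cell_radius Radius for spawned cells (cm).
#' @return List: \code{stem} (moved, possibly reset spawn clock) and
#'   \code{spawn} (a one-row cell data frame, or NULL).
#' @export
stem_cell_step <- function(stem, iteration, grid, step_length = 0.002,
                           cell_radius = 0.001) {
  dim <- length(stem$position)
  dir <- stats::rnorm(dim)
  nrm <- sqrt(sum(dir^2))
  if (nrm == 0) dir <- c(1, rep(0, dim - 1)) else dir <- dir / nrm
  stem$position <- .reflect_inside(stem$position + step_length * dir, grid,
                                   margin = cell_radius)
  spawn <- NULL
  if (iteration - stem$last_spawn >= stem$spawn_period) {
    spawn <- make_cells(x = stem$position[1], y = stem$position[2],
                        z = if (dim == 3) stem$position[3] else NULL,
                        radius = cell_radius, state = "proliferating",
                        health = 1, generation = 0L, mutations = 0L)
    stem$last_spawn <- as.integer(iteration)
  }
  list(stem = stem, spawn = spawn)
}

#' Remove necrotic cells past the dissolution delay
#'
#' Necrotic cells dissolve (apoptosis/lysis) after a fixed number of
#' iterations; others are untouched.
#'
#' @param cells The population.
#' @param iteration Current iteration.
#' @param dissolution_delay Iterations a necrotic cell persists
#'   (\code{Inf} for never).
#' @return List: \code{cells} (survivors) and \code{removed} (count).
#' @export
dissolve_necrotic <- function(cells, iteration, dissolution_delay = 100) {
  gone <- cells$state == "necrotic" & !is.na(cells$necrosis_time) &
    (iteration - cells$necrosis_time) >= dissolution_delay
  out <- cells[!gone, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(cells)
  list(cells = out, removed = sum(gone))
}

#' @export
print.ava_cells <- function(x, ...) {
  tab <- table(factor(x$state, levels = cell_states()))
  cat(sprintf("Cell population: %d cells (%s)\n", nrow(x),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
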