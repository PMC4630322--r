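#' Discretized simulation domain
#'
#' Regular rectangular grid of nodes covering the physical extent, with a
#' boundary mask marking Dirichlet nodes. With \code{shape = "circle"} the
#' domain proper is the inscribed circle (sphere in 3-D): nodes on or outside
#' it, and all nodes on the array edge, are boundary nodes held at the
#' species' boundary value.
#'
#' @param n Integer vector of node counts per axis (length 2 or 3).
#' @param extent Physical extent per axis (cm); recycled to \code{length(n)}.
#' @param shape \code{"circle"} (inscribed circular/spherical domain, the
#'   default) or \code{"rect"} (all interior nodes active, edge nodes
#'   boundary).
#' @param radius Radius of the circular domain (cm); defaults to the
#'   inscribed radius \code{min(extent)/2} and may be smaller (nodes beyond
#'   it are Dirichlet boundary).
#' @return Object of class \code{"ava_grid"}: node counts, spacings, axis
#'   coordinates, center and domain radius, logical \code{interior} array,
#'   interior linear indices and neighbor index matrices.
#' @export
make_grid <- function(n = c(100, 100), extent = 0.4, shape = c("circle", "rect"),
                      radius = NULL) {
  shape <- match.arg(shape)
  n <- as.integer(n)
  dim <- length(n)
  if (!dim %in% c(2L, 3L)) stop("grid must be 2- or 3-dimensional")
  if (any(n < 5L)) stop("need at least 5 nodes per axis")
  extent <- rep_len(extent, dim)
  spacing <- extent / (n - 1)
  coords <- lapply(seq_len(dim), function(a) seq(0, extent[a], length.out = n[a]))
  center <- extent / 2
  if (is.null(radius)) radius <- min(extent) / 2
  if (radius > min(extent) / 2 + 1e-12)
    stop("domain radius cannot exceed the inscribed radius min(extent)/2")

  # logical interior mask
  edge <- vector("list", dim)
  for (a in seq_len(dim)) edge[[a]] <- coords[[a]] > 0 & coords[[a]] < extent[a]
  interior <- array(TRUE, dim = n)
  grids <- do.call(expand.grid, coords)   # column-major, matches array linear order
  if (shape == "circle") {
    d2 <- rowSums(sweep(as.matrix(grids), 2, center)^2)
    interior[] <- d2 < radius^2
  }
  for (a in seq_len(dim)) {
    ia <- slice.index(interior, a)
    interior <- interior & array(edge[[a]][ia], dim = n)
  }
  if (!any(interior)) stop("grid has no interior nodes")

  idx_int <- which(interior)
  strides <- cumprod(c(1L, n[-dim]))
  nbr <- lapply(seq_len(dim), function(a)
    cbind(minus = idx_int - strides[a], plus = idx_int + strides[a]))
  structure(list(n = n, dim = dim, extent = extent, spacing = spacing,
                 coords = coords, center = center, radius = radius,
                 shape = shape, interior = interior, idx_int = idx_int,
                 strides = strides, nbr = nbr),
            class = "ava_grid")
}

#' @export
print.ava_grid <- function(x, ...) {
  cat(sprintf("%d-D %s grid: %s nodes over %s cm (spacing %s cm), %d interior nodes\n",
              x$dim, x$shape, paste(x$n, collapse = "x"),
              paste(format(x$extent), collapse = "x"),
              paste(format(signif(x$spacing, 3)), collapse = "x"),
              length(x$idx_int)))
  invisible(x)
}

#' Default diffusion constants (cm^2/h)
#'
#' Experimentally based diffusion constants for the five species.
#' @return Named numeric vector over \code{\link{species_ids}}.
#' @export
diffusion_constants <- function() {
  c(oxygen = 5.94e-2, glucose = 1.52e-3, waste = 2.124e-3,
    growth_factor = 1e-6, growth_inhibitor = 1e-6)
}

#' Construct one species field
#'
#' @param species Species name (one of \code{\link{species_ids}}).
#' @param grid An \code{\link{make_grid}} object.
#' @param value Initial interior concentration (model-mM).
#' @param diffusion_constant D (cm^2/h).
#' @param boundary_value Dirichlet concentration (model-mM).
#' @return Object of class \code{"ava_field"}.
#' @export
species_field <- function(species, grid, value, diffusion_constant, boundary_value) {
  vals <- array(boundary_value, dim = grid$n)
  vals[grid$idx_int] <- value
  structure(list(species = species, values = vals,
                 diffusion_constant = diffusion_constant,
                 boundary_value = boundary_value,
                 clamped_mass = 0),
            class = "ava_field")
}

#' Initialize all five species fields
#'
#' Every node of each field is set to that species' initial constant
#' (defaulting to its boundary value); boundary nodes carry the boundary
#' value.
#'
#' @param grid An \code{\link{make_grid}} object.
#' @param bc A \code{\link{boundary_conditions}} object.
#' @param D Named diffusion constants; default \code{\link{diffusion_constants}}.
#' @return Named list of \code{"ava_field"} objects.
#' @export
initialize_fields <- function(grid, bc = boundary_conditions(), D = diffusion_constants()) {
  stats::setNames(lapply(species_ids(), function(sp)
    species_field(sp, grid, bc$initial[[sp]], D[[sp]], bc$boundary[[sp]])),
    species_ids())
}

# discrete Laplacian at the interior nodes (vector over idx_int)
laplacian_interior <- function(values, grid) {
  lap <- 0
  ci <- values[grid$idx_int]
  for (a in seq_len(grid$dim)) {
    nb <- grid$nbr[[a]]
    lap <- lap + (values[nb[, 1L]] + values[nb[, 2L]] - 2 * ci) / grid$spacing[a]^2
  }
  lap
}

#' Largest stable explicit time step for a diffusion constant
#' @param grid An \code{"ava_grid"}.
#' @param D Diffusion constant (cm^2/h).
#' @return Stable dt (h): \code{1 / (2 D sum(1/h_a^2))}.
#' @export
stable_dt <- function(grid, D) {
  if (D <= 0) return(Inf)
  1 / (2 * D * sum(1 / grid$spacing^2))
}

#' Pre-factorized backward-Euler diffusion solver
#'
#' Assembles and Cholesky-factorizes the implicit operator
#' \code{I + dt D L_h} over the interior nodes once, for repeated use at a
#' fixed step size. Dirichlet boundary values enter the right-hand side.
#'
#' @param grid An \code{"ava_grid"}.
#' @param D Diffusion constant (cm^2/h).
#' @param dt Time step (h).
#' @return A solver object (list) consumed by \code{\link{diffusion_step}}.
#' @export
make_diffusion_solver <- function(grid, D, dt) {
  nint <- length(grid$idx_int)
  row_of <- array(NA_integer_, dim = grid$n)
  row_of[grid$idx_int] <- seq_len(nint)
  ii <- seq_len(nint)
  is <- ii; js <- ii
  xs <- rep(1, nint)
  bcoef <- numeric(nint)   # sum over boundary neighbors of 1/h^2
  diag_add <- numeric(nint)
  for (a in seq_len(grid$dim)) {
    w <- 1 / grid$spacing[a]^2
    for (side in 1:2) {
      nb <- grid$nbr[[a]][, side]
      r <- row_of[nb]
      inb <- !is.na(r)
      is <- c(is, ii[inb]); js <- c(js, r[inb]); xs <- c(xs, rep(-dt * D * w, sum(inb)))
      bcoef[!inb] <- bcoef[!inb] + w
      diag_add <- diag_add + w
    }
  }
  A <- Matrix::sparseMatrix(i = c(is), j = c(js),
                            x = c(xs[seq_len(nint)] + dt * D * diag_add, xs[-seq_len(nint)]),
                            dims = c(nint, nint))
  fac <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"), LDL = FALSE)
  list(fac = fac, bcoef = bcoef, D = D, dt = dt, n = grid$n, idx_int = grid$idx_int)
}

#' One diffusion time step
#'
#' Advances one species field by \code{dt} under
#' \eqn{\partial C/\partial t = D \nabla^2 C + Q} with Dirichlet boundary
#' values re-imposed and negative concentrations clamped to zero (the clamped
#' mass is accumulated on the field). The explicit scheme sub-cycles
#' automatically when \code{dt} exceeds the stability limit
#' \code{spacing^2/(2 dim D)}; with \code{subcycle = FALSE} an unstable step
#' is refused. The implicit scheme (backward Euler) takes the full step
#' unconditionally and requires a pre-built solver from
#' \code{\link{make_diffusion_solver}}.
#'
#' @param field An \code{"ava_field"}.
#' @param source Source array (model-mM per hour) of the grid's dimensions,
#'   or NULL for none.
#' @param dt Time step (h).
#' @param grid The \code{"ava_grid"} the field lives on.
#' @param method \code{"explicit"} or \code{"implicit"}.
#' @param subcycle Allow explicit sub-cycling (default TRUE).
#' @param solver Solver from \code{\link{make_diffusion_solver}} (implicit).
#' @return The advanced \code{"ava_field"}.
#' @export
diffusion_step <- function(field, source = NULL, dt, grid,
                           method = c("explicit", "implicit"),
                           subcycle = TRUE, solver = NULL) {
  method <- match.arg(method)
  if (dt <= 0) stop("dt must be positive")
  D <- field$diffusion_constant
  vals <- field$values
  qi <- if (is.null(source)) 0 else source[grid$idx_int]
  if (method == "explicit") {
    dts <- stable_dt(grid, D)
    if (dt > dts && !subcycle)
      stop(sprintf("explicit step dt = %g exceeds stability limit %g and sub-cycling is disabled",
                   dt, dts))
    nsub <- max(1L, ceiling(dt / dts))
    h <- dt / nsub
    for (k in seq_len(nsub)) {
      new_int <- vals[grid$idx_int] + h * (D * laplacian_interior(vals, grid) + qi)
      neg <- new_int < 0
      if (any(neg)) {
        field$clamped_mass <- field$clamped_mass - sum(new_int[neg])
        new_int[neg] <- 0
      }
      vals[grid$idx_int] <- new_int
    }
  } else {
    if (is.null(solver)) solver <- make_diffusion_solver(grid, D, dt)
    rhs <- vals[grid$idx_int] + dt * qi + dt * D * solver$bcoef * field$boundary_value
    new_int <- as.numeric(Matrix::solve(solver$fac, rhs))
    neg <- new_int < 0
    if (any(neg)) {
      field$clamped_mass <- field$clamped_mass - sum(new_int[neg])
      new_int[neg] <- 0
    }
    vals[grid$idx_int] <- new_int
  }
  # Dirichlet values re-imposed on every non-interior node
  vals[-grid$idx_int] <- field$boundary_value
  field$values <- vals
  field
}

# fractional node coordinates of physical positions; errors outside the domain
.pos_to_frac <- function(position, grid) {
  position <- rbind(position)
  if (ncol(position) != grid$dim)
    stop("position dimensionality does not match the grid")
  for (a in seq_len(grid$dim))
    if (any(position[, a] < 0 | position[, a] > grid$extent[a]))
      stop("position outside the computational domain")
  if (grid$shape == "circle") {
    d2 <- rowSums(sweep(position, 2, grid$center)^2)
    if (any(d2 > grid$radius^2 * (1 + 1e-9)))
      stop("position outside the circular domain")
  }
  sweep(position, 2, grid$spacing, "/")
}

# multilinear interpolation of an array at fractional coordinates (matrix)
.interp_array <- function(values, frac, grid) {
  np <- nrow(frac)
  i0 <- pmin(pmax(floor(frac), 0), matrix(grid$n - 2, np, grid$dim, byrow = TRUE))
  tt <- frac - i0
  out <- numeric(np)
  for (corner in 0:(2^grid$dim - 1)) {
    bits <- as.integer(intToBits(corner))[seq_len(grid$dim)]
    idx <- 1 + (i0 + matrix(bits, np, grid$dim, byrow = TRUE)) %*% grid$strides
    w <- rep(1, np)
    for (a in seq_len(grid$dim))
      w <- w * if (bits[a] == 1L) tt[, a] else 1 - tt[, a]
    out <- out + w * values[idx]
  }
  as.numeric(out)
}

#' Sample a field at off-lattice positions
#'
#' Multilinear interpolation of the node values at continuous positions.
#'
#' @param field An \code{"ava_field"}.
#' @param position Numeric vector (one point) or matrix (points x dim), cm.
#' @param grid The grid the field lives on.
#' @return Numeric vector of concentrations (model-mM).
#' @export
sample_concentration <- function(field, position, grid) {
  .interp_array(field$values, .pos_to_frac(position, grid), grid)
}

#' Sample a field gradient at off-lattice positions
#'
#' Central-difference nodal gradients (one-sided on the array edge),
#' multilinearly interpolated to the positions.
#'
#' @inheritParams sample_concentration
#' @return Matrix (points x dim) of gradient components (model-mM per cm).
#' @export
sample_gradient <- function(field, position, grid) {
  frac <- .pos_to_frac(position, grid)
  out <- matrix(0, nrow(frac), grid$dim)
  for (a in seq_len(grid$dim)) {
    g <- .axis_gradient(field$values, a, grid)
    out[, a] <- .interp_array(g, frac, grid)
  }
  out
}

# nodal derivative of an array along axis a
.axis_gradient <- function(values, a, grid) {
  n <- grid$n; h <- grid$spacing[a]
  idx_lo <- slice.index(values, a) == 1L
  idx_hi <- slice.index(values, a) == n[a]
  s <- grid$strides[a]
  g <- array(0, dim = n)
  mid <- !(idx_lo | idx_hi)
  wm <- which(mid)
  g[wm] <- (values[wm + s] - values[wm - s]) / (2 * h)
  wl <- which(idx_lo); wh <- which(idx_hi)
  g[wl] <- (values[wl + s] - values[wl]) / h
  g[wh] <- (values[wh] - values[wh - s]) / h
  g
}

#' Write field snapshots to CSV
#'
#' One row per grid node: node index, coordinates, one column per species.
#'
#' @param fields Named list of \code{"ava_field"} objects.
#' @param grid The grid.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_fields_csv <- function(fields, grid, file) {
  co <- do.call(expand.grid, grid$coords)
  names(co) <- c("x", "y", "z")[seq_len(grid$dim)]
  df <- data.frame(node = seq_len(prod(grid$n)), co)
  for (sp in names(fields)) df[[sp]] <- as.numeric(fields[[sp]]$values)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
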