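#' State-dependent spring (adhesion) constants
#'
#' Differential-adhesion spring stiffnesses per contact type. Pairs involving
#' a necrotic cell carry no spring. The neighbor cutoff is a multiple of the
#' summed radii.
#'
#' @param k_pp,k_pq,k_qq Stiffness for proliferating-proliferating,
#'   proliferating-quiescent and quiescent-quiescent contacts (force per
#'   distance, model units).
#' @param cutoff Neighbor cutoff as a multiple of the summed radii (>= 1).
#' @return Named list of class \code{"ava_springs"}.
#' @export
spring_constants <- function(k_pp = 1.0, k_pq = 0.5, k_qq = 0.25, cutoff = 1.2) {
  if (any(c(k_pp, k_pq, k_qq) < 0)) stop("spring constants must be non-negative")
  if (cutoff < 1) stop("cutoff must be at least 1 (touching distance)")
  structure(list(k_pp = k_pp, k_pq = k_pq, k_qq = k_qq, cutoff = cutoff),
            class = "ava_springs")
}

#' Chemotaxis weights
#'
#' Positive weights on the oxygen, glucose and waste gradients in the
#' nutrient-waste direction function m = alpha grad C_O + beta grad C_G -
#' gamma grad C_W.
#'
#' @param alpha,beta,gamma Positive weights (oxygen, glucose, waste).
#' @return Named list of class \code{"ava_chemo"}.
#' @export
chemotaxis_weights <- function(alpha = 1, beta = 1, gamma = 0.5) {
  if (any(c(alpha, beta, gamma) <= 0)) stop("chemotaxis weights must be positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma), class = "ava_chemo")
}

#' All close pairs via uniform spatial hashing
#'
#' Buckets positions on a uniform grid of the cutoff width and enumerates
#' candidate pairs from the 3^dim neighboring buckets; exact distances are
#' then filtered. Equivalent to the O(n^2) pair list.
#'
#' @param pos Position matrix (points x dim).
#' @param cutoff Maximum center distance to report.
#' @return List with integer vectors \code{i}, \code{j} (i < j) and distances
#'   \code{d}.
#' @export
neighbor_pairs <- function(pos, cutoff) {
  n <- nrow(pos)
  empty <- list(i = integer(), j = integer(), d = numeric())
  if (n < 2L) return(empty)
  d <- ncol(pos)
  cidx <- floor(sweep(pos, 2, cutoff, "/"))
  cidx <- sweep(cidx, 2, apply(cidx, 2, min))        # non-negative
  rng <- apply(cidx, 2, max) + 3                     # collision-free strides
  strides <- cumprod(c(1, rng[-d]))
  key <- as.numeric(cidx %*% strides)
  uk <- unique(key)
  bucket_of <- match(key, uk)
  buckets <- split(seq_len(n), bucket_of)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  ii <- integer(0); jj <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nkey <- key + as.numeric(offs[r, , drop = FALSE] %*% strides)
    b2 <- match(nkey, uk)
    has <- which(!is.na(b2))
    if (!length(has)) next
    cand <- buckets[b2[has]]
    cnt <- lengths(cand)
    ii <- c(ii, rep.int(has, cnt))
    jj <- c(jj, unlist(cand, use.names = FALSE))
  }
  keep <- jj > ii
  ii <- ii[keep]; jj <- jj[keep]
  if (!length(ii)) return(empty)
  dd <- sqrt(rowSums((pos[ii, , drop = FALSE] - pos[jj, , drop = FALSE])^2))
  keep <- dd <= cutoff
  list(i = ii[keep], j = jj[keep], d = dd[keep])
}

# scatter-accumulate equal-and-opposite pair contributions into an n x dim
# matrix: +val rows at i, -val rows at j
.accumulate_pairs <- function(n, i, j, val) {
  out <- matrix(0, n, ncol(val))
  acc <- rowsum(rbind(val, -val), group = c(i, j))
  out[as.integer(rownames(acc)), ] <- acc
  out
}

# per-pair spring stiffness from the two states; necrotic pairs get 0
.pair_stiffness <- function(si, sj, springs) {
  k <- numeric(length(si))
  nec <- si == "necrotic" | sj == "necrotic"
  both_p <- si == "proliferating" & sj == "proliferating"
  both_q <- si == "quiescent" & sj == "quiescent"
  k[both_p] <- springs$k_pp
  k[both_q] <- springs$k_qq
  k[!nec & !both_p & !both_q] <- springs$k_pq
  k
}

#' Pairwise spring adhesion forces
#'
#' Every non-necrotic pair of separated neighbors within the cutoff attracts
#' along the center line with Hooke magnitude k d, giving the vector force
#' k (x_j - x_i) on cell i. Pairs already in contact or overlapping
#' (d below the summed radii) carry no spring: the incompressibility
#' projection (\code{\link{resolve_overlaps}}) owns that regime, and pulling
#' overlapping incompressible bodies together would only fight it. Forces
#' are equal and opposite, so they sum to zero over the population.
#'
#' @param cells The population.
#' @param springs A \code{\link{spring_constants}} object.
#' @return Force matrix (cells x dim).
#' @export
adhesion_forces <- function(cells, springs = spring_constants()) {
  pos <- cell_positions(cells)
  n <- nrow(pos)
  F <- matrix(0, n, ncol(pos))
  if (n < 2L) return(F)
  cutoff <- springs$cutoff * 2 * max(cells$radius)
  pr <- neighbor_pairs(pos, cutoff)
  touch <- cells$radius[pr$i] + cells$radius[pr$j]
  keep <- pr$d <= springs$cutoff * touch & pr$d >= touch
  i <- pr$i[keep]; j <- pr$j[keep]
  if (!length(i)) return(F)
  k <- .pair_stiffness(cells$state[i], cells$state[j], springs)
  dx <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
  .accumulate_pairs(n, i, j, dx * k)   # k * d along the unit center line
}

#' Chemotaxis direction vector
#'
#' The nutrient-waste function m = alpha grad C_O + beta grad C_G -
#' gamma grad C_W sampled at off-lattice positions. Only proliferating cells
#' respond to it; quiescent and necrotic cells are unaffected by taxis.
#'
#' @param position Position vector or matrix (cm).
#' @param fields Named list of species fields (needs oxygen, glucose, waste).
#' @param weights A \code{\link{chemotaxis_weights}} object.
#' @param grid The grid.
#' @return Matrix (points x dim) of direction components.
#' @export
chemotaxis_vector <- function(position, fields, weights = chemotaxis_weights(), grid) {
  weights$alpha * sample_gradient(fields$oxygen, position, grid) +
    weights$beta * sample_gradient(fields$glucose, position, grid) -
    weights$gamma * sample_gradient(fields$waste, position, grid)
}

#' Resolve pairwise overlaps (incompressibility)
#'
#' Iterative pairwise projection: each overlapping pair is pushed apart along
#' the center line, each cell moving half the overlap; coincident centers are
#' separated along a random direction. Terminates when the maximum overlap is
#' below \code{tol} times the radius or the iteration cap is reached (a
#' warning is logged; the state stays valid). Positions are kept inside the
#' domain.
#'
#' @param cells The population.
#' @param grid The domain grid.
#' @param tol Overlap tolerance as a fraction of the (minimum pair) radius.
#' @param max_iter Projection sweep cap.
#' @param relax Over-relaxation factor on the projection corrections
#'   (1 = plain projection, exact for an isolated pair; values up to ~1.8
#'   speed convergence in dense packings at the cost of slight
#'   over-separation).
#' @return The population with adjusted positions.
#' @export
resolve_overlaps <- function(cells, grid, tol = 0.01, max_iter = 50L,
                             relax = 1) {
  n <- nrow(cells)
  if (n < 2L) return(cells)
  pos <- cell_positions(cells)
  dim <- ncol(pos)
  rad <- cells$radius
  cutoff <- 2 * max(rad)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pr <- neighbor_pairs(pos, cutoff)
    keep <- logical(0)
    if (length(pr$i)) {
      ov <- rad[pr$i] + rad[pr$j] - pr$d
      keep <- ov > tol * pmin(rad[pr$i], rad[pr$j])
    }
    if (!any(keep)) { converged <- TRUE; break }
    i <- pr$i[keep]; j <- pr$j[keep]
    touch <- rad[i] + rad[j]
    dx <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
    dd <- sqrt(rowSums(dx^2))
    zero <- dd < 1e-12
    u <- dx / pmax(dd, 1e-300)
    if (any(zero)) {                 # coincident: random separation direction
      rd <- matrix(stats::rnorm(sum(zero) * dim), ncol = dim)
      u[zero, ] <- rd / sqrt(rowSums(rd^2))
    }
    push <- relax * (touch - pmin(dd, touch)) / 2
    shift <- u * push
    pos <- pos + .accumulate_pairs(n, i, j, -shift)
    pos <- .clamp_positions(pos, rad, grid)
  }
  if (!converged)
    warning("overlap resolution hit the iteration cap; residual overlaps remain")
  .set_positions(cells, pos)
}

# keep every position inside the domain (radial clamp for circular domains)
.clamp_positions <- function(pos, rad, grid) {
  if (grid$shape == "circle") {
    v <- sweep(pos, 2, grid$center)
    r <- sqrt(rowSums(v^2))
    rmax <- grid$radius - rad
    out <- r > rmax & r > 0
    if (any(out)) {
      scale <- rmax[out] / r[out]
      pos[out, ] <- sweep(v[out, , drop = FALSE] * scale, 2, grid$center, "+")
    }
  }
  for (a in seq_len(ncol(pos)))
    pos[, a] <- pmin(pmax(pos[, a], rad), grid$extent[a] - rad)
  pos
}

#' Overdamped motion integration
#'
#' First-order (viscosity-dominated) update: displacement = mobility x net
#' force x dt, followed by overlap resolution and domain clamping.
#'
#' @param cells The population.
#' @param forces Net force matrix (cells x dim).
#' @param dt Time step (h).
#' @param mobility Mobility coefficient (displacement per force per h).
#' @param grid The domain grid.
#' @param resolve Run \code{\link{resolve_overlaps}} afterwards (default TRUE).
#' @return The moved population.
#' @export
integrate_motion <- function(cells, forces, dt = 1, mobility = 0.5, grid,
                             resolve = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  if (!nrow(cells)) return(cells)
  pos <- cell_positions(cells) + mobility * forces * dt
  pos <- .clamp_positions(pos, cells$radius, grid)
  cells <- .set_positions(cells, pos)
  if (resolve) cells <- resolve_overlaps(cells, grid)
  cells
}
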