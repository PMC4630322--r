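.pair_cells <- function(d, states = c("proliferating", "proliferating"),
                        radius = 0.001) {
  make_cells(x = c(0.2, 0.2 + d), y = c(0.2, 0.2), radius = radius,
             state = states, health = 1)
}

test_that("spatial-hash neighbor search agrees with the O(n^2) pair list", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 150
    pos <- cbind(runif(n, 0, 0.1), runif(n, 0, 0.1))
    cutoff <- 0.008
    pr <- neighbor_pairs(pos, cutoff)
    dm <- as.matrix(dist(pos))
    oracle <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
    got <- paste(pr$i, pr$j)
    want <- paste(oracle[, 1], oracle[, 2])
    expect_setequal(got, want)
    expect_equal(pr$d, dm[cbind(pr$i, pr$j)], tolerance = 1e-12)
  }
})

test_that("adhesion forces obey Newton's third law and the necrotic exclusion", {
  springs <- spring_constants()
  # separated P-P pair inside the cutoff: equal and opposite, magnitude k d
  d <- 0.0022
  F <- adhesion_forces(.pair_cells(d), springs)
  expect_equal(F[1, ], -F[2, ])
  expect_equal(sqrt(sum(F[1, ]^2)), springs$k_pp * d)
  expect_gt(F[1, 1], 0)   # attraction: first cell pulled toward the second
  # necrotic-quiescent pair: no spring
  Fn <- adhesion_forces(.pair_cells(d, c("necrotic", "quiescent")), springs)
  expect_equal(Fn, matrix(0, 2, 2))
  # coincident centers: zero force, no NaN
  F0 <- adhesion_forces(.pair_cells(0), springs)
  expect_equal(F0, matrix(0, 2, 2))
})

test_that("adhesion forces sum to zero over a random population (momentum audit)", {
  set.seed(22)
  cells <- make_cells(x = runif(80, 0.18, 0.22), y = runif(80, 0.18, 0.22),
                      state = sample(cell_states(), 80, replace = TRUE),
                      health = 1)
  F <- adhesion_forces(cells)
  expect_equal(colSums(F), c(0, 0), tolerance = 1e-15)
})

test_that("state-dependent stiffness selects the right constant per pair", {
  springs <- spring_constants(k_pp = 2, k_pq = 1, k_qq = 0.5)
  d <- 0.0021
  mag <- function(st) {
    F <- adhesion_forces(.pair_cells(d, st), springs)
    sqrt(sum(F[1, ]^2))
  }
  expect_equal(mag(c("proliferating", "proliferating")), 2 * d)
  expect_equal(mag(c("proliferating", "quiescent")), 1 * d)
  expect_equal(mag(c("quiescent", "proliferating")), 1 * d)   # symmetric
  expect_equal(mag(c("quiescent", "quiescent")), 0.5 * d)
})

test_that("chemotaxis vector composes weighted gradients with the waste sign flipped", {
  g <- make_grid(c(21, 21), 0.1, shape = "rect")
  co <- do.call(expand.grid, g$coords)
  mk_ramp <- function(slope) {
    f <- species_field("oxygen", g, 0, 0.01, 0)
    f$values[] <- 1 + slope * co[[1]]
    f
  }
  fields <- list(oxygen = mk_ramp(1), glucose = mk_ramp(1), waste = mk_ramp(1))
  w <- chemotaxis_weights(alpha = 1, beta = 1, gamma = 1)
  p <- rbind(c(0.05, 0.05))
  m <- chemotaxis_vector(p, fields, w, g)
  expect_equal(m, matrix(c(1 + 1 - 1, 0), 1, 2), tolerance = 1e-10)
  # uniform fields: zero vector
  fu <- list(oxygen = mk_ramp(0), glucose = mk_ramp(0), waste = mk_ramp(0))
  expect_equal(chemotaxis_vector(p, fu, w, g), matrix(0, 1, 2))
  # pure waste ramp: anti-parallel to the ramp
  fw <- list(oxygen = mk_ramp(0), glucose = mk_ramp(0), waste = mk_ramp(2))
  mw <- chemotaxis_vector(p, fw, w, g)
  expect_lt(mw[1, 1], 0)
})

test_that("two coincident cells are separated to exactly touching with midpoint preserved", {
  g <- make_grid(c(30, 30), 0.4)
  set.seed(23)
  cells <- make_cells(x = c(0.2, 0.2), y = c(0.2, 0.2), radius = 0.001)
  out <- resolve_overlaps(cells, g)
  pos <- cell_positions(out)
  expect_equal(sqrt(sum((pos[1, ] - pos[2, ])^2)), 0.002, tolerance = 1e-12)
  expect_equal(unname(colMeans(pos)), c(0.2, 0.2), tolerance = 1e-12)
})

test_that("non-overlapping configurations pass through overlap resolution unchanged", {
  g <- make_grid(c(30, 30), 0.4)
  cells <- make_cells(x = c(0.18, 0.2, 0.22), y = rep(0.2, 3), radius = 0.001)
  out <- resolve_overlaps(cells, g)
  expect_equal(cell_positions(out), cell_positions(cells))
})

test_that("a dense random cluster resolves below tolerance (all-pairs oracle)", {
  g <- make_grid(c(50, 50), 0.4)
  set.seed(24)
  n <- 120
  cells <- make_cells(x = runif(n, 0.195, 0.205), y = runif(n, 0.195, 0.205),
                      radius = 0.001)
  out <- suppressWarnings(resolve_overlaps(cells, g, tol = 0.01, max_iter = 500))
  dm <- as.matrix(dist(cell_positions(out)))     # brute-force all-pairs check
  overlap <- 0.002 - dm[upper.tri(dm)]
  expect_lt(max(overlap), 0.01 * 0.001 + 1e-9)
  # resolution never increases the maximum pairwise overlap
  dm0 <- as.matrix(dist(cell_positions(cells)))
  expect_lte(max(0.002 - dm[upper.tri(dm)]), max(0.002 - dm0[upper.tri(dm0)]))
})

test_that("motion integration is overdamped and clamps cells inside the domain", {
  g <- make_grid(c(30, 30), 0.4)
  cells <- make_cells(x = 0.2, y = 0.2, radius = 0.001)
  # zero force: unchanged
  out <- integrate_motion(cells, matrix(0, 1, 2), dt = 1, mobility = 0.1, g)
  expect_equal(cell_positions(out), cell_positions(cells))
  # displacement linear in dt and mobility
  Fm <- matrix(c(0.01, 0), 1, 2)
  d1 <- cell_positions(integrate_motion(cells, Fm, 1, 0.1, g))[1, 1] - 0.2
  d2 <- cell_positions(integrate_motion(cells, Fm, 2, 0.1, g))[1, 1] - 0.2
  d3 <- cell_positions(integrate_motion(cells, Fm, 1, 0.2, g))[1, 1] - 0.2
  expect_equal(d2, 2 * d1)
  expect_equal(d3, 2 * d1)
  # a huge force cannot push the cell out of the domain
  big <- matrix(c(1e6, 0), 1, 2)
  out2 <- integrate_motion(cells, big, 1, 1, g)
  p <- cell_positions(out2)
  expect_lte(sqrt(sum((p - g$center)^2)), g$radius - 0.001 + 1e-12)
})

test_that("a two-cell spring relaxes along the closed-form overdamped solution", {
  # point-like cells (tiny radius) so the spring acts down to contact:
  # d(t) = d0 exp(-2 mobility k t), from dx/dt = -2 mobility k x per gap
  g <- make_grid(c(30, 30), 0.4)
  k <- 0.8; mob <- 0.05; d0 <- 0.01
  cells <- make_cells(x = c(0.2, 0.2 + d0), y = c(0.2, 0.2), radius = 1e-6,
                      state = "proliferating")
  springs <- spring_constants(k_pp = k, cutoff = 1e5)  # pair always in range
  dt <- 0.01
  nst <- 200
  for (s in seq_len(nst)) {
    F <- adhesion_forces(cells, springs)
    cells <- integrate_motion(cells, F, dt, mob, g, resolve = FALSE)
  }
  d_num <- diff(cell_positions(cells)[, 1])
  d_exact <- d0 * exp(-2 * mob * k * nst * dt)
  expect_equal(d_num, d_exact, tolerance = 0.01)
})

test_that("no cell leaves the domain through repeated force integration", {
  g <- make_grid(c(30, 30), 0.4)
  set.seed(25)
  cells <- make_cells(x = runif(40, 0.1, 0.3), y = runif(40, 0.1, 0.3),
                      radius = 0.001, state = "proliferating")
  for (s in 1:30) {
    F <- matrix(rnorm(80, sd = 0.05), 40, 2)
    cells <- suppressWarnings(integrate_motion(cells, F, 1, 0.5, g))
    d <- sqrt(rowSums(sweep(cell_positions(cells), 2, g$center)^2))
    expect_true(all(d <= g$radius - 0.001 + 1e-9))
  }
})
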