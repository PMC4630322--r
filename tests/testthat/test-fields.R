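# small rectangular test grid: every edge node is Dirichlet, interior regular
.test_grid <- function(n = 15, extent = 0.1, dim = 2) {
  make_grid(rep(n, dim), extent, shape = "rect")
}

test_that("a uniform field at the boundary value is a steady state", {
  g <- .test_grid()
  f <- species_field("oxygen", g, value = 0.00053, diffusion_constant = 0.0594,
                     boundary_value = 0.00053)
  f2 <- diffusion_step(f, NULL, dt = 1, g, method = "explicit")
  expect_equal(f2$values, f$values, tolerance = 1e-14)
  f3 <- diffusion_step(f, NULL, dt = 1, g, method = "implicit")
  expect_equal(f3$values, f$values, tolerance = 1e-12)
})

test_that("zero diffusion leaves the field unchanged", {
  g <- .test_grid()
  set.seed(1)
  f <- species_field("waste", g, value = 0, diffusion_constant = 0,
                     boundary_value = 0)
  f$values[g$idx_int] <- runif(length(g$idx_int))
  f2 <- diffusion_step(f, NULL, dt = 1, g, method = "explicit")
  expect_equal(f2$values, f$values)
})

test_that("an unstable explicit step is refused when sub-cycling is disabled", {
  g <- .test_grid()
  f <- species_field("oxygen", g, 0.5, 0.0594, 0.5)
  expect_gt(1, stable_dt(g, 0.0594))  # dt = 1 really is unstable here
  expect_error(diffusion_step(f, NULL, dt = 1, g, method = "explicit",
                              subcycle = FALSE), "stability")
  expect_s3_class(diffusion_step(f, NULL, dt = stable_dt(g, 0.0594) / 2, g,
                                 method = "explicit", subcycle = FALSE),
                  "ava_field")
})

test_that("point-sink steady state matches an independent Jacobi relaxation oracle", {
  g <- .test_grid(n = 13, extent = 0.012)
  D <- 1.52e-3
  b <- 1
  src <- array(0, g$n)
  src[7, 7] <- -40      # point sink, mild enough to stay positive
  # independent oracle: Jacobi relaxation of the discrete Poisson problem
  h <- g$spacing[1]
  C <- array(b, g$n)
  for (k in 1:30000) {
    Cn <- C
    i <- 2:(g$n[1] - 1); j <- 2:(g$n[2] - 1)
    Cn[i, j] <- (C[i - 1, j] + C[i + 1, j] + C[i, j - 1] + C[i, j + 1] +
                   h^2 * src[i, j] / D) / 4
    if (max(abs(Cn - C)) < 1e-14) { C <- Cn; break }
    C <- Cn
  }
  # package path: time-step the diffusion equation to stationarity
  f <- species_field("glucose", g, b, D, b)
  s <- make_diffusion_solver(g, D, dt = 50)
  for (k in 1:400) f <- diffusion_step(f, src, dt = 50, g, "implicit", solver = s)
  expect_lt(max(abs(f$values - C)), 1e-8)
  expect_true(all(f$values >= 0))
})

test_that("interior mass change equals the independently computed boundary flux", {
  g <- .test_grid(n = 21, extent = 0.1)
  D <- 2.124e-3
  set.seed(7)
  f <- species_field("waste", g, 0, D, 0.3)
  f$values[g$idx_int] <- runif(length(g$idx_int), 0.2, 0.8)
  dt <- stable_dt(g, D) / 4
  before <- f$values
  f2 <- diffusion_step(f, NULL, dt, g, "explicit", subcycle = FALSE)
  expect_equal(f2$clamped_mass, 0)
  h2 <- prod(g$spacing)
  mass_change <- sum((f2$values - before)[g$idx_int]) * h2
  # independent flux audit over interior-boundary links of the pre-step field
  flux <- 0
  for (a in 1:2) {
    s <- g$strides[a]
    for (nb in c(-s, s)) {
      bdry <- !g$interior[g$idx_int + nb]
      ii <- g$idx_int[bdry]
      flux <- flux + sum(before[ii + nb] - before[ii]) / g$spacing[a]^2
    }
  }
  # interior-interior links cancel pairwise, so the Laplacian sum telescopes
  # to the boundary-link flux
  expect_equal(mass_change, dt * D * flux * h2, tolerance = 1e-10)
})

test_that("the diffusion step is linear in field and source (superposition)", {
  g <- .test_grid(n = 11, extent = 0.05)
  D <- 1e-3
  set.seed(11)
  mk <- function(bv) {
    f <- species_field("oxygen", g, bv, D, bv)
    f$values[g$idx_int] <- runif(length(g$idx_int), 0.5, 1.5) * max(bv, 0.5)
    f
  }
  f1 <- mk(0.4); f2 <- mk(0.7)
  s1 <- array(runif(prod(g$n), 0, 0.1), g$n)
  s2 <- array(runif(prod(g$n), 0, 0.1), g$n)
  fsum <- species_field("oxygen", g, 0, D, f1$boundary_value + f2$boundary_value)
  fsum$values <- f1$values + f2$values
  dt <- stable_dt(g, D) / 2
  a1 <- diffusion_step(f1, s1, dt, g, "explicit", subcycle = FALSE)
  a2 <- diffusion_step(f2, s2, dt, g, "explicit", subcycle = FALSE)
  asum <- diffusion_step(fsum, s1 + s2, dt, g, "explicit", subcycle = FALSE)
  expect_equal(asum$values, a1$values + a2$values, tolerance = 1e-12)
})

test_that("long integration under constant boundary relaxes to the uniform boundary value", {
  g <- .test_grid(n = 13, extent = 0.05)
  D <- 5.94e-2
  f <- species_field("oxygen", g, 0, D, 0.00053)   # start empty inside
  s <- make_diffusion_solver(g, D, dt = 1)
  for (k in 1:200) f <- diffusion_step(f, NULL, 1, g, "implicit", solver = s)
  expect_lt(max(abs(f$values - 0.00053)), 1e-6 * 0.00053)
})

test_that("field initialization honors boundary and initial constants", {
  g <- make_grid(c(30, 30), 0.4)
  fs <- initialize_fields(g)
  expect_named(fs, species_ids())
  expect_true(all(fs$oxygen$values == 0.00053))
  expect_true(all(fs$waste$values == 0))
  expect_equal(fs$glucose$diffusion_constant, 1.52e-3)
  # custom initial override
  fs2 <- initialize_fields(g, boundary_conditions(initial = c(oxygen = 2e-4)))
  expect_true(all(fs2$oxygen$values[g$idx_int] == 2e-4))
  expect_true(all(fs2$oxygen$values[!g$interior] == 0.00053))
})

test_that("sampling interpolates exactly on nodes, linear ramps and uniform fields", {
  g <- .test_grid(n = 21, extent = 0.1)
  set.seed(3)
  f <- species_field("oxygen", g, 0, 0.01, 0)
  f$values[] <- runif(prod(g$n))
  # at a grid node the sample equals the node value
  node <- c(5, 9)
  p_node <- c(g$coords[[1]][node[1]], g$coords[[2]][node[2]])
  expect_equal(sample_concentration(f, p_node, g), f$values[node[1], node[2]])
  # uniform field: zero gradient
  fu <- species_field("oxygen", g, 0.7, 0.01, 0.7)
  p <- rbind(c(0.033, 0.041), c(0.05, 0.05))
  expect_equal(sample_gradient(fu, p, g), matrix(0, 2, 2))
  # linear ramp: gradient equals the slope everywhere in the interior
  co <- do.call(expand.grid, g$coords)
  fr <- fu
  fr$values[] <- 2 * co[[1]] + 3 * co[[2]]
  expect_equal(sample_concentration(fr, p, g), 2 * p[, 1] + 3 * p[, 2])
  expect_equal(sample_gradient(fr, p, g),
               matrix(c(2, 2, 3, 3), 2, 2), tolerance = 1e-10)
  expect_error(sample_concentration(f, c(1, 1), g), "outside")
})
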