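.src_setup <- function(n = 50, extent = 0.4) {
  g <- make_grid(c(n, n), extent)
  list(grid = g, fields = initialize_fields(g))
}

test_that("an empty population deposits all-zero source terms", {
  s <- .src_setup()
  out <- deposit_sources(make_cells(), s$grid, s$fields)
  for (sp in species_ids()) expect_true(all(out$sources[[sp]] == 0))
  expect_equal(nrow(out$uptake), 0L)
})

test_that("a fully supplied proliferating cell sinks and sources at the table rates", {
  s <- .src_setup()
  cells <- make_cells(x = 0.2, y = 0.2, state = "proliferating", health = 2)
  out <- deposit_sources(cells, s$grid, s$fields, coupling = 1)
  expect_equal(sum(out$sources$oxygen), -108)
  expect_equal(sum(out$sources$glucose), -162)
  expect_equal(sum(out$sources$waste), 240)
  expect_equal(sum(out$sources$growth_factor), 1)
  expect_equal(sum(out$sources$growth_inhibitor), 0)
  # realized uptake and yield at full availability
  expect_equal(out$uptake$oxygen, 108)
  expect_equal(out$uptake$glucose, 162)
  expect_equal(out$yield$total, 828)
  expect_equal(out$activity, 1)
})

test_that("a necrotic cell only releases growth inhibitor, at rate 2", {
  s <- .src_setup()
  cells <- make_cells(x = 0.2, y = 0.2, state = "necrotic", health = 0.2,
                      necrosis_time = 1L)
  out <- deposit_sources(cells, s$grid, s$fields, coupling = 1)
  expect_true(all(out$sources$oxygen == 0))
  expect_true(all(out$sources$glucose == 0))
  expect_true(all(out$sources$waste == 0))
  expect_true(all(out$sources$growth_factor == 0))
  expect_equal(sum(out$sources$growth_inhibitor), 2)
  expect_true(all(out$sources$growth_inhibitor >= 0))
})

test_that("starved cells scale their uptake with local availability", {
  s <- .src_setup()
  # deplete the oxygen field to half the boundary value
  s$fields$oxygen$values[s$grid$idx_int] <- 0.00053 / 2
  cells <- make_cells(x = 0.2, y = 0.2, state = "quiescent", health = 1)
  out <- deposit_sources(cells, s$grid, s$fields, coupling = 1)
  expect_equal(sum(out$sources$oxygen), -50 * 0.5)
  expect_equal(sum(out$sources$glucose), -80)   # glucose still at boundary level
  # fully starved
  s$fields$oxygen$values[] <- 0
  s$fields$glucose$values[] <- 0
  out0 <- deposit_sources(cells, s$grid, s$fields, coupling = 1)
  expect_equal(sum(out0$sources$oxygen), 0)
  expect_equal(out0$yield$total, 0)
  expect_equal(out0$activity, 0)
  expect_equal(sum(out0$sources$waste), 0)      # no metabolism, no waste
})

test_that("deposits conserve each cell's total rate and avoid boundary nodes", {
  s <- .src_setup()
  set.seed(51)
  cells <- make_cells(x = runif(20, 0.15, 0.25), y = runif(20, 0.15, 0.25),
                      state = sample(c("proliferating", "quiescent"), 20, TRUE),
                      health = 1)
  out <- deposit_sources(cells, s$grid, s$fields, coupling = 1)
  rates <- metabolic_rate_table()
  expect_equal(sum(out$sources$oxygen), -sum(rates[cells$state, "oxygen"]))
  # nothing lands on Dirichlet nodes
  for (sp in species_ids())
    expect_true(all(out$sources[[sp]][!s$grid$interior] == 0))
  # coupling scales amplitudes linearly
  out2 <- deposit_sources(cells, s$grid, s$fields, coupling = 1e-5)
  expect_equal(out2$sources$oxygen, out$sources$oxygen * 1e-5)
})

test_that("a cell outside the domain is rejected", {
  s <- .src_setup()
  bad <- make_cells(x = 0.39, y = 0.39, state = "quiescent", health = 1)
  expect_error(deposit_sources(bad, s$grid, s$fields), "outside")
})

test_that("competitive uptake is stable, conservative and shares under crowding", {
  g <- make_grid(c(50, 50), 0.1)
  fields <- initialize_fields(g)
  rates <- metabolic_rate_table()
  # a single isolated cell realizes nearly its full glucose demand; oxygen
  # (whose boundary concentration is far lower) is partially limited, and
  # the anaerobic pathway compensates: the energy balance stays strongly
  # positive (well above the quiescent maintenance level H_Q)
  one <- make_cells(x = 0.05, y = 0.05, state = "proliferating", health = 2)
  up1 <- nutrient_uptake(one, g, fields, rates, coupling = 2e-5)
  expect_gt(up1$uptake$glucose, 0.75 * 162)
  expect_gt(up1$yield$total, 1.2 * 393.4)
  # sinks are non-positive, zero on boundary nodes, and conserve the
  # realized uptake mass (geometry factor included)
  expect_true(all(up1$sinks$oxygen <= 0))
  expect_true(all(up1$sinks$oxygen[!g$interior] == 0))
  geom <- pi * 0.001^2 / prod(g$spacing)
  expect_equal(sum(up1$sinks$oxygen),
               -up1$uptake$oxygen * 2e-5 * geom, tolerance = 1e-6)
  # a stack of cells at one spot shares the supply: per-cell yield drops
  many <- make_cells(x = rep(0.05, 30), y = rep(0.05, 30),
                     state = "proliferating", health = 2)
  upm <- nutrient_uptake(many, g, fields, rates, coupling = 2e-5)
  expect_lt(upm$yield$total[1], up1$yield$total)
  # total drain never exceeds what the nodes hold (no overdraw)
  drained <- -sum(upm$sinks$glucose)        # model-mM per hour over nodes
  stored <- sum(fields$glucose$values[g$idx_int])
  expect_lt(drained, stored)
  # iterating uptake+diffusion relaxes monotonically (no flip-flop)
  f2 <- fields
  solver <- make_diffusion_solver(g, f2$glucose$diffusion_constant, 1)
  act <- numeric(8)
  for (k in 1:8) {
    up <- nutrient_uptake(many, g, f2, rates, coupling = 2e-5)
    act[k] <- mean(up$activity)
    f2$glucose <- diffusion_step(f2$glucose, up$sinks$glucose, 1, g,
                                 "implicit", solver = solver)
  }
  expect_true(all(abs(diff(act)[-1]) <= abs(diff(act)[-length(act) + 1]) + 1e-9))
  expect_true(all(act > 0))
})

test_that("production sources scale with activity and the footprint ratio", {
  g <- make_grid(c(50, 50), 0.1)
  cells <- make_cells(x = c(0.05, 0.06), y = 0.05,
                      state = c("proliferating", "necrotic"),
                      necrosis_time = c(NA_integer_, 1L))
  geom <- pi * 0.001^2 / prod(g$spacing)
  prod_full <- production_sources(cells, g, activity = c(1, 0), coupling = 1)
  expect_equal(sum(prod_full$waste), 240 * geom)
  expect_equal(sum(prod_full$growth_inhibitor), 2 * geom)  # necrotic, unscaled
  prod_half <- production_sources(cells, g, activity = c(0.5, 0), coupling = 1)
  expect_equal(sum(prod_half$waste), 120 * geom)
  expect_equal(sum(prod_half$growth_inhibitor), 2 * geom)
})
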