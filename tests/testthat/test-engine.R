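# small, fast study configurations for engine behavior tests
.quick_cfg <- function(...) {
  # canonical physics (0.002 cm spacing) on a small domain for fast runs
  args <- utils::modifyList(
    list(grid_n = 30L, extent = 0.06, domain_radius = NULL,
         iterations = 25L, snapshot_interval = 5L),
    list(...))
  do.call(simulation_config, args)
}

test_that("a zero-iteration run yields only the initial state", {
  run <- run_simulation(.quick_cfg(iterations = 0L, seed = 2L))
  expect_equal(nrow(run$series), 0L)
  expect_named(run$snapshots, "0")
  expect_equal(nrow(run$snapshots[["0"]]), 1L)          # the founder
  expect_equal(run$snapshots[["0"]]$state, "proliferating")
  expect_true(all(run$fields$oxygen$values == 0.00053))  # untouched fields
  expect_true(all(run$fields$waste$values == 0))
})

test_that("identical configurations and seeds give byte-identical outputs", {
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  r1 <- suppressWarnings(run_simulation(.quick_cfg(seed = 7L, out_dir = d1)))
  r2 <- suppressWarnings(run_simulation(.quick_cfg(seed = 7L, out_dir = d2)))
  expect_identical(r1$series, r2$series)
  expect_identical(r1$cells, r2$cells)
  for (f in list.files(d1)) {
    if (f == "manifest.json") next
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     info = f)
  }
  # a different seed diverges
  r3 <- suppressWarnings(run_simulation(.quick_cfg(seed = 8L)))
  expect_false(identical(r1$cells, r3$cells))
})

test_that("the per-iteration ledger balances births, spawns and dissolutions exactly", {
  run <- suppressWarnings(run_simulation(.quick_cfg(seed = 3L, iterations = 40L)))
  lg <- run$ledger
  expect_equal(lg$n_after,
               lg$n_before + lg$births + lg$spawns - lg$removed)
  # continuity between iterations
  expect_equal(lg$n_before[-1], lg$n_after[-nrow(lg)])
})

test_that("no generation ever exceeds the Hayflick limit and cells stay in the domain", {
  run <- suppressWarnings(run_simulation(.quick_cfg(seed = 4L, iterations = 40L)))
  for (snap in run$snapshots) {
    expect_true(all(snap$generation <= 60L))
    d <- sqrt((snap$x - run$grid$center[1])^2 + (snap$y - run$grid$center[2])^2)
    expect_true(all(d <= run$grid$radius + 1e-12))
  }
})

test_that("a nutrient-rich environment sustains unchecked early growth", {
  cfg <- .quick_cfg(seed = 5L, iterations = 30L,
                    oxygen_boundary = 0.053, glucose_boundary = 0.5,
                    stem_enabled = FALSE)
  run <- suppressWarnings(run_simulation(cfg))
  s <- run$series
  living <- s$proliferating + s$quiescent
  expect_gt(living[30], 10)                       # population multiplied
  expect_true(all(diff(living) >= 0))             # no deaths, no shrinkage
  # growth trend is exponential-like once past the stochastic founder phase
  grow <- which(living >= 4)
  fit <- lm(log(living[grow]) ~ s$iteration[grow])
  expect_gt(summary(fit)$r.squared, 0.9)
  expect_gt(coef(fit)[2], 0)
  expect_equal(run$first_necrotic, NA_integer_)   # nobody starves in plenty
})

test_that("the quiescent region appears before any necrotic cell", {
  cfg <- .quick_cfg(seed = 6L, iterations = 90L, stem_enabled = FALSE)
  run <- suppressWarnings(run_simulation(cfg))
  expect_false(is.na(run$first_quiescent))
  expect_false(is.na(run$first_necrotic))
  expect_lt(run$first_quiescent, run$first_necrotic)
})

test_that("doubling the nutrient boundaries strictly increases the sustained population", {
  base <- suppressWarnings(run_simulation(.quick_cfg(seed = 9L, iterations = 80L,
                                                     stem_enabled = FALSE)))
  rich <- suppressWarnings(run_simulation(.quick_cfg(seed = 9L, iterations = 80L,
                                                     stem_enabled = FALSE,
                                                     oxygen_boundary = 2 * 0.00053,
                                                     glucose_boundary = 2 * 0.005)))
  tail_living <- function(r) {
    s <- utils::tail(r$series, 15)
    mean(s$proliferating + s$quiescent)
  }
  expect_gt(tail_living(rich), tail_living(base))
})

test_that("configurations validate their keys and reject unknown ones", {
  expect_error(simulation_config(dim = 4L))
  expect_error(simulation_config(dt = -1))
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(grid_n = 30, bogus_key = 1), tmp, auto_unbox = TRUE)
  expect_error(load_config(tmp), "unknown configuration keys")
  jsonlite::write_json(list(grid_n = 30, iterations = 5), tmp, auto_unbox = TRUE)
  cfg <- load_config(tmp)
  expect_equal(cfg$grid_n, 30)
  expect_equal(cfg$iterations, 5)
  expect_equal(cfg$dt, 1)   # defaults fill the rest
})

test_that("region analysis of a simulated snapshot reports ordered radii", {
  run <- suppressWarnings(run_simulation(.quick_cfg(seed = 10L, iterations = 60L,
                                                    stem_enabled = FALSE)))
  rg <- classify_regions(run$cells)
  r <- unlist(rg$radii)
  r <- r[!is.na(r)]
  expect_true(all(diff(r) >= -1e-12))   # monotone inside-out whenever present
})

test_that("the engine supports three-dimensional domains", {
  cfg <- simulation_config(dim = 3L, grid_n = 15L, extent = 0.03,
                           domain_radius = NULL, iterations = 8L, seed = 12L)
  run <- suppressWarnings(run_simulation(cfg))
  expect_true("z" %in% names(run$cells))
  p <- cell_positions(run$cells)
  expect_equal(ncol(p), 3L)
  d <- sqrt(rowSums(sweep(p, 2, run$grid$center)^2))
  expect_true(all(d <= run$grid$radius + 1e-12))
})
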