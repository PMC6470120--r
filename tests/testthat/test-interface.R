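write_yaml_config <- function(text) {
  f <- tempfile(fileext = ".yaml")
  writeLines(text, f)
  f
}

test_that("a minimal config loads with all defaults applied", {
  cfg <- load_config(write_yaml_config(
    "model:\n  curve:\n    form: constant\n    rho: 0.5"))
  expect_s3_class(cfg, "ciu_config")
  expect_identical(cfg$model$curve$form, "constant")
  expect_equal(cfg$model$curve$rho, 0.5)
  expect_equal(cfg$model$n_g1, 1)
  expect_identical(cfg$model$k_max, 1000L)
  expect_equal(cfg$model$mutation$mu, 0)
  expect_equal(cfg$model$efficiency$alpha, 1)
  expect_identical(cfg$seed, 0L)
  expect_identical(cfg$log_level, "info")
  expect_null(cfg$sweep)
})

test_that("config validation names the offending key path", {
  expect_error(load_config(write_yaml_config(
    "model:\n  curve:\n    form: constant\n    rho: 1.5")),
    "model.curve.*rho")
  expect_error(load_config(write_yaml_config(
    "model:\n  curve:\n    form: constant\n    rho: 0.5\n    wobble: 2")),
    "wobble")
  expect_error(load_config(write_yaml_config(
    "model:\n  curve:\n    form: constant\n    rho: 0.5\nextra: 1")),
    "extra")
  expect_error(load_config(write_yaml_config(
    "model:\n  mutation:\n    mu: 0.1")),
    "model.curve")
  expect_error(load_config(tempfile()), "not found")
})

test_that("sweep axes expand ranges and reject bad specs", {
  lin <- axis_values(list(name = "curve.rho", range = c(0.1, 0.5),
                          count = 5, spacing = "linear"))
  expect_equal(lin$values, seq(0.1, 0.5, length.out = 5))
  lg <- axis_values(list(name = "curve.rho", range = c(0.001, 1),
                         count = 4, spacing = "log"))
  expect_equal(lg$values, 10^seq(-3, 0, length.out = 4))
  expect_error(axis_values(list(name = "x", range = c(0, 1), count = 3,
                                spacing = "log")), "positive")
  expect_error(axis_values(list(name = "x", values = c(1, 3, 2))),
               "monotone")
  expect_error(axis_values(list(name = "x")), "values")
  cfg <- load_config(write_yaml_config(paste(
    "model:", "  curve:", "    form: diminishing", "    rho: 0.1",
    "    k_t: 5", "    shape: 2", "sweep:", "  axis1:",
    "    name: curve.rho", "    values: [0.01, 0.1]", "  axis2:",
    "    name: mutation.mu", "    values: [0.0, 0.5]", sep = "\n")))
  expect_identical(cfg$sweep$axis1$name, "curve.rho")
  expect_error(load_config(write_yaml_config(paste(
    "model:", "  curve:", "    form: constant", "    rho: 0.1", "sweep:",
    "  axis1:", "    name: bogus.key", "    values: [1]", "  axis2:",
    "    name: curve.rho", "    values: [0.5]", sep = "\n"))),
    "unknown parameter")
})

test_that("configs round-trip through serialisation", {
  cfg <- load_config(fixture_config("fig3d"))
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  expect_equal(load_config(f), cfg)
})

test_that("every bundled fixture loads and defines a sweep", {
  for (id in c("fig1c", "fig1d", "fig2b", "fig3c", "fig3d")) {
    cfg <- load_config(fixture_config(id))
    expect_s3_class(cfg$model, "ciu_model")
    expect_false(is.null(cfg$sweep))
    expect_gte(length(cfg$sweep$axis1$values), 1)
  }
  expect_error(fixture_config("fig9z"))
})

test_that("landscape CSV has the documented shape and round-trips at 12 digits", {
  m <- ciu_model(group_benefit_curve("diminishing", rho = 1 / 3, k_t = 3,
                                     shape = 2), k_max = 3)
  ls <- fitness_landscape(m)
  f <- tempfile(fileext = ".csv")
  write_landscape(ls, f)
  lines <- readLines(f)
  expect_length(lines, 4)  # header + one row per size
  expect_match(lines[1], "^\"?k\"?,\"?fitness\"?,\"?is_argmax\"?$")
  back <- utils::read.csv(f)
  expect_equal(back$k, ls$k_values)
  expect_equal(back$fitness, signif(ls$fitness, 12), tolerance = 1e-12)
  expect_identical(back$is_argmax, ls$k_values == ls$argmax)
})

test_that("sweep CSV is long-format in row-major axis order", {
  base <- ciu_model(group_benefit_curve("diminishing", rho = 0.1, k_t = 4,
                                        shape = 2), k_max = 50)
  grid <- sweep_optimal_k(base,
                          list(name = "curve.rho", values = c(0.05, 0.2)),
                          list(name = "mutation.mu", values = c(0, 0.3)))
  f <- tempfile(fileext = ".csv")
  write_sweep(grid, f)
  back <- utils::read.csv(f)
  expect_length(readLines(f), 5)  # header + 2x2 cells
  expect_equal(names(back), c("axis1_name", "axis1_value", "axis2_name",
                              "axis2_value", "k_star", "favoured"))
  expect_equal(back$axis1_value, c(0.05, 0.05, 0.2, 0.2))
  expect_equal(back$axis2_value, c(0, 0.3, 0, 0.3))
  expect_identical(back$k_star, as.integer(t(grid$kstar)))
})

test_that("heatmap rendering produces a non-empty file, even for 1x1 grids", {
  base <- ciu_model(group_benefit_curve("diminishing", rho = 0.1, k_t = 4,
                                        shape = 2), k_max = 50)
  tiny <- sweep_optimal_k(base,
                          list(name = "curve.rho", values = 0.1),
                          list(name = "curve.shape", values = 2))
  f <- tempfile(fileext = ".png")
  render_heatmap(tiny, f)
  expect_true(file.exists(f))
  expect_gt(file.size(f), 0)
})
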