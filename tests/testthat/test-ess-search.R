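test_that("fitness reduces to the expected closed forms", {
  # all multipliers are 1 at k = 1
  m1 <- ciu_model(group_benefit_curve("diminishing", rho = 0.3, k_t = 5,
                                      shape = 2))
  expect_equal(fitness(m1, 1), 0.3)
  # constant curve with full spherical gains: (k^(1/3)/k) * rho
  m2 <- ciu_model(group_benefit_curve("constant", rho = 0.4),
                  efficiency = efficiency_model(alpha = 0))
  expect_equal(fitness(m2, 8), 2 / 8 * 0.4)
  expect_error(fitness(m1, 0), "positive")
})

test_that("fitness agrees with an independent single-expression evaluation", {
  set.seed(202)
  for (i in 1:100) {
    model <- ciu_model(
      curve = random_curve(),
      efficiency = efficiency_model(alpha = runif(1),
                                    geom_exponent = runif(1, 0, 1 / 3)),
      mutation = random_mutation(mu_range = c(0, 0.99)),
      n_g1 = runif(1, 0.1, 10)
    )
    k <- sample(1:60, 1)
    expect_equal(fitness(model, k), direct_fitness(model, k),
                 tolerance = 1e-12)
  }
})

test_that("the landscape is the pure 1/k decay for a flat curve", {
  m <- ciu_model(group_benefit_curve("constant", rho = 0.35), k_max = 5)
  ls <- fitness_landscape(m)
  expect_equal(ls$fitness, 0.35 / (1:5))
  expect_identical(ls$argmax, 1L)
  expect_false(ls$boundary_flag)
  df <- as.data.frame(ls)
  expect_identical(df$is_argmax, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("argmax matches a brute-force scan and breaks ties downward", {
  set.seed(303)
  for (i in 1:20) {
    model <- ciu_model(random_curve(), mutation = random_mutation(),
                       k_max = 200)
    ls <- fitness_landscape(model)
    expect_identical(ls$argmax,
                     as.integer(which(ls$fitness == max(ls$fitness))[1]))
    expect_equal(ls$fitness, fitness(model, ls$k_values))
  }
  # constructed exact tie W(1) = W(2): s(1) = 0.5, s(2) = 1
  tie <- ciu_model(group_benefit_curve("diminishing", rho = 0.5, k_t = 2,
                                       shape = 1), k_max = 10)
  expect_identical(fitness(tie, 1), fitness(tie, 2))
  expect_identical(optimal_k(tie), 1L)
})

test_that("optimal size behaves as theory dictates in the canonical cases", {
  # efficiency alone cannot favour collective units
  eff_only <- ciu_model(group_benefit_curve("constant", rho = 0.6),
                        efficiency = efficiency_model(alpha = 0), k_max = 500)
  expect_identical(optimal_k(eff_only), 1L)
  expect_false(ciu_favoured(eff_only))
  # near-linear benefits with rho = 0 push the optimum to the saturation size
  lin <- ciu_model(group_benefit_curve("diminishing", rho = 0, k_t = 6,
                                       shape = 1e6), k_max = 100)
  expect_identical(optimal_k(lin), 6L)
  # cheap threshold benefits overwhelmingly beat a hopeless singleton
  thr <- ciu_model(group_benefit_curve("threshold", rho = 1e-6, k_t = 5,
                                       shape = 0.5), k_max = 100)
  expect_true(ciu_favoured(thr))
  expect_identical(ciu_favoured(thr), optimal_k(thr) > 1L)
  # a single candidate is trivially optimal
  expect_identical(optimal_k(ciu_model(group_benefit_curve("constant",
                                                           rho = 0.2),
                                       k_max = 1)), 1L)
})

test_that("optimal size is invariant to the baseline genome budget", {
  set.seed(404)
  for (i in 1:10) {
    crv <- random_curve(forms = c("diminishing", "threshold"))
    base <- ciu_model(crv, mutation = random_mutation(mu_range = c(0, 0.8)),
                      k_max = 300)
    k0 <- suppressWarnings(optimal_k(base))
    for (scale in c(0.01, 7, 1e4)) {
      expect_identical(suppressWarnings(
        optimal_k(set_model_param(base, "n_g1", scale))), k0)
    }
  }
})

test_that("the search bound extends with mutational load and flags boundaries", {
  crv <- group_benefit_curve("diminishing", rho = 0.05, k_t = 5, shape = 5)
  heavy <- ciu_model(crv, mutation = mutation_model(0.95, 0), k_max = 10)
  ls <- fitness_landscape(heavy)
  expect_gt(length(ls$k_values), 10)      # widened beyond the configured bound
  expect_false(ls$boundary_flag)
  clipped <- ciu_model(group_benefit_curve("diminishing", rho = 0, k_t = 50,
                                           shape = 1e6), k_max = 20)
  expect_warning(optimal_k(clipped), "search bound")
})

test_that("set_model_param addresses every documented key and rejects others", {
  base <- ciu_model(group_benefit_curve("diminishing", rho = 0.2, k_t = 5,
                                        shape = 2))
  m <- set_model_param(base, "mutation.iota", 0.25)
  expect_equal(m$mutation$iota, 0.25)
  m <- set_model_param(base, "curve.form", "threshold")
  expect_identical(m$curve$form, "threshold")
  m <- set_model_param(base, "efficiency.alpha", 0.5)
  expect_equal(m$efficiency$alpha, 0.5)
  expect_error(set_model_param(base, "curve.banana", 1), "valid keys")
  expect_error(set_model_param(base, "curve.rho", 2), "rho")
})

test_that("sweeps recompute cell-by-cell and carry the favoured mask", {
  base <- ciu_model(group_benefit_curve("diminishing", rho = 0.1, k_t = 5,
                                        shape = 2), k_max = 200)
  one <- sweep_optimal_k(base,
                         list(name = "curve.rho", values = 0.02),
                         list(name = "curve.shape", values = 3))
  expect_identical(dim(one$kstar), c(1L, 1L))
  expect_identical(one$kstar[1, 1],
                   optimal_k(set_model_param(
                     set_model_param(base, "curve.rho", 0.02),
                     "curve.shape", 3)))
  rhos <- c(0.01, 0.1, 0.5)
  shapes <- c(0.5, 5)
  grid <- sweep_optimal_k(base,
                          list(name = "curve.rho", values = rhos),
                          list(name = "curve.shape", values = shapes))
  for (i in seq_along(rhos)) {
    for (j in seq_along(shapes)) {
      mij <- set_model_param(set_model_param(base, "curve.rho", rhos[i]),
                             "curve.shape", shapes[j])
      expect_identical(grid$kstar[i, j], optimal_k(mij))
    }
  }
  expect_identical(grid$favoured, grid$kstar > 1L)
  df <- as.data.frame(grid)
  expect_identical(nrow(df), 6L)
  # row-major, axis1 outermost
  expect_equal(df$axis1_value, rep(rhos, each = 2))
  expect_equal(df$axis2_value, rep(shapes, times = 3))
  expect_error(sweep_optimal_k(base, list(name = "nope", values = 1),
                               list(name = "curve.shape", values = 1)),
               "unknown parameter")
})

test_that("the optimum shrinks as the interfering fraction grows", {
  base <- ciu_model(group_benefit_curve("diminishing", rho = 0.05, k_t = 5,
                                        shape = 5),
                    mutation = mutation_model(0.5, 0))
  iotas <- c(0, 1e-3, 1e-2, 1e-1, 0.5)
  ks <- vapply(iotas, function(io) suppressWarnings(
    optimal_k(set_model_param(base, "mutation.iota", io))), integer(1))
  expect_true(all(diff(ks) <= 0))
  expect_gt(ks[1], 1)
})
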