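#' Full CIU strategy model
#'
#' Bundles the ingredients of the fitness function for a pure strategy of
#' infectious-unit size \eqn{k}:
#' \deqn{W(k) = \frac{n_g(1)\, g(k)}{k}\; s_{\mathrm{eff}}(k),}
#' the number of units produced per cell (genome budget over unit size) times
#' the effective success of each unit. With no mutational load this is the
#' bare size--number trade-off \eqn{W(k) = n_g(k)\, s(k) / k}.
#'
#' @param curve A [group_benefit_curve()].
#' @param efficiency An [efficiency_model()]; the default
#'   (\code{alpha = 1}) confers no efficiency gains.
#' @param mutation A [mutation_model()]; the default has no defective
#'   progeny.
#' @param n_g1 Baseline genome budget of a cell under the singleton strategy
#'   (positive; a pure scale factor that never moves the optimum).
#' @param k_max Upper bound of the integer search over unit size.
#' @return An object of class \code{"ciu_model"}.
#' @seealso [fitness()], [fitness_landscape()], [optimal_k()],
#'   [sweep_optimal_k()]
#' @examples
#' mod <- ciu_model(group_benefit_curve("threshold", rho = 0.01, k_t = 5,
#'                                      shape = 0.5))
#' optimal_k(mod)
#' @export
ciu_model <- function(curve,
                      efficiency = efficiency_model(),
                      mutation = mutation_model(),
                      n_g1 = 1,
                      k_max = 1000L) {
  stopifnot(inherits(curve, "group_benefit_curve"),
            inherits(efficiency, "efficiency_model"),
            inherits(mutation, "mutation_model"))
  if (!is.numeric(n_g1) || length(n_g1) != 1L || is.na(n_g1) || n_g1 <= 0) {
    stop("invalid 'n_g1': must be a single positive real", call. = FALSE)
  }
  if (!is.numeric(k_max) || length(k_max) != 1L || is.na(k_max) ||
      k_max < 1 || k_max != round(k_max)) {
    stop("invalid 'k_max': must be a single integer >= 1", call. = FALSE)
  }
  structure(
    list(curve = curve, efficiency = efficiency, mutation = mutation,
         n_g1 = n_g1, k_max = as.integer(k_max)),
    class = "ciu_model"
  )
}

#' @export
print.ciu_model <- function(x, ...) {
  cat("CIU strategy model\n")
  print(x$curve)
  print(x$efficiency)
  print(x$mutation)
  cat(sprintf("  n_g1 = %g, k_max = %d\n", x$n_g1, x$k_max))
  invisible(x)
}

#' Fitness of a pure unit-size strategy
#'
#' Evaluates \eqn{W(k) = n_g(1)\, g(k)\, s_{\mathrm{eff}}(k) / k}.
#' Vectorised over \code{k}.
#'
#' @param model A [ciu_model()].
#' @param k Vector of positive integers.
#' @return Numeric vector of non-negative fitness values.
#' @export
fitness <- function(model, k) {
  stopifnot(inherits(model, "ciu_model"))
  if (length(k) == 0L) return(numeric(0))
  if (any(!is.finite(k)) || any(k < 1) || any(k != round(k))) {
    stop("'k' must contain positive integers", call. = FALSE)
  }
  model$n_g1 * genome_multiplier(model$efficiency, k) / k *
    effective_success(model$curve, model$mutation, k)
}

# Effective search bound: with defective progeny the optimum can sit far
# beyond k_t (it tracks k_t'), so the bound is widened to 10 * k_t'(0.001)
# when that exceeds the configured k_max.
effective_k_max <- function(model) {
  k_max <- model$k_max
  mu <- model$mutation$mu
  if (mu > 0 && mu < 1 && model$curve$form != "constant") {
    k_max <- max(k_max, 10L * kt_prime(model$curve$k_t, mu, 0.001))
  }
  as.integer(k_max)
}

#' Fitness landscape over unit sizes
#'
#' Evaluates the fitness of every integer unit size from 1 up to the search
#' bound and locates the optimum. With defective progeny
#' (\eqn{\mu > 0}) the bound is automatically extended to
#' \eqn{\max(k_{max}, 10\,k_t'(\mu, 0.001))} so the optimum is not clipped.
#' Ties are resolved toward the smallest maximiser, so the reported optimum
#' exceeds 1 only when some collective strategy is strictly better than
#' singleton transmission.
#'
#' @param model A [ciu_model()].
#' @return An object of class \code{"fitness_landscape"}: a list with
#'   \code{k_values}, \code{fitness}, \code{argmax} and \code{boundary_flag}
#'   (\code{TRUE} when the optimum sits on the search bound, i.e. the bound
#'   may be too small).
#' @export
fitness_landscape <- function(model) {
  stopifnot(inherits(model, "ciu_model"))
  k <- seq_len(effective_k_max(model))
  w <- fitness(model, k)
  argmax <- which.max(w)  # which.max returns the first (smallest) maximiser
  structure(
    list(k_values = k, fitness = w, argmax = as.integer(argmax),
         boundary_flag = argmax == length(k)),
    class = "fitness_landscape"
  )
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("Fitness landscape over k = 1..%d\n", length(x$k_values)))
  cat(sprintf("  k* = %d, W(k*) = %g%s\n", x$argmax, x$fitness[x$argmax],
              if (x$boundary_flag) " [optimum on search bound]" else ""))
  invisible(x)
}

#' @describeIn fitness_landscape Coerce to a data frame with columns
#'   \code{k}, \code{fitness}, \code{is_argmax}.
#' @param x A \code{"fitness_landscape"}.
#' @param ... Unused.
#' @export
as.data.frame.fitness_landscape <- function(x, ...) {
  data.frame(k = x$k_values, fitness = x$fitness,
             is_argmax = x$k_values == x$argmax)
}

#' Optimal unit size (candidate ESS)
#'
#' The integer unit size maximising [fitness()] -- the candidate
#' evolutionarily stable strategy. A warning is emitted when the optimum sits
#' on the search bound, since the true optimum may then lie beyond it.
#'
#' @param model A [ciu_model()].
#' @return A positive integer.
#' @export
optimal_k <- function(model) {
  ls <- fitness_landscape(model)
  if (ls$boundary_flag && length(ls$k_values) > 1L) {
    warning(sprintf(
      "optimal k sits on the search bound (k_max = %d); consider raising k_max",
      length(ls$k_values)), call. = FALSE)
  }
  ls$argmax
}

#' Are collective infectious units favoured?
#'
#' \code{TRUE} exactly when some unit size \eqn{k > 1} has strictly higher
#' fitness than singleton transmission (strictness follows from the
#' smallest-maximiser tie-break in [fitness_landscape()]).
#'
#' @param model A [ciu_model()].
#' @return Logical scalar.
#' @export
ciu_favoured <- function(model) {
  fitness_landscape(model)$argmax > 1L
}

# ---- parameter addressing for sweeps and configs -------------------------

sweep_param_keys <- c(
  "curve.form", "curve.rho", "curve.k_t", "curve.shape",
  "efficiency.alpha", "efficiency.geom_exponent",
  "mutation.mu", "mutation.iota",
  "n_g1", "k_max"
)

#' Override a model parameter by dotted key
#'
#' Rebuilds a [ciu_model()] with one parameter replaced, addressed by its
#' dotted configuration key (e.g. \code{"curve.rho"}, \code{"mutation.iota"}).
#' All component validation re-runs, so out-of-domain values error.
#'
#' @param model A [ciu_model()].
#' @param key One of \code{curve.form}, \code{curve.rho}, \code{curve.k_t},
#'   \code{curve.shape}, \code{efficiency.alpha},
#'   \code{efficiency.geom_exponent}, \code{mutation.mu},
#'   \code{mutation.iota}, \code{n_g1}, \code{k_max}.
#' @param value Replacement value.
#' @return A new \code{"ciu_model"}.
#' @export
set_model_param <- function(model, key, value) {
  stopifnot(inherits(model, "ciu_model"))
  if (!is.character(key) || length(key) != 1L ||
      !key %in% sweep_param_keys) {
    stop(sprintf("unknown parameter key '%s'; valid keys: %s",
                 as.character(key)[1],
                 paste(sweep_param_keys, collapse = ", ")), call. = FALSE)
  }
  crv <- unclass(model$curve)
  eff <- unclass(model$efficiency)
  mut <- unclass(model$mutation)
  n_g1 <- model$n_g1
  k_max <- model$k_max
  switch(key,
    "curve.form" = crv$form <- value,
    "curve.rho" = crv$rho <- value,
    "curve.k_t" = crv$k_t <- value,
    "curve.shape" = crv$shape <- value,
    "efficiency.alpha" = eff$alpha <- value,
    "efficiency.geom_exponent" = eff$geom_exponent <- value,
    "mutation.mu" = mut$mu <- value,
    "mutation.iota" = mut$iota <- value,
    "n_g1" = n_g1 <- value,
    "k_max" = k_max <- value
  )
  ciu_model(
    curve = group_benefit_curve(crv$form, crv$rho, crv$k_t, crv$shape),
    efficiency = efficiency_model(eff$alpha, eff$geom_exponent),
    mutation = mutation_model(mut$mu, mut$iota),
    n_g1 = n_g1, k_max = k_max
  )
}

#' Two-dimensional sweep of the optimal unit size
#'
#' Recomputes [optimal_k()] over a grid formed by overriding two model
#' parameters of a template model -- the computation behind optimal-size
#' heatmaps (e.g. singleton success \eqn{\rho} against curve shape, or
#' defective proportion \eqn{\mu} against interfering fraction \eqn{\iota}).
#'
#' @param template A [ciu_model()] supplying every non-swept parameter.
#' @param axis1,axis2 Lists with elements \code{name} (a dotted parameter
#'   key, see [set_model_param()]) and \code{values} (the ordered grid
#'   values).
#' @return An object of class \code{"sweep_grid"}: axis definitions plus an
#'   integer matrix \code{kstar} (\code{length(axis1$values)} rows by
#'   \code{length(axis2$values)} columns), a logical matrix \code{favoured}
#'   (\code{kstar > 1}), and \code{boundary} flagging cells whose optimum hit
#'   the search bound.
#' @export
sweep_optimal_k <- function(template, axis1, axis2) {
  stopifnot(inherits(template, "ciu_model"))
  check_axis <- function(ax, which) {
    if (!is.list(ax) || is.null(ax$name) || is.null(ax$values) ||
        length(ax$values) < 1L) {
      stop(sprintf("%s must be a list with 'name' and non-empty 'values'",
                   which), call. = FALSE)
    }
  }
  check_axis(axis1, "axis1")
  check_axis(axis2, "axis2")
  n1 <- length(axis1$values)
  n2 <- length(axis2$values)
  kstar <- matrix(NA_integer_, n1, n2)
  boundary <- matrix(FALSE, n1, n2)
  for (i in seq_len(n1)) {
    m1 <- set_model_param(template, axis1$name, axis1$values[[i]])
    for (j in seq_len(n2)) {
      mij <- set_model_param(m1, axis2$name, axis2$values[[j]])
      ls <- fitness_landscape(mij)
      kstar[i, j] <- ls$argmax
      boundary[i, j] <- ls$boundary_flag
    }
  }
  structure(
    list(axis1 = list(name = axis1$name, values = axis1$values),
         axis2 = list(name = axis2$name, values = axis2$values),
         kstar = kstar, favoured = kstar > 1L, boundary = boundary),
    class = "sweep_grid"
  )
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("Optimal-size sweep: %s (%d values) x %s (%d values)\n",
              x$axis1$name, length(x$axis1$values),
              x$axis2$name, length(x$axis2$values)))
  cat(sprintf("  k* range %d..%d; favoured in %d/%d cells%s\n",
              min(x$kstar), max(x$kstar), sum(x$favoured), length(x$favoured),
              if (any(x$boundary)) "; some cells hit the search bound" else ""))
  invisible(x)
}

#' @describeIn sweep_optimal_k Coerce a sweep to a long-format data frame
#'   with columns \code{axis1_name}, \code{axis1_value}, \code{axis2_name},
#'   \code{axis2_value}, \code{k_star}, \code{favoured}, in row-major
#'   (axis1-then-axis2) order.
#' @param x A \code{"sweep_grid"}.
#' @param ... Unused.
#' @export
as.data.frame.sweep_grid <- function(x, ...) {
  n1 <- length(x$axis1$values)
  n2 <- length(x$axis2$values)
  data.frame(
    axis1_name = x$axis1$name,
    axis1_value = rep(unlist(x$axis1$values), each = n2),
    axis2_name = x$axis2$name,
    axis2_value = rep(unlist(x$axis2$values), times = n1),
    k_star = as.integer(t(x$kstar)),
    favoured = as.logical(t(x$favoured))
  )
}
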