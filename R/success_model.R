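#' Group-benefit success curve
#'
#' Constructs the per-unit infection success function \eqn{s(k)}: the expected
#' number of future cellular infections seeded by an infectious unit carrying
#' \eqn{k} complete genomes, scaled so that the maximum attainable benefit is
#' 1. Benefits saturate at the threshold size \code{k_t}: delivering more than
#' \code{k_t} complete genomes to a cell buys nothing further, so
#' \eqn{s(k) = 1} for all \eqn{k \ge k_t}. A unit delivering zero complete
#' genomes founds no infection, so \eqn{s(0) = 0} for every form.
#'
#' Three functional forms are supported:
#' \describe{
#'   \item{\code{"diminishing"}}{Concave (decelerating) returns,
#'     \deqn{s(k) = \rho + (1-\rho)\,
#'       \frac{1 - e^{-(k-1)/a}}{1 - e^{-(k_t-1)/a}}, \quad 1 \le k \le k_t,}
#'     where \code{shape} is the scale \eqn{a}: small \eqn{a} gives a steep,
#'     quickly-saturating curve, large \eqn{a} approaches the straight line
#'     from \eqn{(1, \rho)} to \eqn{(k_t, 1)}.}
#'   \item{\code{"threshold"}}{Sigmoidal, a logistic in \eqn{k} with midpoint
#'     \eqn{(1+k_t)/2} and width \code{shape}, rescaled so that
#'     \eqn{s(1) = \rho} and \eqn{s(k_t) = 1}; smaller \code{shape} gives a
#'     sharper switch.}
#'   \item{\code{"constant"}}{\eqn{s(k) = \rho} for all \eqn{k \ge 1}: success
#'     independent of unit size, the null curve used to isolate efficiency or
#'     mutation effects.}
#' }
#'
#' @param form One of \code{"diminishing"}, \code{"threshold"},
#'   \code{"constant"}.
#' @param rho Success of a unit carrying a single complete genome, in
#'   \eqn{[0, 1]}.
#' @param k_t Integer saturation size (\eqn{\ge 1}); ignored by the constant
#'   form. \code{k_t = 1} denotes the degenerate curve that is already
#'   saturated at a single genome (\eqn{s(k) = 1} for \eqn{k \ge 1}).
#' @param shape Positive shape parameter (ignored by the constant form): the
#'   exponential scale \eqn{a} for \code{"diminishing"}, the logistic width
#'   for \code{"threshold"}.
#'
#' @return An object of class \code{"group_benefit_curve"}.
#' @seealso [success()], [curve_table()], [effective_success()]
#' @examples
#' crv <- group_benefit_curve("diminishing", rho = 0.2, k_t = 5, shape = 2)
#' success(crv, 0:7)
#' @export
group_benefit_curve <- function(form = c("diminishing", "threshold", "constant"),
                                rho, k_t = 1L, shape = 1) {
  form <- match.arg(form)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < 0 || rho > 1) {
    stop("invalid 'rho': must be a single probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(k_t) || length(k_t) != 1L || is.na(k_t) ||
      k_t < 1 || k_t != round(k_t)) {
    stop("invalid 'k_t': must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(shape) || length(shape) != 1L || is.na(shape) || shape <= 0) {
    stop("invalid 'shape': must be a single positive real", call. = FALSE)
  }
  structure(
    list(form = form, rho = rho, k_t = as.integer(k_t), shape = shape),
    class = "group_benefit_curve"
  )
}

#' @export
print.group_benefit_curve <- function(x, ...) {
  cat(sprintf("Group-benefit success curve (%s)\n", x$form))
  cat(sprintf("  rho = %g", x$rho))
  if (x$form != "constant") {
    cat(sprintf(", k_t = %d, shape = %g", x$k_t, x$shape))
  }
  cat("\n")
  invisible(x)
}

# Size at and beyond which the curve is flat: used by effective_success() to
# collapse the binomial tail. Constant curves are flat from k = 1.
saturation_size <- function(curve) {
  if (curve$form == "constant") 1L else curve$k_t
}

#' Evaluate a group-benefit success curve
#'
#' Computes \eqn{s(k)} for integer unit sizes \code{k}. Vectorised over
#' \code{k}; \eqn{s(0) = 0} always, and \eqn{s(k) = 1} for \eqn{k \ge k_t}
#' (diminishing and threshold forms).
#'
#' @param curve A [group_benefit_curve()].
#' @param k Vector of non-negative integers.
#' @return Numeric vector of success probabilities, same length as \code{k}.
#' @export
success <- function(curve, k) {
  stopifnot(inherits(curve, "group_benefit_curve"))
  if (length(k) == 0L) return(numeric(0))
  if (any(!is.finite(k)) || any(k < 0) || any(k != round(k))) {
    stop("'k' must contain non-negative integers", call. = FALSE)
  }
  rho <- curve$rho
  k_t <- curve$k_t
  a <- curve$shape

  s <- numeric(length(k))
  pos <- k >= 1L
  if (curve$form == "constant") {
    s[pos] <- rho
    return(s)
  }
  if (k_t == 1L) {
    s[pos] <- 1
    return(s)
  }
  sat <- k >= k_t
  s[sat] <- 1
  mid <- pos & !sat
  if (any(mid)) {
    km <- k[mid]
    if (curve$form == "diminishing") {
      # expm1 keeps the ratio accurate for large a (near-linear limit)
      s[mid] <- rho + (1 - rho) * expm1(-(km - 1) / a) / expm1(-(k_t - 1) / a)
    } else { # threshold: logistic pinned at (1, rho) and (k_t, 1)
      m <- (1 + k_t) / 2
      sig <- function(x) stats::plogis(x)
      lo <- sig((1 - m) / a)
      hi <- sig((k_t - m) / a)
      s[mid] <- rho + (1 - rho) * (sig((km - m) / a) - lo) / (hi - lo)
    }
  }
  s
}

#' Tabulate a success curve
#'
#' Materialises \eqn{(k, s(k))} for \eqn{k = 1, \dots, k_{max}}, e.g. for
#' plotting the size--success relationship.
#'
#' @inheritParams success
#' @param k_max Largest size to tabulate (integer \eqn{\ge 1}).
#' @return A data frame with columns \code{k} and \code{s}.
#' @export
curve_table <- function(curve, k_max) {
  if (!is.numeric(k_max) || length(k_max) != 1L || is.na(k_max) ||
      k_max < 1 || k_max != round(k_max)) {
    stop("invalid 'k_max': must be a single integer >= 1", call. = FALSE)
  }
  k <- seq_len(k_max)
  data.frame(k = k, s = success(curve, k))
}

#' Packaging-efficiency model
#'
#' Larger infectious units can package genomes more cheaply: if the resource
#' cost of a unit scales with its surface area while its genome capacity
#' scales with volume, a unit of size \eqn{k} saves a factor of up to
#' \eqn{k^{1/3}} (spherical, isometric growth) relative to \eqn{k} singleton
#' units. When those savings are re-invested in genome replication, the
#' per-cell genome budget rises by the multiplier
#' \deqn{g(k) = k^{(1-\alpha)\,\epsilon},}
#' where \eqn{\epsilon} is the geometric savings exponent (\code{1/3} for
#' spheres; \code{0} for rod-shaped units that elongate in one dimension, which
#' save nothing) and \eqn{\alpha \in [0, 1]} measures how little of the saving
#' is converted into extra genomes: \eqn{\alpha = 0} is full conversion (the
#' largest possible gain, the cube-root law), \eqn{\alpha = 1} is none.
#'
#' @param alpha Conversion loss in \eqn{[0, 1]}; 0 = maximal conversion of
#'   packaging savings into genome production.
#' @param geom_exponent Geometric savings exponent in \eqn{[0, 1/3]};
#'   \code{1/3} for spherical units, \code{0} for rods.
#' @return An object of class \code{"efficiency_model"}.
#' @seealso [genome_multiplier()]
#' @examples
#' genome_multiplier(efficiency_model(alpha = 0), k = 8) # 8^(1/3) = 2
#' @export
efficiency_model <- function(alpha = 1, geom_exponent = 1 / 3) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("invalid 'alpha': must be a single real in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(geom_exponent) || length(geom_exponent) != 1L ||
      is.na(geom_exponent) || geom_exponent < 0 || geom_exponent > 1 / 3) {
    stop("invalid 'geom_exponent': must be a single real in [0, 1/3]",
         call. = FALSE)
  }
  structure(list(alpha = alpha, geom_exponent = geom_exponent),
            class = "efficiency_model")
}

#' @export
print.efficiency_model <- function(x, ...) {
  cat(sprintf("Efficiency model: alpha = %g, geom_exponent = %g (g(k) = k^%g)\n",
              x$alpha, x$geom_exponent, (1 - x$alpha) * x$geom_exponent))
  invisible(x)
}

#' Genome-budget multiplier
#'
#' Evaluates \eqn{g(k) = k^{(1-\alpha)\,\epsilon}}, the factor by which a
#' strategy of unit size \eqn{k} inflates the baseline genome budget through
#' packaging-efficiency gains. \eqn{g(1) = 1} and \eqn{g(k) \le k^{1/3}}
#' always; crucially \eqn{g(k)/k} is strictly decreasing, which is why
#' efficiency gains alone can never favour collective units.
#'
#' @param eff An [efficiency_model()].
#' @param k Vector of positive integers.
#' @return Numeric vector of multipliers \eqn{\ge 1}.
#' @export
genome_multiplier <- function(eff, k) {
  stopifnot(inherits(eff, "efficiency_model"))
  if (length(k) == 0L) return(numeric(0))
  if (any(!is.finite(k)) || any(k < 1) || any(k != round(k))) {
    stop("'k' must contain positive integers", call. = FALSE)
  }
  k^((1 - eff$alpha) * eff$geom_exponent)
}
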