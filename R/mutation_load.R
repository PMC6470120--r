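#' Defective and defective-interfering progeny model
#'
#' Viral replication is error-prone: a proportion \code{mu} of progeny genomes
#' are defective (they occupy packaging slots but cannot seed an infection),
#' and a fraction \code{iota} of those defectives are additionally
#' interfering -- they parasitise the replication of co-packaged complete
#' genomes, and a cell receiving even one interfering genome yields no
#' productive progeny. Each genome in a unit is independently
#' \describe{
#'   \item{complete}{with probability \eqn{1 - \mu},}
#'   \item{defective (non-interfering)}{with probability \eqn{\mu(1-\iota)},}
#'   \item{defective interfering}{with probability \eqn{\mu\iota}.}
#' }
#'
#' @param mu Proportion of progeny genomes that are defective, in
#'   \eqn{[0, 1]}.
#' @param iota Fraction of defective genomes that are also interfering, in
#'   \eqn{[0, 1]}.
#' @return An object of class \code{"mutation_model"}.
#' @seealso [class_probabilities()], [effective_success()], [kt_prime()]
#' @export
mutation_model <- function(mu = 0, iota = 0) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0 || mu > 1) {
    stop("invalid 'mu': must be a single probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(iota) || length(iota) != 1L || is.na(iota) ||
      iota < 0 || iota > 1) {
    stop("invalid 'iota': must be a single probability in [0, 1]",
         call. = FALSE)
  }
  structure(list(mu = mu, iota = iota), class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  p <- class_probabilities(x)
  cat(sprintf("Mutation model: mu = %g, iota = %g\n", x$mu, x$iota))
  cat(sprintf("  P(complete) = %g, P(defective) = %g, P(interfering) = %g\n",
              p[["complete"]], p[["defective"]], p[["interfering"]]))
  invisible(x)
}

#' Per-genome class probabilities
#'
#' @param m A [mutation_model()].
#' @return Named numeric vector \code{c(complete, defective, interfering)}
#'   summing to 1; \code{defective} counts only non-interfering defectives.
#' @export
class_probabilities <- function(m) {
  stopifnot(inherits(m, "mutation_model"))
  c(complete = 1 - m$mu,
    defective = m$mu * (1 - m$iota),
    interfering = m$mu * m$iota)
}

#' Effective success of an infectious unit under mutational load
#'
#' The effective success of a unit packaging \code{k} progeny genomes: the
#' unit fails outright if it carries any interfering genome, and otherwise
#' succeeds according to the group-benefit curve evaluated at its number of
#' complete genomes \eqn{j},
#' \deqn{s_{\mathrm{eff}}(k) = \sum_{j=0}^{k} \binom{k}{j} (1-\mu)^j
#'   \left[\mu(1-\iota)\right]^{k-j} s(j).}
#' Equivalently, conditioning on the DI-free event (probability
#' \eqn{(1-\mu\iota)^k}), \eqn{j} is Binomial\eqn{(k, (1-\mu)/(1-\mu\iota))};
#' the implementation uses this factorisation together with the curve's flat
#' tail (\eqn{s(j) = 1} for \eqn{j \ge k_t}) so each evaluation costs
#' \eqn{O(k_t)} and is numerically stable for \eqn{k} well beyond \eqn{10^4}.
#'
#' @param curve A [group_benefit_curve()].
#' @param m A [mutation_model()].
#' @param k Vector of positive integers (unit sizes).
#' @return Numeric vector of effective success probabilities.
#' @export
effective_success <- function(curve, m, k) {
  stopifnot(inherits(curve, "group_benefit_curve"),
            inherits(m, "mutation_model"))
  if (length(k) == 0L) return(numeric(0))
  if (any(!is.finite(k)) || any(k < 1) || any(k != round(k))) {
    stop("'k' must contain positive integers", call. = FALSE)
  }
  mu <- m$mu
  iota <- m$iota
  if (mu == 0) return(success(curve, k))
  if (mu == 1) return(numeric(length(k)))  # every genome defective; s(0) = 0

  escape <- (1 - mu * iota)^k             # P(no interfering genome)
  q <- (1 - mu) / (1 - mu * iota)         # P(complete | not interfering)
  sat <- saturation_size(curve)           # s flat at s(sat) for j >= sat
  s_sat <- success(curve, sat)

  vapply(seq_along(k), function(i) {
    ki <- k[i]
    jmax <- min(ki, sat - 1L)
    head_sum <- if (jmax >= 1L) {
      j <- seq_len(jmax)
      sum(stats::dbinom(j, ki, q) * success(curve, j))
    } else 0
    tail_sum <- if (ki >= sat) {
      s_sat * stats::pbinom(sat - 1L, ki, q, lower.tail = FALSE)
    } else 0
    escape[i] * (head_sum + tail_sum)
  }, numeric(1))
}

#' Monte-Carlo estimate of effective success
#'
#' Independent stochastic oracle for [effective_success()]: samples
#' \code{n_draws} units of \code{k} genomes with classes drawn per
#' [class_probabilities()], scores each unit 0 if it contains any interfering
#' genome and \eqn{s(\#\mathrm{complete})} otherwise, and returns the mean
#' score with its standard error. Reproducible for a fixed \code{seed}.
#'
#' @inheritParams effective_success
#' @param k A single positive integer unit size.
#' @param n_draws Number of simulated units (\eqn{\ge 1}).
#' @param seed Integer seed for the draw.
#' @return List with elements \code{estimate} and \code{std_error}.
#' @export
effective_success_mc <- function(curve, m, k, n_draws, seed = 0L) {
  stopifnot(inherits(curve, "group_benefit_curve"),
            inherits(m, "mutation_model"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("'k' must be a single positive integer", call. = FALSE)
  }
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 1 ||
      n_draws != round(n_draws)) {
    stop("'n_draws' must be a single positive integer", call. = FALSE)
  }
  p <- class_probabilities(m)
  counts <- withr_seed(seed, function() {
    stats::rmultinom(n_draws, size = k, prob = p)
  })
  score <- ifelse(counts["interfering", ] > 0, 0,
                  success(curve, counts["complete", ]))
  est <- mean(score)
  se <- if (n_draws > 1) stats::sd(score) / sqrt(n_draws) else 0
  list(estimate = est, std_error = se)
}

# Run fn() under a local RNG state seeded with `seed`, restoring the caller's
# state afterwards (no withr dependency needed for this one use).
withr_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Probability that a unit is free of interfering genomes
#'
#' The escape factor \eqn{(1-\mu\iota)^k}: the chance that none of the
#' \code{k} genomes in a unit is defective interfering. The entire cost of
#' interference enters the model through this factor, which is why it depends
#' on \eqn{\mu} and \eqn{\iota} only through their product.
#'
#' @param m A [mutation_model()].
#' @param k Vector of positive integers.
#' @return Numeric vector of probabilities.
#' @export
di_free_probability <- function(m, k) {
  stopifnot(inherits(m, "mutation_model"))
  if (any(!is.finite(k)) || any(k < 1) || any(k != round(k))) {
    stop("'k' must contain positive integers", call. = FALSE)
  }
  (1 - m$mu * m$iota)^k
}

#' Secondary saturation threshold under defective progeny
#'
#' The size \eqn{k_t'} at which a unit almost surely still delivers the
#' saturating number of complete genomes despite defective progeny: the
#' smallest \eqn{k} such that
#' \eqn{P(\mathrm{Binomial}(k, 1-\mu) \ge k_t) \ge 1 - \epsilon}.
#' As \eqn{\mu} grows, units must be larger to reach maximal success, and the
#' optimum unit size tracks this secondary threshold rather than \eqn{k_t}.
#'
#' @param k_t Saturation size of the group-benefit curve (integer
#'   \eqn{\ge 1}).
#' @param mu Defective proportion, in \eqn{[0, 1)} (for \eqn{\mu = 1} no
#'   finite size works unless \code{epsilon = 1}).
#' @param epsilon Tolerated failure probability in \eqn{(0, 1]}; default
#'   \code{0.001}.
#' @return The smallest qualifying integer size.
#' @export
kt_prime <- function(k_t, mu, epsilon = 0.001) {
  if (!is.numeric(k_t) || length(k_t) != 1L || k_t < 1 || k_t != round(k_t)) {
    stop("invalid 'k_t': must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0 || mu > 1) {
    stop("invalid 'mu': must be a single probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon <= 0 || epsilon > 1) {
    stop("invalid 'epsilon': must be in (0, 1]", call. = FALSE)
  }
  if (epsilon == 1) return(1L)
  if (mu == 1) {
    stop("no finite size attains the target: mu = 1 with epsilon < 1",
         call. = FALSE)
  }
  ok <- function(k) {
    stats::pbinom(k_t - 1, k, 1 - mu, lower.tail = FALSE) >= 1 - epsilon
  }
  # geometric bracket then bisect: the tail probability is nondecreasing in k
  lo <- k_t
  if (ok(lo)) return(as.integer(lo))
  hi <- lo
  repeat {
    hi <- hi * 2L
    if (ok(hi)) break
    if (hi > .Machine$integer.max / 4) {
      stop("search for k_t' exceeded integer range", call. = FALSE)
    }
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (ok(mid)) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
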