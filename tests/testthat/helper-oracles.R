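# Independent oracles and random-model generators shared across tests.
# Oracles deliberately avoid the package's computational path: enumeration
# over per-genome class assignments, direct single-expression fitness, and
# log-space binomial sums.

# Random valid curve; forms can be restricted.
random_curve <- function(forms = c("diminishing", "threshold", "constant"),
                         rho_range = c(0, 1), k_t_range = 2:20,
                         shape_range = c(0.1, 10)) {
  form <- sample(forms, 1)
  group_benefit_curve(
    form = form,
    rho = stats::runif(1, rho_range[1], rho_range[2]),
    k_t = sample(k_t_range, 1),
    shape = stats::runif(1, shape_range[1], shape_range[2])
  )
}

random_mutation <- function(mu_range = c(0, 1), iota_range = c(0, 1)) {
  mutation_model(mu = stats::runif(1, mu_range[1], mu_range[2]),
                 iota = stats::runif(1, iota_range[1], iota_range[2]))
}

# Exhaustive oracle for effective_success: enumerate all 3^k per-genome
# class assignments (1 = complete, 2 = defective, 3 = interfering), score
# each, and sum probability-weighted scores. Feasible for k <= 12.
enum_effective_success <- function(curve, m, k) {
  stopifnot(k >= 1, k <= 12)
  p <- class_probabilities(m)
  classes <- as.matrix(do.call(expand.grid, rep(list(1:3), k)))
  n_complete <- rowSums(classes == 1)
  n_defective <- rowSums(classes == 2)
  n_interfering <- rowSums(classes == 3)
  prob <- p[["complete"]]^n_complete * p[["defective"]]^n_defective *
    p[["interfering"]]^n_interfering
  score <- ifelse(n_interfering > 0, 0, success(curve, n_complete))
  sum(prob * score)
}

# Normalisation companion: total probability over all class assignments.
enum_total_probability <- function(m, k) {
  p <- class_probabilities(m)
  classes <- as.matrix(do.call(expand.grid, rep(list(1:3), k)))
  sum(p[["complete"]]^rowSums(classes == 1) *
        p[["defective"]]^rowSums(classes == 2) *
        p[["interfering"]]^rowSums(classes == 3))
}

# Independent single-expression evaluation of the fitness equation
# W(k) = n_g1 * k^((1-alpha)*eps) / k * sum_j C(k,j)(1-mu)^j (mu(1-iota))^(k-j) s(j)
# using choose() directly (no binomial factorisation, no flat-tail collapse).
direct_fitness <- function(model, k) {
  crv <- model$curve
  eff <- model$efficiency
  mu <- model$mutation$mu
  iota <- model$mutation$iota
  j <- 0:k
  s_eff <- sum(choose(k, j) * (1 - mu)^j * (mu * (1 - iota))^(k - j) *
                 success(crv, j))
  model$n_g1 * k^((1 - eff$alpha) * eff$geom_exponent) / k * s_eff
}

# DI-free probability computed independently in log space: sum over the
# number of complete genomes c of C(k,c) p_c^c p_d^(k-c).
logspace_di_free <- function(m, k) {
  p <- class_probabilities(m)
  if (p[["complete"]] == 0 && p[["defective"]] == 0) {
    return(if (k == 0) 1 else 0)
  }
  cvals <- 0:k
  terms <- lchoose(k, cvals) +
    ifelse(cvals == 0, 0, cvals * log(p[["complete"]])) +
    ifelse(cvals == k, 0, (k - cvals) * log(p[["defective"]]))
  keep <- is.finite(terms)
  sum(exp(terms[keep]))
}
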