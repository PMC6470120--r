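#' @importFrom ggplot2 ggplot aes geom_tile scale_fill_viridis_c labs
#'   theme_minimal ggsave scale_colour_manual guides guide_legend
NULL

config_keys <- list(
  top = c("model", "sweep", "output", "seed", "log_level"),
  model = c("curve", "efficiency", "mutation", "n_g1", "k_max"),
  curve = c("form", "rho", "k_t", "shape"),
  efficiency = c("alpha", "geom_exponent"),
  mutation = c("mu", "iota"),
  axis = c("name", "values", "range", "count", "spacing")
)

check_keys <- function(x, allowed, where) {
  if (!is.list(x)) {
    stop(sprintf("config section '%s' must be a mapping", where),
         call. = FALSE)
  }
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown config key(s) under '%s': %s (valid: %s)", where,
                 paste(bad, collapse = ", "), paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Expand a sweep-axis specification into grid values
#'
#' An axis is given either as explicit \code{values} or as a \code{range}
#' (\code{c(lo, hi)}) with a \code{count} and a \code{spacing} of
#' \code{"linear"} or \code{"log"}. The result must be strictly monotone.
#'
#' @param spec A list with \code{name} and either \code{values} or
#'   \code{range} + \code{count} + \code{spacing}.
#' @return A list with \code{name} and numeric \code{values}, suitable for
#'   [sweep_optimal_k()].
#' @export
axis_values <- function(spec) {
  check_keys(spec, config_keys$axis, "sweep axis")
  if (is.null(spec$name)) {
    stop("sweep axis needs a 'name'", call. = FALSE)
  }
  if (!is.null(spec$values)) {
    vals <- unlist(spec$values)
  } else {
    if (is.null(spec$range) || is.null(spec$count)) {
      stop(sprintf("sweep axis '%s' needs 'values' or 'range' + 'count'",
                   spec$name), call. = FALSE)
    }
    rng <- unlist(spec$range)
    if (length(rng) != 2L || !is.numeric(rng)) {
      stop(sprintf("sweep axis '%s': 'range' must be two numbers", spec$name),
           call. = FALSE)
    }
    spacing <- if (is.null(spec$spacing)) "linear" else spec$spacing
    if (!spacing %in% c("linear", "log")) {
      stop(sprintf("sweep axis '%s': spacing must be 'linear' or 'log'",
                   spec$name), call. = FALSE)
    }
    vals <- if (spacing == "log") {
      if (any(rng <= 0)) {
        stop(sprintf("sweep axis '%s': log spacing needs a positive range",
                     spec$name), call. = FALSE)
      }
      exp(seq(log(rng[1]), log(rng[2]), length.out = spec$count))
    } else {
      seq(rng[1], rng[2], length.out = spec$count)
    }
  }
  if (length(vals) > 1L && !(all(diff(vals) > 0) || all(diff(vals) < 0))) {
    stop(sprintf("sweep axis '%s': values must be strictly monotone",
                 spec$name), call. = FALSE)
  }
  list(name = spec$name, values = vals)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing a CIU model and (optionally) a
#' two-axis sweep. The schema is strict: unknown keys are rejected with the
#' offending key path, every parameter is validated against its domain, and
#' defaults are applied (\code{efficiency} none, \code{mutation} none,
#' \code{n_g1 = 1}, \code{k_max = 1000}, \code{seed = 0},
#' \code{log_level = "info"}, \code{output = "results"}).
#'
#' @param path Path to a YAML file.
#' @return An object of class \code{"ciu_config"}: a list with a
#'   [ciu_model()] in \code{$model}, \code{$sweep} (axis list or
#'   \code{NULL}), \code{$output}, \code{$seed}, \code{$log_level}.
#' @seealso [write_config()], [fixture_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  check_keys(raw, config_keys$top, "<top level>")
  if (is.null(raw$model) || is.null(raw$model$curve)) {
    stop("config must define model.curve", call. = FALSE)
  }
  check_keys(raw$model, config_keys$model, "model")
  check_keys(raw$model$curve, config_keys$curve, "model.curve")
  crv <- raw$model$curve
  curve <- tryCatch(
    group_benefit_curve(
      form = if (is.null(crv$form)) "diminishing" else crv$form,
      rho = crv$rho,
      k_t = if (is.null(crv$k_t)) 1L else crv$k_t,
      shape = if (is.null(crv$shape)) 1 else crv$shape
    ),
    error = function(e) stop(sprintf("model.curve: %s", conditionMessage(e)),
                             call. = FALSE)
  )
  eff <- efficiency_model()
  if (!is.null(raw$model$efficiency)) {
    check_keys(raw$model$efficiency, config_keys$efficiency,
               "model.efficiency")
    e <- raw$model$efficiency
    eff <- tryCatch(
      efficiency_model(
        alpha = if (is.null(e$alpha)) 1 else e$alpha,
        geom_exponent = if (is.null(e$geom_exponent)) 1 / 3 else e$geom_exponent
      ),
      error = function(err) stop(sprintf("model.efficiency: %s",
                                         conditionMessage(err)), call. = FALSE)
    )
  }
  mut <- mutation_model()
  if (!is.null(raw$model$mutation)) {
    check_keys(raw$model$mutation, config_keys$mutation, "model.mutation")
    m <- raw$model$mutation
    mut <- tryCatch(
      mutation_model(
        mu = if (is.null(m$mu)) 0 else m$mu,
        iota = if (is.null(m$iota)) 0 else m$iota
      ),
      error = function(err) stop(sprintf("model.mutation: %s",
                                         conditionMessage(err)), call. = FALSE)
    )
  }
  model <- tryCatch(
    ciu_model(
      curve = curve, efficiency = eff, mutation = mut,
      n_g1 = if (is.null(raw$model$n_g1)) 1 else raw$model$n_g1,
      k_max = if (is.null(raw$model$k_max)) 1000L else raw$model$k_max
    ),
    error = function(e) stop(sprintf("model: %s", conditionMessage(e)),
                             call. = FALSE)
  )
  sweep <- NULL
  if (!is.null(raw$sweep)) {
    check_keys(raw$sweep, c("axis1", "axis2"), "sweep")
    if (is.null(raw$sweep$axis1) || is.null(raw$sweep$axis2)) {
      stop("sweep needs both axis1 and axis2", call. = FALSE)
    }
    ax1 <- axis_values(raw$sweep$axis1)
    ax2 <- axis_values(raw$sweep$axis2)
    for (ax in list(ax1, ax2)) {
      set_model_param(model, ax$name, ax$values[[1]])  # validates key + domain
    }
    sweep <- list(axis1 = ax1, axis2 = ax2)
  }
  log_level <- if (is.null(raw$log_level)) "info" else raw$log_level
  if (!log_level %in% c("debug", "info", "warning", "error")) {
    stop(sprintf("invalid log_level '%s'", log_level), call. = FALSE)
  }
  structure(
    list(model = model,
         sweep = sweep,
         output = if (is.null(raw$output)) "results" else raw$output,
         seed = if (is.null(raw$seed)) 0L else as.integer(raw$seed),
         log_level = log_level),
    class = "ciu_config"
  )
}

#' Serialise a run configuration back to YAML
#'
#' Inverse of [load_config()]: writes a YAML file that loads back to an
#' equivalent configuration (sweep axes are written as explicit value lists).
#'
#' @param cfg A \code{"ciu_config"}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ciu_config"))
  m <- cfg$model
  out <- list(
    model = list(
      curve = list(form = m$curve$form, rho = m$curve$rho,
                   k_t = m$curve$k_t, shape = m$curve$shape),
      efficiency = list(alpha = m$efficiency$alpha,
                        geom_exponent = m$efficiency$geom_exponent),
      mutation = list(mu = m$mutation$mu, iota = m$mutation$iota),
      n_g1 = m$n_g1,
      k_max = m$k_max
    ),
    output = cfg$output,
    seed = cfg$seed,
    log_level = cfg$log_level
  )
  if (!is.null(cfg$sweep)) {
    out$sweep <- list(
      axis1 = list(name = cfg$sweep$axis1$name,
                   values = as.list(cfg$sweep$axis1$values)),
      axis2 = list(name = cfg$sweep$axis2$name,
                   values = as.list(cfg$sweep$axis2$values))
    )
  }
  yaml::write_yaml(out, path, precision = 12L)
  invisible(path)
}

#' Bundled sweep configurations
#'
#' Returns the path of one of the packaged sweep configurations, which cover
#' the qualitative regimes of the model: optimal size over singleton success
#' and curve shape for diminishing (\code{"fig1c"}) and threshold
#' (\code{"fig1d"}) group benefits, the same with maximal spherical
#' efficiency gains (\code{"fig2b"}), and optimal size over the defective
#' proportion against curve shape (\code{"fig3c"}) or against the interfering
#' fraction (\code{"fig3d"}).
#'
#' @param id One of \code{"fig1c"}, \code{"fig1d"}, \code{"fig2b"},
#'   \code{"fig3c"}, \code{"fig3d"}.
#' @return Path to the bundled YAML file.
#' @export
fixture_config <- function(id = c("fig1c", "fig1d", "fig2b", "fig3c",
                                  "fig3d")) {
  id <- match.arg(id)
  path <- system.file("extdata", paste0(id, ".yaml"), package = "ciuevol",
                      mustWork = TRUE)
  path
}

format_real <- function(x) {
  ifelse(is.na(x), "", sprintf("%.12g", x))
}

write_table_rfc4180 <- function(df, path) {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  on.exit(close(con))
  utils::write.table(df, con, sep = ",", row.names = FALSE, col.names = TRUE,
                     qmethod = "double", quote = which(!vapply(df, is.numeric,
                                                               logical(1))),
                     eol = "\r\n", na = "")
  invisible(path)
}

#' Write a fitness landscape as CSV
#'
#' Columns \code{k}, \code{fitness} (12 significant digits),
#' \code{is_argmax}; RFC-4180 formatting.
#'
#' @param landscape A \code{"fitness_landscape"}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  df <- as.data.frame(landscape)
  df$fitness <- format_real(df$fitness)
  df$is_argmax <- ifelse(df$is_argmax, "TRUE", "FALSE")
  write_table_rfc4180(df, path)
}

#' Write a sweep grid as long-format CSV
#'
#' Columns \code{axis1_name}, \code{axis1_value}, \code{axis2_name},
#' \code{axis2_value}, \code{k_star}, \code{favoured}, in row-major
#' axis1-then-axis2 order; reals at 12 significant digits.
#'
#' @param grid A \code{"sweep_grid"}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_sweep <- function(grid, path) {
  stopifnot(inherits(grid, "sweep_grid"))
  df <- as.data.frame(grid)
  if (is.numeric(df$axis1_value)) df$axis1_value <- format_real(df$axis1_value)
  if (is.numeric(df$axis2_value)) df$axis2_value <- format_real(df$axis2_value)
  df$favoured <- ifelse(df$favoured, "TRUE", "FALSE")
  write_table_rfc4180(df, path)
}

#' Render a sweep grid as a heatmap
#'
#' Optimal unit size as tile colour over the two sweep axes, with favoured
#' cells (\eqn{k^* > 1}) outlined -- the standard view of these sweeps.
#'
#' @param grid A \code{"sweep_grid"}.
#' @param path Output image path (\code{.png} or \code{.pdf}).
#' @param log_kstar Colour on a log scale (useful when \eqn{k^*} spans orders
#'   of magnitude); default \code{TRUE}.
#' @return \code{path}, invisibly.
#' @export
render_heatmap <- function(grid, path, log_kstar = TRUE) {
  stopifnot(inherits(grid, "sweep_grid"))
  df <- as.data.frame(grid)
  df$a1 <- as.numeric(factor(df$axis1_value, levels = unique(df$axis1_value)))
  df$a2 <- as.numeric(factor(df$axis2_value, levels = unique(df$axis2_value)))
  p <- ggplot(df, aes(x = a1, y = a2, fill = k_star)) +
    geom_tile(aes(colour = favoured), linewidth = 0.2) +
    scale_fill_viridis_c(trans = if (log_kstar) "log10" else "identity",
                         name = "k*") +
    scale_colour_manual(values = c(`TRUE` = "white", `FALSE` = NA),
                        na.value = NA, name = "CIU favoured") +
    labs(x = grid$axis1$name, y = grid$axis2$name) +
    theme_minimal()
  ggsave(path, p, width = 6, height = 4.5, dpi = 150)
  invisible(path)
}
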