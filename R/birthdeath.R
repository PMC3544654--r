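#' Constant-birth / Gamma-survivorship turnover model
#'
#' New miRNA families arise on the focal lineage at a constant rate `v` per
#' Myr; a family born at time 0 survives to age `t` with probability
#' `P(t) = 1 - GammaCDF(t; shape, scale)`, so `P(0) = 1` and `P(t) -> 0`.
#' The expected number of families born within the last `t` Myr that are
#' still extant is `N(t) = v * integral_0^t P(s) ds`, which is fitted to the
#' observed cumulative age distribution by least squares.
#'
#' @name birth_death
NULL

#' Birth-death model parameters
#'
#' @param v birth rate (new families per Myr), `>= 0`.
#' @param shape Gamma shape `k > 0` of the lifespan distribution.
#' @param scale Gamma scale `theta > 0` (Myr).
#' @return a `bd_params` list.
#' @export
bd_params <- function(v, shape, scale) {
  if (v < 0) abort("birth rate v must be >= 0")
  if (shape <= 0 || scale <= 0) abort("Gamma shape and scale must be > 0")
  structure(list(v = v, shape = shape, scale = scale), class = "bd_params")
}

#' Survivorship function P(t)
#'
#' @param t age(s) in Myr, `>= 0`.
#' @param params a [bd_params()].
#' @return `1 - pgamma(t, shape, scale = scale)`.
#' @export
bd_survival <- function(t, params) {
  if (any(t < 0)) abort("t must be >= 0")
  1 - pgamma(t, shape = params$shape, scale = params$scale)
}

#' Expected cumulative extant count N(t)
#'
#' `N(t) = v * integral_0^t P(s) ds`, evaluated with the exact identity
#' `integral_0^t (1 - F_k(s)) ds = k * theta * F_{k+1}(t) + t * (1 - F_k(t))`
#' for the Gamma CDF `F_k`. `N(0) = 0`, N is non-decreasing and concave, and
#' `N(t) -> v * shape * scale` as `t -> Inf` (mean lifespan times birth rate).
#'
#' @inheritParams bd_survival
#' @export
bd_expected_cumulative <- function(t, params) {
  if (any(t < 0)) abort("t must be >= 0")
  k <- params$shape; th <- params$scale
  integral <- k * th * pgamma(t, shape = k + 1, scale = th) +
    t * (1 - pgamma(t, shape = k, scale = th))
  params$v * integral
}

#' Birth rate, horizon survivorship and net gain
#'
#' The long-term net gain is the birth rate discounted by survivorship at the
#' horizon: `net_gain = v * P(horizon)`.
#'
#' @param params a [bd_params()].
#' @param horizon horizon in Myr, `> 0` (default 100).
#' @return a one-row tibble: `birth_rate`, `survivorship`, `net_gain`.
#' @export
bd_derived_rates <- function(params, horizon = 100) {
  if (horizon <= 0) abort("horizon must be > 0")
  p <- bd_survival(horizon, params)
  tibble(
    horizon_myr = horizon,
    birth_rate = params$v,
    survivorship = p,
    net_gain = params$v * p
  )
}

#' Solve the Gamma scale giving a target survivorship at a horizon
#'
#' Convenience for parameterising the model by `P(horizon)` instead of the
#' scale: finds `theta` with `1 - pgamma(horizon, shape, scale = theta) = p`.
#'
#' @param shape Gamma shape.
#' @param horizon horizon in Myr.
#' @param p target survivorship in (0, 1).
#' @export
bd_scale_for_survival <- function(shape, horizon, p) {
  if (p <= 0 || p >= 1) abort("target survivorship must be in (0, 1)")
  f <- function(th) pgamma(horizon, shape = shape, scale = th) - (1 - p)
  stats::uniroot(f, lower = horizon * 1e-6, upper = horizon * 1e6, tol = 1e-12)$root
}

#' Observed cumulative age counts from age assignments
#'
#' Bins family ages at the root-to-focal node times of the tree and accumulates
#' from the youngest interval: the count at node time `t_r` is the number of
#' extant families with origin in intervals `t0..t(r-1)`, i.e. families younger
#' than `t_r` Myr.
#'
#' @param assignments tibble with `age_index` (from [assign_ages()]).
#' @param tree a [species_tree()].
#' @return a tibble with `time_myr` and `cumulative` (one row per path node).
#' @export
observed_cumulative <- function(assignments, tree) {
  k <- nrow(tree$path)
  per <- tabulate(assignments$age_index + 1L, nbins = k + 1L)
  tibble(
    time_myr = tree$path$time_myr,
    cumulative = cumsum(per)[1:k]
  )
}

#' Fit the birth-death model by least squares
#'
#' Minimises the sum of squared differences between observed and expected
#' cumulative counts over `(v, shape, scale)`, log-parameterised for
#' positivity, with `nlminb` started from a 3 x 3 x 3 multistart grid. The
#' shallow SSE surface leaves (shape, scale) only weakly identified from a few
#' coarse bins; the stable combination `v * shape * scale` (the asymptotic
#' extant count) is reported alongside.
#'
#' @param observed tibble/data frame with columns `time_myr` and `cumulative`
#'   (non-negative, non-decreasing in time), e.g. from [observed_cumulative()].
#' @return a `bd_fit` object; see [tidy()] and [glance()] methods.
#' @export
bd_fit <- function(observed) {
  observed <- as_tibble(observed)
  for (cn in c("time_myr", "cumulative")) {
    if (!cn %in% names(observed)) abort(paste0("observed needs column '", cn, "'"))
  }
  observed <- arrange(observed, .data$time_myr)
  t <- observed$time_myr
  y <- observed$cumulative
  if (length(t) < 4) abort("need at least 4 time points to fit 3 parameters")
  if (any(y < 0)) abort("counts must be non-negative")
  if (any(diff(y) < 0)) abort("cumulative counts must be non-decreasing in time")
  if (all(y == 0)) abort("all-zero counts cannot constrain the model")

  sse <- function(lp) {
    p <- bd_params(exp(lp[1]), exp(lp[2]), exp(lp[3]))
    sum((bd_expected_cumulative(t, p) - y)^2)
  }
  # multistart grid: v around the crude recent slope, shape around 1,
  # scale around a fraction of the observed span
  slope <- max(y) / max(t)
  starts <- expand.grid(
    v = log(pmax(slope * c(1, 10, 100), 1e-6)),
    shape = log(c(0.5, 1, 2)),
    scale = log(max(t) * c(0.02, 0.1, 0.5))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      nlminb(as.numeric(starts[i, ]), sse,
             control = list(iter.max = 500, eval.max = 800)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) abort("birth-death fit failed from every start")
  params <- bd_params(exp(best$par[1]), exp(best$par[2]), exp(best$par[3]))
  fitted <- bd_expected_cumulative(t, params)
  structure(
    list(
      params = params,
      sse = best$objective,
      converged = best$convergence == 0,
      observed = observed,
      fitted = tibble(time_myr = t, observed = y, fitted = fitted),
      asymptote = params$v * params$shape * params$scale,
      n = length(t)
    ),
    class = "bd_fit"
  )
}

#' @export
print.bd_fit <- function(x, ...) {
  cat("Birth-death fit (constant birth, Gamma survivorship)\n")
  cat(sprintf("  v = %.3f /Myr, shape = %.3f, scale = %.3f Myr\n",
              x$params$v, x$params$shape, x$params$scale))
  cat(sprintf("  SSE = %.4g over %d time points; converged: %s\n",
              x$sse, x$n, x$converged))
  cat(sprintf("  asymptotic extant count v*shape*scale = %.1f\n", x$asymptote))
  invisible(x)
}

#' @export
tidy.bd_fit <- function(x, ...) {
  tibble(
    term = c("birth_rate", "gamma_shape", "gamma_scale"),
    estimate = c(x$params$v, x$params$shape, x$params$scale)
  )
}

#' @export
glance.bd_fit <- function(x, ...) {
  tibble(
    sse = x$sse,
    converged = x$converged,
    n = x$n,
    asymptote = x$asymptote
  )
}

#' @export
autoplot.bd_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$fitted, c("observed", "fitted"),
                            names_to = "series", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_myr, y = .data$count,
                                   colour = .data$series)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$series == "fitted")) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$series == "observed")) +
    ggplot2::labs(x = "age (Myr)", y = "cumulative extant families",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tab-delimited fit report
#'
#' @param fit a `bd_fit`.
#' @param path output path.
#' @param horizon horizon (Myr) for derived rates.
#' @export
write_bd_report <- function(fit, path, horizon = 100) {
  rates <- bd_derived_rates(fit$params, horizon)
  report <- tibble(
    quantity = c("birth_rate_per_myr", "gamma_shape", "gamma_scale_myr",
                 "sse", "converged", "asymptotic_count",
                 paste0("survivorship_", horizon, "myr"),
                 paste0("net_gain_per_myr_", horizon, "myr")),
    value = c(fit$params$v, fit$params$shape, fit$params$scale,
              fit$sse, as.numeric(fit$converged), fit$asymptote,
              rates$survivorship, rates$net_gain)
  )
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
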