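#' Parameters for a lognormal AR(1) invader trajectory
#'
#' Generator settings for synthetic invader abundance / shell-production
#' trajectories. On the natural-log scale the series is a stationary
#' first-order autoregression with mean `log(mean_level)`, marginal
#' standard deviation `log_sd` and lag-1 autocorrelation `autocorr`; the
#' exponentiated series is therefore lognormal with geometric mean
#' `mean_level` and strictly positive values.
#'
#' The defaults (25 years, `log_sd = 0.61`, `autocorr = 0.3`) mimic a
#' moderately variable riverine dreissenid population whose year-to-year
#' biomass variation spans approximately an order of magnitude: under the
#' defaults the median max/min ratio of a trajectory is ~10 across seeds.
#'
#' @param n_years Series length in years (>= 1).
#' @param mean_level Geometric mean of the series, in abundance or
#'   production units (default 1 kg/m^2/yr).
#' @param log_sd Marginal standard deviation on the log scale (>= 0).
#' @param autocorr Lag-1 autocorrelation in \[0, 1).
#' @param seed Optional integer seed baked into the parameters.
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(n_years = 25, mean_level = 1,
                              log_sd = 0.61, autocorr = 0.3, seed = NULL) {
  if (n_years < 1) stop("`n_years` must be at least 1", call. = FALSE)
  if (mean_level <= 0) stop("`mean_level` must be positive", call. = FALSE)
  if (log_sd < 0) stop("`log_sd` must be non-negative", call. = FALSE)
  if (autocorr < 0 || autocorr >= 1) {
    stop("`autocorr` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_years = as.integer(n_years), mean_level = mean_level,
                 log_sd = log_sd, autocorr = autocorr, seed = seed),
            class = "trajectory_params")
}

# deterministic per-component seed derivation, kept below 2^31
derive_seed <- function(master, index, salt = 1L) {
  (as.numeric(master) * 7919 + as.numeric(index) * 104729 +
     as.numeric(salt) * 15485863) %% 2147483629
}

#' Generate a synthetic invader trajectory
#'
#' Draws a lognormal AR(1) series: log values `z_t` follow
#' `z_1 ~ N(mu, sd^2)`, `z_t = mu + phi (z_{t-1} - mu) + eps_t` with
#' `eps_t ~ N(0, sd^2 (1 - phi^2))`, so the log-series is stationary with
#' the specified mean, sd and autocorrelation at every `t`; values are
#' `exp(z_t)`. Deterministic under `seed`: the same seed always yields the
#' same series.
#'
#' @param params [trajectory_params()].
#' @param seed Integer seed; overrides `params$seed` if given.
#' @return A [production_series()] on year marks `1..n_years`.
#' @examples
#' generate_trajectory(trajectory_params(seed = 42))
#' @export
generate_trajectory <- function(params = trajectory_params(), seed = NULL) {
  stopifnot(inherits(params, "trajectory_params"))
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_years
  mu <- log(params$mean_level)
  sd <- params$log_sd
  phi <- params$autocorr
  z <- numeric(n)
  z[1L] <- stats::rnorm(1L, mu, sd)
  if (n > 1L) {
    innov_sd <- sd * sqrt(1 - phi^2)
    eps <- stats::rnorm(n - 1L, 0, innov_sd)
    for (t in 2:n) z[t] <- mu + phi * (z[t - 1L] - mu) + eps[t - 1L]
  }
  production_series(seq_len(n), exp(z))
}

#' Hudson-like production trajectory preset
#'
#' Convenience wrapper: a [trajectory_params()] with the default
#' order-of-magnitude calibration, optionally longer than 25 years (the
#' shell model's slow-dissolution coupling diagnostic needs a long record
#' to outlast its burn-in).
#'
#' @param n_years Series length (default 25).
#' @param seed Optional seed.
#' @return A `trajectory_params` object.
#' @export
hudson_trajectory <- function(n_years = 25, seed = NULL) {
  trajectory_params(n_years = n_years, seed = seed)
}

# largest-remainder apportionment of n among proportions
largest_remainder <- function(n, proportions) {
  quota <- n * proportions
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    frac <- quota - counts
    take <- order(frac, decreasing = TRUE)[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Realize a landscape: assign types and generate per-lake trajectories
#'
#' Assigns each lake an ecosystem type by largest-remainder rounding of
#' `n_lakes * proportions` (so realized counts match the proportions as
#' closely as integers allow; ties broken by type order), then generates an
#' independent abundance trajectory per lake. Per-lake seeds are derived
#' deterministically from `(seed, lake index)`, so the landscape is
#' reproducible and adding lakes does not perturb existing ones.
#'
#' @param spec [landscape()].
#' @param seed Integer master seed.
#' @return A list of class `realized_landscape`: `lakes` (each a list
#'   `id`, `type_index`, `trajectory`), `type_counts`, `seed`.
#' @examples
#' ls <- landscape(list(ecosystem_type(3), ecosystem_type(1), ecosystem_type(0.2)),
#'                 c(0.6, 0.3, 0.1), n_lakes = 10)
#' generate_landscape(ls, seed = 1)$type_counts
#' @export
generate_landscape <- function(spec, seed) {
  stopifnot(inherits(spec, "landscape"))
  counts <- largest_remainder(spec$n_lakes, spec$proportions)
  type_of_lake <- rep(seq_along(spec$types), counts)
  lakes <- lapply(seq_len(spec$n_lakes), function(i) {
    tp <- if (spec$per_type_trajectory) {
      spec$trajectory[[type_of_lake[i]]]
    } else {
      spec$trajectory
    }
    list(id = i, type_index = type_of_lake[i],
         trajectory = generate_trajectory(tp, seed = derive_seed(seed, i)))
  })
  labels <- vapply(spec$types, `[[`, character(1), "label")
  labels <- ifelse(nzchar(labels), labels, paste0("type", seq_along(labels)))
  structure(list(lakes = lakes,
                 type_counts = stats::setNames(counts, labels),
                 seed = seed),
            class = "realized_landscape")
}

#' @export
print.realized_landscape <- function(x, ...) {
  cat(sprintf("Realized landscape: %d lakes (seed %s); type counts: %s\n",
              length(x$lakes), format(x$seed),
              paste(sprintf("%s = %d", names(x$type_counts), x$type_counts),
                    collapse = ", ")))
  invisible(x)
}
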