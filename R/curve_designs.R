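#' Abundance-impact curve
#'
#' Ordered (abundance, impact) pairs with an explicit record of which of the
#' three non-interchangeable curve formulations they represent:
#' `within_system` (points from one ecosystem over time or treatments),
#' `snapshot` (single visits to many ecosystems), or `long_term` (long-term
#' means of many ecosystems).
#'
#' @param abundance Non-negative invader abundances (density, biomass,
#'   production or filtration rate — whatever metric fits the impact).
#' @param impact Impact values, same length.
#' @param kind One of `"within_system"`, `"snapshot"`, `"long_term"`.
#' @param source_label Free-text provenance label.
#' @param extra Optional data frame of extra per-point columns to carry.
#' @return A data frame of class `abundance_impact_curve` with columns
#'   `abundance` and `impact` (plus any extras) and attributes `kind` and
#'   `source_label`.
#' @export
abundance_impact_curve <- function(abundance, impact,
                                   kind = c("within_system", "snapshot", "long_term"),
                                   source_label = "", extra = NULL) {
  kind <- match.arg(kind)
  abundance <- as.numeric(abundance)
  impact <- as.numeric(impact)
  if (length(abundance) != length(impact)) {
    stop("`abundance` and `impact` must have equal length", call. = FALSE)
  }
  if (any(abundance < 0)) stop("abundances must be non-negative", call. = FALSE)
  df <- data.frame(abundance = abundance, impact = impact)
  if (!is.null(extra)) df <- cbind(df, extra)
  structure(df, class = c("abundance_impact_curve", "data.frame"),
            kind = kind, source_label = source_label)
}

#' @export
print.abundance_impact_curve <- function(x, ...) {
  cat(sprintf("Abundance-impact curve [%s]%s: %d points, abundance %g-%g\n",
              attr(x, "kind"),
              if (nzchar(attr(x, "source_label"))) paste0(" (", attr(x, "source_label"), ")") else "",
              nrow(x), min(x$abundance), max(x$abundance)))
  invisible(x)
}

#' @export
plot.abundance_impact_curve <- function(x, ...,
                                        xlab = "Invader abundance",
                                        ylab = "Impact") {
  graphics::plot(x$abundance, x$impact, xlab = xlab, ylab = ylab,
                 main = attr(x, "kind"), ...)
  invisible(x)
}

#' Curve kind accessor
#' @param curve An [abundance_impact_curve].
#' @return The curve's kind string.
#' @export
curve_kind <- function(curve) attr(curve, "kind")

#' Ecosystem type with a within-system impact response
#'
#' An ecosystem type is characterised by its within-system abundance-impact
#' response. The canonical case is linear through the origin (zero invader,
#' zero impact) with a type-specific slope; an arbitrary response function
#' can be supplied to study nonlinear (e.g. convex or saturating) types.
#'
#' @param slope Impact per unit abundance of the linear response.
#' @param label Free-text type name.
#' @param response Optional function `f(abundance) -> impact` overriding the
#'   linear response (the `slope` is still recorded for reporting).
#' @return An object of class `ecosystem_type`.
#' @export
ecosystem_type <- function(slope, label = "", response = NULL) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope)) {
    stop("`slope` must be a single finite number", call. = FALSE)
  }
  if (is.null(response)) {
    force(slope)
    response <- function(abundance) slope * abundance
    linear <- TRUE
  } else {
    stopifnot(is.function(response))
    linear <- FALSE
  }
  structure(list(slope = slope, label = as.character(label)[1L],
                 response = response, linear = linear),
            class = "ecosystem_type")
}

#' Landscape of lakes holding several ecosystem types
#'
#' A landscape is a mixture of ecosystem types in given proportions, with an
#' invader-abundance trajectory generator shared by all lakes (or supplied
#' per type). Lakes are assigned to types by largest-remainder rounding of
#' `n_lakes * proportions` so that realized counts match the proportions as
#' closely as integers allow.
#'
#' @param types List of [ecosystem_type()] objects.
#' @param proportions Non-negative fractions, one per type, summing to 1.
#' @param n_lakes Number of lakes (>= 1).
#' @param trajectory A [trajectory_params()], or a list of one per type.
#' @return An object of class `landscape`.
#' @seealso [generate_landscape()], [snapshot_sample()], [long_term_sample()]
#' @export
landscape <- function(types, proportions, n_lakes,
                      trajectory = trajectory_params()) {
  if (length(types) == 0L) stop("landscape needs at least one ecosystem type", call. = FALSE)
  stopifnot(all(vapply(types, inherits, logical(1), "ecosystem_type")))
  if (length(proportions) != length(types)) {
    stop("`proportions` must match `types` in length", call. = FALSE)
  }
  if (any(proportions < 0)) stop("`proportions` must be non-negative", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("`proportions` must sum to 1", call. = FALSE)
  }
  if (n_lakes < 1) stop("`n_lakes` must be at least 1", call. = FALSE)
  per_type <- is.list(trajectory) && !inherits(trajectory, "trajectory_params")
  if (per_type) {
    stopifnot(length(trajectory) == length(types),
              all(vapply(trajectory, inherits, logical(1), "trajectory_params")))
  } else {
    stopifnot(inherits(trajectory, "trajectory_params"))
  }
  structure(list(types = types, proportions = as.numeric(proportions),
                 n_lakes = as.integer(n_lakes), trajectory = trajectory,
                 per_type_trajectory = per_type),
            class = "landscape")
}

#' Within-system abundance-impact curve of one ecosystem type
#'
#' Evaluates a type's within-system response on a set of abundances.
#'
#' @param type [ecosystem_type()].
#' @param abundances Non-negative abundances.
#' @return An [abundance_impact_curve] of kind `within_system`.
#' @examples
#' within_system_curve(ecosystem_type(2), 0:3)
#' @export
within_system_curve <- function(type, abundances) {
  stopifnot(inherits(type, "ecosystem_type"))
  abundance_impact_curve(abundances, type$response(abundances),
                         kind = "within_system", source_label = type$label)
}

#' Cross-system snapshot sample of a landscape
#'
#' Visits every lake in the landscape once: each lake is assigned its type,
#' a single year is drawn uniformly at random from the lake's abundance
#' trajectory, and the impact is computed from that lake's within-system
#' response at the drawn abundance. This is the "horizontal"
#' (space-for-time) sampling design; the pooled points generally do not
#' trace any single within-system curve.
#'
#' Fixed abundances can be supplied instead of trajectory draws (e.g. an
#' evenly spaced density layout), one per lake in lake order.
#'
#' @param landscape [landscape()].
#' @param seed Integer seed; identical seeds reproduce identical samples
#'   bit-for-bit.
#' @param abundances Optional numeric vector of length `n_lakes` overriding
#'   the random year draw.
#' @return An [abundance_impact_curve] of kind `snapshot` with per-point
#'   columns `lake_id` and `type`.
#' @export
snapshot_sample <- function(landscape, seed, abundances = NULL) {
  stopifnot(inherits(landscape, "landscape"))
  real <- generate_landscape(landscape, seed)
  n <- landscape$n_lakes
  if (is.null(abundances)) {
    set.seed(derive_seed(seed, 0L, salt = 2L))
    ab <- vapply(real$lakes, function(lk) {
      vals <- lk$trajectory$production
      vals[sample.int(length(vals), 1L)]
    }, numeric(1))
  } else {
    if (length(abundances) != n) {
      stop("`abundances` must supply one value per lake", call. = FALSE)
    }
    ab <- as.numeric(abundances)
  }
  type_idx <- vapply(real$lakes, `[[`, integer(1), "type_index")
  imp <- vapply(seq_len(n), function(i) {
    landscape$types[[type_idx[i]]]$response(ab[i])
  }, numeric(1))
  labels <- vapply(landscape$types, `[[`, character(1), "label")
  abundance_impact_curve(
    ab, imp, kind = "snapshot", source_label = "landscape snapshot",
    extra = data.frame(
      lake_id = seq_len(n),
      type = ifelse(nzchar(labels[type_idx]), labels[type_idx],
                    paste0("type", type_idx))
    )
  )
}

#' Cross-system long-term sample of a landscape
#'
#' Revisits every lake over `n_years` and records the long-term mean
#' abundance and the long-term mean impact (the mean of the within-system
#' response evaluated year by year). For a linear response the point falls
#' exactly on the within-system line; for a nonlinear response the mean
#' impact differs from the response at the mean abundance (Jensen's
#' inequality), which is what separates the long-term from the snapshot
#' curve.
#'
#' @param landscape [landscape()].
#' @param n_years Number of years to average (>= 2); defaults to the full
#'   trajectory length.
#' @param seed Integer seed.
#' @return An [abundance_impact_curve] of kind `long_term` with per-point
#'   columns `lake_id` and `type`.
#' @export
long_term_sample <- function(landscape, n_years = NULL, seed = 1L) {
  stopifnot(inherits(landscape, "landscape"))
  real <- generate_landscape(landscape, seed)
  n <- landscape$n_lakes
  mean_ab <- numeric(n); mean_imp <- numeric(n); type_idx <- integer(n)
  for (i in seq_len(n)) {
    lk <- real$lakes[[i]]
    vals <- lk$trajectory$production
    ny <- if (is.null(n_years)) length(vals) else n_years
    if (ny < 2L) stop("`n_years` must be at least 2", call. = FALSE)
    if (ny > length(vals)) {
      stop("`n_years` exceeds the trajectory length", call. = FALSE)
    }
    vals <- vals[seq_len(ny)]
    type_idx[i] <- lk$type_index
    mean_ab[i] <- mean(vals)
    mean_imp[i] <- mean(landscape$types[[lk$type_index]]$response(vals))
  }
  labels <- vapply(landscape$types, `[[`, character(1), "label")
  abundance_impact_curve(
    mean_ab, mean_imp, kind = "long_term", source_label = "landscape long-term means",
    extra = data.frame(
      lake_id = seq_len(n),
      type = ifelse(nzchar(labels[type_idx]), labels[type_idx],
                    paste0("type", type_idx))
    )
  )
}

#' Ordinary least-squares line through an abundance-impact curve
#'
#' Fits the unconstrained OLS line through all points, as a field analyst
#' would fit a pooled regression through a cross-system data set.
#'
#' @param curve [abundance_impact_curve] with at least 2 distinct abundances.
#' @return An object of class `curve_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`, and the curve `kind` it was fitted to.
#' @examples
#' fit_linear(within_system_curve(ecosystem_type(3), 0:4))
#' @export
fit_linear <- function(curve) {
  stopifnot(inherits(curve, "abundance_impact_curve"))
  if (length(unique(curve$abundance)) < 2L) {
    stop("need at least 2 distinct abundances to fit a line", call. = FALSE)
  }
  fit <- stats::lm(impact ~ abundance, data = curve)
  # r^2 from sums of squares directly; summary.lm warns on exact fits
  sse <- sum(stats::resid(fit)^2)
  sst <- sum((curve$impact - mean(curve$impact))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = if (sst > 0) 1 - sse / sst else 1,
                 n = nrow(curve),
                 kind = attr(curve, "kind")),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("OLS fit [%s]: impact = %.4g + %.4g * abundance (r^2 = %.3f, n = %d)\n",
              x$kind, x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Average and marginal per-capita effects
#'
#' At a given abundance on a curve, the average per-capita effect is
#' `impact / abundance` and the marginal per-capita effect is the local
#' slope of the curve. Both are read off a linear interpolant of the
#' curve's points; the marginal effect uses a centered finite difference
#' (one-sided at the range boundaries). The two coincide everywhere only
#' for a line through the origin.
#'
#' @param curve [abundance_impact_curve] with at least 2 distinct abundances.
#' @param abundance Abundance within the curve's observed range.
#' @return List with `average` (`NA` with `average_defined = FALSE` at
#'   abundance 0) and `marginal`.
#' @examples
#' sq <- abundance_impact_curve(seq(0, 4, 0.01), seq(0, 4, 0.01)^2, "within_system")
#' per_capita_effects(sq, 2)  # average 2, marginal 4
#' @export
per_capita_effects <- function(curve, abundance) {
  stopifnot(inherits(curve, "abundance_impact_curve"))
  o <- order(curve$abundance)
  x <- curve$abundance[o]; y <- curve$impact[o]
  keep <- !duplicated(x)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 distinct abundances", call. = FALSE)
  if (abundance < min(x) || abundance > max(x)) {
    stop("`abundance` must lie within the curve's observed range", call. = FALSE)
  }
  f <- stats::approxfun(x, y)
  h <- (max(x) - min(x)) / 1000
  lo <- max(abundance - h, min(x))
  hi <- min(abundance + h, max(x))
  marginal <- (f(hi) - f(lo)) / (hi - lo)
  if (abundance == 0) {
    list(average = NA_real_, marginal = marginal, average_defined = FALSE)
  } else {
    list(average = f(abundance) / abundance, marginal = marginal,
         average_defined = TRUE)
  }
}

#' Compare the three sampling designs on one landscape
#'
#' Builds the per-type within-system slopes, a pooled snapshot fit and a
#' pooled long-term fit on the same landscape, and reports how the
#' cross-system fits relate to the within-system truth: slope differences,
#' sign-agreement flags, and the mean absolute error of each pooled line's
#' predictions against each within-system line over the observed abundance
#' range. All three agree (up to fitting noise) only when the landscape has
#' a single type with a linear response.
#'
#' @param landscape [landscape()].
#' @param seed Integer seed.
#' @param n_years Years averaged for the long-term design (default: full
#'   trajectory).
#' @param abundances Optional fixed per-lake abundances for the snapshot
#'   design (see [snapshot_sample()]).
#' @return An object of class `design_comparison`: `within_slopes`,
#'   `snapshot_fit`, `long_term_fit`, `snapshot`, `long_term` (the point
#'   sets), and a `discrepancy` data frame (design, type, slope_diff,
#'   sign_agreement, mean_abs_pred_error).
#' @export
compare_designs <- function(landscape, seed, n_years = NULL, abundances = NULL) {
  stopifnot(inherits(landscape, "landscape"))
  snap <- snapshot_sample(landscape, seed, abundances = abundances)
  lt <- long_term_sample(landscape, n_years = n_years, seed = seed)
  snap_fit <- fit_linear(snap)
  lt_fit <- fit_linear(lt)
  within <- vapply(landscape$types, `[[`, numeric(1), "slope")
  labels <- vapply(landscape$types, `[[`, character(1), "label")
  labels <- ifelse(nzchar(labels), labels, paste0("type", seq_along(within)))
  rng <- range(snap$abundance)
  grid <- seq(rng[1L], rng[2L], length.out = 101L)
  disc <- do.call(rbind, lapply(seq_along(within), function(j) {
    truth <- within[j] * grid
    rows <- lapply(list(snapshot = snap_fit, long_term = lt_fit), function(f) {
      pred <- f$intercept + f$slope * grid
      data.frame(type = labels[j],
                 slope_diff = f$slope - within[j],
                 sign_agreement = sign(f$slope) == sign(within[j]),
                 mean_abs_pred_error = mean(abs(pred - truth)))
    })
    cbind(design = names(rows), do.call(rbind, rows), row.names = NULL)
  }))
  structure(list(within_slopes = stats::setNames(within, labels),
                 snapshot_fit = snap_fit, long_term_fit = lt_fit,
                 snapshot = snap, long_term = lt, discrepancy = disc),
            class = "design_comparison")
}

#' @export
print.design_comparison <- function(x, ...) {
  cat("Sampling-design comparison\n")
  cat("  within-system slopes: ",
      paste(sprintf("%s = %.4g", names(x$within_slopes), x$within_slopes),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  pooled snapshot slope:  %.4g (r^2 = %.3f)\n",
              x$snapshot_fit$slope, x$snapshot_fit$r_squared))
  cat(sprintf("  pooled long-term slope: %.4g (r^2 = %.3f)\n",
              x$long_term_fit$slope, x$long_term_fit$r_squared))
  if (!all(x$discrepancy$sign_agreement)) {
    cat("  WARNING: a pooled slope disagrees in sign with a within-system slope\n")
  }
  invisible(x)
}
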