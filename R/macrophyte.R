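#' Chlorophyll response to mussel filtration
#'
#' Parameters of the exponential decline of phytoplankton biomass with
#' dreissenid population filtration rate:
#' `chl_post = f_r chl_pre + f_l chl_pre exp(-c DFR)`,
#' where `DFR` is the population filtration rate in % of the water column
#' per day, `f_r` the refractory fraction of chlorophyll that filtration
#' cannot remove, `f_l = 1 - f_r` the labile fraction, and `c` the decay
#' coefficient per (%/day).
#'
#' @param refractory_fraction Fraction of pre-invasion chlorophyll immune to
#'   filtration (default 0.2).
#' @param labile_fraction Fraction removed exponentially (default 0.8).
#' @param decay_coeff Decay rate per unit DFR (default 0.0347).
#' @return An object of class `chl_response_params`.
#' @export
chl_response_params <- function(refractory_fraction = 0.2,
                                labile_fraction = 0.8,
                                decay_coeff = 0.0347) {
  if (refractory_fraction < 0 || labile_fraction < 0 || decay_coeff < 0) {
    stop("chlorophyll-response coefficients must be non-negative", call. = FALSE)
  }
  if (abs(refractory_fraction + labile_fraction - 1) > 1e-8) {
    stop("refractory_fraction + labile_fraction must equal 1", call. = FALSE)
  }
  structure(list(refractory_fraction = refractory_fraction,
                 labile_fraction = labile_fraction,
                 decay_coeff = decay_coeff),
            class = "chl_response_params")
}

#' Chlorophyll-Secchi regression
#'
#' Log-log regression of water clarity on phytoplankton biomass:
#' `log10(Secchi) = slope * log10(chl) + intercept` (Secchi in m,
#' chlorophyll in ug/L). Defaults are the classical eutrophication-survey
#' coefficients (-0.473, 0.803).
#'
#' @param slope Regression slope (< 0: clarity decreases with chlorophyll).
#' @param intercept Regression intercept.
#' @return An object of class `secchi_model`.
#' @export
secchi_model <- function(slope = -0.473, intercept = 0.803) {
  if (slope >= 0) stop("`slope` must be negative", call. = FALSE)
  structure(list(slope = slope, intercept = intercept), class = "secchi_model")
}

#' Underwater light model
#'
#' Beer-Lambert light attenuation tied to Secchi depth: the extinction
#' coefficient is `eta = secchi_extinction_product / Secchi` (default
#' product 1.7, the standard limnological constant), and submersed
#' macrophytes survive down to the depth reached by `survival_light_fraction`
#' of surface light (default 0.05).
#'
#' @param secchi_extinction_product Dimensionless product `eta * Secchi`
#'   (default 1.7).
#' @param survival_light_fraction Fraction of surface light at the deepest
#'   colonizable depth, in (0, 1] (default 0.05).
#' @return An object of class `light_model`.
#' @export
light_model <- function(secchi_extinction_product = 1.7,
                        survival_light_fraction = 0.05) {
  if (secchi_extinction_product <= 0) {
    stop("`secchi_extinction_product` must be positive", call. = FALSE)
  }
  if (survival_light_fraction <= 0 || survival_light_fraction > 1) {
    stop("`survival_light_fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(secchi_extinction_product = secchi_extinction_product,
                 survival_light_fraction = survival_light_fraction),
            class = "light_model")
}

#' Lake hypsography (cumulative plan-area over depth)
#'
#' A bathymetry maps depth `z` to the fraction of the lake's plan (surface)
#' area whose bottom is shallower than `z` — the hypsographic curve. Three
#' kinds are supported.
#'
#' `conical_bathymetry(max_depth)`: a right circular cone; the cumulative
#' fraction is `1 - (1 - z/max_depth)^2`, a function of `z/max_depth` only.
#'
#' `shelf_bathymetry()`: an intermediate-depth basin with a pronounced
#' shallow shelf. A fraction `shelf_area_fraction` of the plan area lies on
#' the shelf, spread uniformly between `shelf_top` and `shelf_bottom`; the
#' remaining area is distributed with a single uniform slope over the full
#' depth range.
#'
#' `tabulated_bathymetry(depth, area_fraction)`: linear interpolation of a
#' measured hypsographic table (must be non-decreasing, 0 at the surface,
#' 1 at maximum depth).
#'
#' @param max_depth Maximum depth, m.
#' @param shelf_top,shelf_bottom Depth range of the shelf, m.
#' @param shelf_area_fraction Fraction of plan area on the shelf.
#' @param depth,area_fraction Vectors tabulating the hypsographic curve.
#' @return An object of class `bathymetry` with fields `kind`, `max_depth`
#'   and the cumulative-area function.
#' @examples
#' colonizable_fraction(conical_bathymetry(50), 25)  # 0.75
#' @name bathymetry
NULL

new_bathymetry <- function(kind, max_depth, fun, extra = list()) {
  structure(c(list(kind = kind, max_depth = max_depth, fun = fun), extra),
            class = "bathymetry")
}

#' @rdname bathymetry
#' @export
conical_bathymetry <- function(max_depth) {
  if (max_depth <= 0) stop("`max_depth` must be positive", call. = FALSE)
  fun <- function(z) 1 - (1 - z / max_depth)^2
  new_bathymetry("conical", max_depth, fun)
}

#' @rdname bathymetry
#' @export
shelf_bathymetry <- function(max_depth = 15, shelf_top = 2.5,
                             shelf_bottom = 3, shelf_area_fraction = 0.5) {
  if (max_depth <= 0) stop("`max_depth` must be positive", call. = FALSE)
  if (!(0 <= shelf_top && shelf_top < shelf_bottom && shelf_bottom <= max_depth)) {
    stop("need 0 <= shelf_top < shelf_bottom <= max_depth", call. = FALSE)
  }
  if (shelf_area_fraction < 0 || shelf_area_fraction >= 1) {
    stop("`shelf_area_fraction` must lie in [0, 1)", call. = FALSE)
  }
  fun <- function(z) {
    ramp <- pmin(pmax((z - shelf_top) / (shelf_bottom - shelf_top), 0), 1)
    (1 - shelf_area_fraction) * z / max_depth + shelf_area_fraction * ramp
  }
  new_bathymetry("shelf", max_depth, fun,
                 list(shelf_top = shelf_top, shelf_bottom = shelf_bottom,
                      shelf_area_fraction = shelf_area_fraction))
}

#' @rdname bathymetry
#' @export
tabulated_bathymetry <- function(depth, area_fraction) {
  if (length(depth) != length(area_fraction) || length(depth) < 2L) {
    stop("`depth` and `area_fraction` must be equal-length vectors (>= 2)",
         call. = FALSE)
  }
  o <- order(depth)
  depth <- depth[o]; area_fraction <- area_fraction[o]
  if (depth[1L] != 0 || abs(area_fraction[1L]) > 1e-8) {
    stop("hypsographic table must start at (0, 0)", call. = FALSE)
  }
  if (abs(area_fraction[length(area_fraction)] - 1) > 1e-8) {
    stop("hypsographic table must reach area fraction 1 at maximum depth",
         call. = FALSE)
  }
  if (any(diff(area_fraction) < -1e-12)) {
    stop("hypsographic curve must be non-decreasing in depth", call. = FALSE)
  }
  fun <- stats::approxfun(depth, area_fraction, rule = 2)
  new_bathymetry("tabulated", max(depth), fun)
}

#' @export
print.bathymetry <- function(x, ...) {
  cat(sprintf("Bathymetry (%s): max depth %g m\n", x$kind, x$max_depth))
  invisible(x)
}

#' Lake scenario for the macrophyte-habitat model
#'
#' Bundles a lake's hypsography, pre-invasion chlorophyll and the three
#' model components (chlorophyll response, Secchi regression, light model).
#'
#' @param bathymetry A [bathymetry] object.
#' @param chl_pre Pre-invasion chlorophyll concentration, ug/L (> 0).
#' @param response [chl_response_params()].
#' @param secchi [secchi_model()].
#' @param light [light_model()].
#' @param label Optional scenario name.
#' @return An object of class `lake_scenario`.
#' @seealso [lake_presets()] for the six canonical lake x productivity
#'   combinations.
#' @export
lake_scenario <- function(bathymetry, chl_pre,
                          response = chl_response_params(),
                          secchi = secchi_model(),
                          light = light_model(),
                          label = "") {
  stopifnot(inherits(bathymetry, "bathymetry"),
            inherits(response, "chl_response_params"),
            inherits(secchi, "secchi_model"),
            inherits(light, "light_model"))
  if (chl_pre <= 0) stop("`chl_pre` must be positive", call. = FALSE)
  structure(list(bathymetry = bathymetry, chl_pre = chl_pre,
                 response = response, secchi = secchi, light = light,
                 label = as.character(label)[1L]),
            class = "lake_scenario")
}

#' Canonical lake scenarios
#'
#' The six model lakes: shallow (5 m conical), deep (50 m conical) and
#' shelf (15 m with a pronounced shelf at 2.5-3 m) basins, each run as an
#' unproductive (pre-invasion chlorophyll 3 ug/L) and a productive
#' (30 ug/L) lake.
#'
#' @return Named list of [lake_scenario()] objects.
#' @export
lake_presets <- function() {
  baths <- list(shallow = conical_bathymetry(5),
                deep    = conical_bathymetry(50),
                shelf   = shelf_bathymetry())
  chl <- c(unproductive = 3, productive = 30)
  out <- list()
  for (b in names(baths)) {
    for (p in names(chl)) {
      nm <- paste(b, p, sep = "-")
      out[[nm]] <- lake_scenario(baths[[b]], chl[[p]], label = nm)
    }
  }
  out
}

#' Post-invasion chlorophyll concentration
#'
#' `chl_post = f_r chl_pre + f_l chl_pre exp(-c DFR)`. Strictly decreasing
#' in `dfr` and bounded below by the refractory floor `f_r * chl_pre`.
#'
#' @param chl_pre Pre-invasion chlorophyll, ug/L (> 0).
#' @param dfr Population filtration rate, % of water column/day (>= 0).
#'   Vectorized.
#' @param params [chl_response_params()].
#' @return Post-invasion chlorophyll, ug/L.
#' @examples
#' chl_post(30, 20)      # ~18 ug/L
#' chl_post(30, 1e4)     # -> 6, the refractory floor
#' @export
chl_post <- function(chl_pre, dfr, params = chl_response_params()) {
  stopifnot(inherits(params, "chl_response_params"))
  if (any(chl_pre <= 0)) stop("`chl_pre` must be positive", call. = FALSE)
  if (any(dfr < 0)) stop("`dfr` must be non-negative", call. = FALSE)
  params$refractory_fraction * chl_pre +
    params$labile_fraction * chl_pre * exp(-params$decay_coeff * dfr)
}

#' Secchi depth from chlorophyll
#'
#' `Secchi = 10^(slope * log10(chl) + intercept)`, m.
#'
#' @param chl Chlorophyll concentration, ug/L (> 0). Vectorized.
#' @param model [secchi_model()].
#' @return Secchi depth, m.
#' @export
secchi_from_chl <- function(chl, model = secchi_model()) {
  stopifnot(inherits(model, "secchi_model"))
  if (any(chl <= 0)) stop("`chl` must be positive", call. = FALSE)
  10^(model$slope * log10(chl) + model$intercept)
}

#' Light extinction coefficient from Secchi depth
#'
#' `eta = secchi_extinction_product / Secchi` (per m), the standard
#' limnological inverse relation with product 1.7.
#'
#' @param secchi Secchi depth, m (> 0). Vectorized.
#' @param model [light_model()].
#' @return Extinction coefficient, per m.
#' @export
extinction_from_secchi <- function(secchi, model = light_model()) {
  stopifnot(inherits(model, "light_model"))
  if (any(secchi <= 0)) stop("`secchi` must be positive", call. = FALSE)
  model$secchi_extinction_product / secchi
}

#' Macrophyte colonization depth
#'
#' Depth at which Beer-Lambert attenuated light `exp(-eta z)` falls to the
#' survival fraction: `z* = -log(survival_light_fraction) / eta`.
#'
#' @param eta Light extinction coefficient, per m (> 0). Vectorized.
#' @param model [light_model()].
#' @return Colonization depth, m.
#' @export
colonization_depth <- function(eta, model = light_model()) {
  stopifnot(inherits(model, "light_model"))
  if (any(eta <= 0)) stop("`eta` must be positive", call. = FALSE)
  -log(model$survival_light_fraction) / eta
}

#' Colonizable fraction of the lake bottom
#'
#' Fraction of the lake's plan area with bottom depth at most `z`, from the
#' hypsographic curve; saturates at 1 for `z >= max_depth`.
#'
#' @param bath A [bathymetry] object.
#' @param z Depth, m (>= 0). Vectorized.
#' @return Area fraction in \[0, 1\].
#' @export
colonizable_fraction <- function(bath, z) {
  stopifnot(inherits(bath, "bathymetry"))
  if (any(z < 0)) stop("`z` must be non-negative", call. = FALSE)
  bath$fun(pmin(z, bath$max_depth))
}

#' Habitat-gain abundance-impact curve for a lake
#'
#' For each population filtration rate in `dfr_grid`, composes the full
#' chain chlorophyll response -> Secchi depth -> light extinction ->
#' colonization depth -> colonizable bottom fraction, and reports the gain
#' in colonizable area fraction over the pre-invasion (`dfr = 0`) baseline.
#' This is the within-system, instantaneous abundance-impact curve of the
#' water-clarification pathway; impact is a fraction of total lake surface
#' so lakes of different absolute size are comparable.
#'
#' @param lake [lake_scenario()].
#' @param dfr_grid Non-empty, non-negative filtration-rate grid (default
#'   0-100 %/day in steps of 1).
#' @return An [abundance_impact_curve] (kind `within_system`) whose columns
#'   additionally trace the chain: `dfr`, `chl_post`, `secchi_m`,
#'   `eta_per_m`, `z_star_m`, `colonizable_fraction`, `gain`.
#' @examples
#' lk <- lake_presets()[["deep-productive"]]
#' head(habitat_gain_curve(lk))
#' @export
habitat_gain_curve <- function(lake, dfr_grid = 0:100) {
  stopifnot(inherits(lake, "lake_scenario"))
  if (length(dfr_grid) == 0L) stop("`dfr_grid` must be non-empty", call. = FALSE)
  if (any(dfr_grid < 0)) stop("`dfr_grid` must be non-negative", call. = FALSE)
  chain <- function(dfr) {
    chl <- chl_post(lake$chl_pre, dfr, lake$response)
    sec <- secchi_from_chl(chl, lake$secchi)
    eta <- extinction_from_secchi(sec, lake$light)
    zst <- colonization_depth(eta, lake$light)
    frac <- colonizable_fraction(lake$bathymetry, zst)
    list(chl = chl, sec = sec, eta = eta, zst = zst, frac = frac)
  }
  base <- chain(0)
  full <- chain(dfr_grid)
  out <- data.frame(
    dfr = dfr_grid,
    chl_post = full$chl,
    secchi_m = full$sec,
    eta_per_m = full$eta,
    z_star_m = full$zst,
    colonizable_fraction = full$frac,
    gain = full$frac - base$frac
  )
  abundance_impact_curve(out$dfr, out$gain, kind = "within_system",
                         source_label = lake$label, extra = out[, -c(1, 7)])
}
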