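# High-cycle fatigue-life mapping.
#
# Durability follows a Basquin-type S-N curve
#     sigma_eq = sigma_f + sigma_L * N^(-beta)
# anchored so that the curve passes through the material yield point at
# 10^3 cycles, which fixes sigma_L = 10^(3 beta) * (sigma_0.2 - sigma_f).
# Multi-axial loading uses the Smith-Watson-Topper (SWT) criterion,
#     sqrt(<sigma1_max> * Dsigma1 / 2) = sigma_u~ + sigma_V * N^(-beta_VH),
# whose Macaulay bracket <.> gates out compressive maximum principal
# stresses (opening-mode cracking only).

#' Basquin amplitude coefficient from the yield-point anchor
#'
#' Computes `sigma_L = 10^(3 beta) * (sigma_02 - sigma_f)`, the coefficient
#' that makes the S-N curve return the yield point at 10^3 cycles.
#'
#' @param sigma_02 yield point, MPa.
#' @param sigma_f fatigue limit, MPa (must be below `sigma_02`).
#' @param beta fatigue exponent (> 0, or 0 for a flat anchor).
#' @return sigma_L in MPa.
#' @export
calibrate_sigma_L <- function(sigma_02, sigma_f, beta) {
  if (!is.finite(sigma_02) || !is.finite(sigma_f) || sigma_02 <= sigma_f)
    stop("invalid fatigue material: yield point sigma_02 must exceed ",
         "the fatigue limit sigma_f")
  if (beta < 0) stop("fatigue exponent beta must be >= 0")
  10^(3 * beta) * (sigma_02 - sigma_f)
}

#' Fatigue parameter set
#'
#' Constants of the Basquin S-N curve and the SWT criterion, plus the
#' cycle cap and mastication schedule used to convert cycles to years.
#'
#' The default set is a documented placeholder for denture-base acrylic:
#' the yield point is tied to the 60 MPa ultimate compressive strength of
#' the base material, the fatigue limit to 40 percent of it (the stress
#' level at which gradual degradation of the acrylic sets in), and the
#' exponent to 0.1. The SWT curve reuses the same triple. These are not
#' measured constants; supply experimental values for non-demo use
#' (`confirmed = TRUE` acknowledges the placeholder).
#'
#' @param sigma_02 yield point, MPa.
#' @param sigma_f fatigue limit, MPa.
#' @param beta Basquin exponent.
#' @param swt_sigma_u,swt_sigma_V,swt_beta endurance term, amplitude
#'   coefficient and exponent of the SWT fatigue curve, MPa/MPa/unitless.
#' @param n_max cycle cap; lives at or beyond it are "non-hazardous"
#'   (default 1e9, beyond human life expectancy at mastication rates).
#' @param meals_per_day,chews_per_meal mastication schedule used by
#'   [cycles_to_years()] (defaults 3 meals x 1000 chews).
#' @param confirmed set `TRUE` to acknowledge use of placeholder fatigue
#'   constants outside demos.
#' @return an object of class `fatigue_params` with derived `sigma_L`.
#' @export
fatigue_params <- function(sigma_02 = 60, sigma_f = 0.4 * 60, beta = 0.1,
                           swt_sigma_u = sigma_f, swt_sigma_V = NULL,
                           swt_beta = beta, n_max = 1e9,
                           meals_per_day = 3, chews_per_meal = 1000,
                           confirmed = FALSE) {
  sigma_L <- calibrate_sigma_L(sigma_02, sigma_f, beta)
  if (is.null(swt_sigma_V))
    swt_sigma_V <- calibrate_sigma_L(sigma_02, swt_sigma_u, swt_beta)
  if (n_max < 1e3) stop("n_max must be at least 1e3")
  if (meals_per_day <= 0 || chews_per_meal <= 0)
    stop("mastication schedule must be positive")
  structure(list(sigma_02 = sigma_02, sigma_f = sigma_f, beta = beta,
                 sigma_L = sigma_L, swt_sigma_u = swt_sigma_u,
                 swt_sigma_V = swt_sigma_V, swt_beta = swt_beta,
                 n_max = n_max, meals_per_day = meals_per_day,
                 chews_per_meal = chews_per_meal,
                 placeholder = !isTRUE(confirmed)),
            class = "fatigue_params")
}

#' @export
print.fatigue_params <- function(x, ...) {
  cat(sprintf(paste0("<fatigue_params> sigma_02 = %g MPa, sigma_f = %g MPa, ",
                     "beta = %g, sigma_L = %.4f MPa\n"),
              x$sigma_02, x$sigma_f, x$beta, x$sigma_L))
  cat(sprintf("  SWT: sigma_u~ = %g, sigma_V = %.4f, beta_VH = %g; cap %g cycles\n",
              x$swt_sigma_u, x$swt_sigma_V, x$swt_beta, x$n_max))
  cat(sprintf("  schedule: %g meals/day x %g chews/meal%s\n",
              x$meals_per_day, x$chews_per_meal,
              if (x$placeholder) "  [placeholder constants]" else ""))
  invisible(x)
}

#' Basquin S-N curve: stress at a given life
#'
#' `sigma_eq(N) = sigma_f + sigma_L * N^(-beta)`; strictly decreasing in N
#' and approaching the fatigue limit as N grows.
#'
#' @param N cycles (>= 1).
#' @param params a [fatigue_params()] object.
#' @return equivalent stress in MPa.
#' @export
basquin_stress <- function(N, params) {
  if (any(N < 1)) stop("N must be >= 1")
  params$sigma_f + params$sigma_L * N^(-params$beta)
}

# shared inversion of sigma = s_inf + s_amp N^-b with capping
invert_sn <- function(sigma, s_inf, s_amp, b, n_max) {
  N <- rep(n_max, length(sigma))
  above <- sigma > s_inf
  if (b <= 0) {  # flat curve: any stress above the limit fails immediately
    N[above] <- 1
  } else {
    N[above] <- ((sigma[above] - s_inf) / s_amp)^(-1 / b)
  }
  pmin(pmax(N, 1), n_max)
}

#' Cycles to failure from the Basquin curve
#'
#' Total inverse of [basquin_stress()]: stresses at or below the fatigue
#' limit map to the cycle cap `n_max` (non-hazardous); stresses at or above
#' `sigma_f + sigma_L` map to 1 cycle.
#'
#' @param sigma_eq equivalent stress(es), MPa (>= 0).
#' @param params a [fatigue_params()] object.
#' @return cycles to failure, clamped to `[1, n_max]`.
#' @export
basquin_cycles <- function(sigma_eq, params) {
  if (any(sigma_eq < 0)) stop("sigma_eq must be >= 0")
  invert_sn(sigma_eq, params$sigma_f, params$sigma_L, params$beta,
            params$n_max)
}

#' Smith-Watson-Topper equivalent stress
#'
#' `sigma_SWT = sqrt(<sigma1_max> * Dsigma1 / 2)` with the Macaulay bracket
#' `<x> = max(x, 0)`: a compressive maximum principal stress yields zero
#' (no opening-mode crack driving force). For a fully reversed cycle of
#' amplitude `s` (`sigma1_max = s`, `Dsigma1 = 2 s`) it reduces to `s`.
#'
#' @param sigma1_max maximum (over the cycle) first principal stress, MPa.
#' @param delta_sigma1 first-principal stress range over the cycle, MPa
#'   (>= 0).
#' @return SWT equivalent stress, MPa.
#' @export
swt_equivalent <- function(sigma1_max, delta_sigma1) {
  if (any(delta_sigma1 < 0)) stop("delta_sigma1 must be >= 0")
  sqrt(pmax(sigma1_max, 0) * delta_sigma1 / 2)
}

#' Cycles to failure from the SWT fatigue curve
#'
#' Inverts `sigma_SWT = sigma_u~ + sigma_V * N^(-beta_VH)` with the same
#' capping rules as [basquin_cycles()].
#'
#' @param sigma_swt SWT equivalent stress(es), MPa (>= 0).
#' @param params a [fatigue_params()] object.
#' @return cycles to failure, clamped to `[1, n_max]`.
#' @export
swt_cycles <- function(sigma_swt, params) {
  if (any(sigma_swt < 0)) stop("sigma_swt must be >= 0")
  invert_sn(sigma_swt, params$swt_sigma_u, params$swt_sigma_V,
            params$swt_beta, params$n_max)
}

#' Convert cycles to years of service
#'
#' `years = N / (meals_per_day * chews_per_meal * 365)`. With the default
#' 3 meals x 1000 chews schedule, about 1.1 million cycles correspond to
#' one year of operation.
#'
#' @param N cycles.
#' @param meals_per_day,chews_per_meal mastication schedule.
#' @return years.
#' @export
cycles_to_years <- function(N, meals_per_day = 3, chews_per_meal = 1000) {
  if (meals_per_day <= 0 || chews_per_meal <= 0)
    stop("mastication schedule must be positive")
  N / (meals_per_day * chews_per_meal * 365)
}

hazard_class <- function(N, n_max = 1e9) {
  # tolerate roundoff at the 1e3-cycle class boundary
  factor(ifelse(N <= 1e3 * (1 + 1e-9), "red",
                ifelse(N >= n_max, "non-hazardous", "intermediate")),
         levels = c("red", "intermediate", "non-hazardous"))
}

#' Nodewise fatigue-life field from a static stress field
#'
#' Maps the stress field of the maximum-effort load to per-node cycles to
#' failure, years of service and a hazard class. Two criteria:
#' `"swt-principal"` (default) applies the SWT criterion to the first
#' principal stress; `"basquin-mises"` enters the S-N curve with the von
#' Mises equivalent stress. Two cycle models: `"pulsating"` (load applied
#' and removed each mastication event, `Dsigma1 = sigma1_max`, the default)
#' and `"fully-reversed"` (`Dsigma1 = 2 sigma1_max`).
#'
#' @param stress a `stress_field` (see [recover_stress()]).
#' @param params a [fatigue_params()] object.
#' @param criterion `"swt-principal"` or `"basquin-mises"`.
#' @param cycle_model `"pulsating"` or `"fully-reversed"`.
#' @return a `life_field`: data.frame with columns `N`, `years`, `hazard`,
#'   plus the driving equivalent stress `sigma_drive`.
#' @export
life_field <- function(stress, params, criterion = c("swt-principal",
                                                     "basquin-mises"),
                       cycle_model = c("pulsating", "fully-reversed")) {
  criterion <- match.arg(criterion)
  cycle_model <- match.arg(cycle_model)
  stopifnot(inherits(params, "fatigue_params"))
  if (criterion == "swt-principal") {
    if (is.null(params$swt_sigma_u) || is.null(params$swt_sigma_V) ||
        is.null(params$swt_beta))
      stop("SWT constants missing from fatigue_params")
    s1 <- stress$nodal$s1
    ds1 <- switch(cycle_model, pulsating = pmax(s1, 0),
                  `fully-reversed` = 2 * pmax(s1, 0))
    drive <- swt_equivalent(s1, ds1)
    N <- swt_cycles(drive, params)
  } else {
    drive <- stress$nodal$von_mises
    N <- basquin_cycles(drive, params)
  }
  out <- data.frame(N = N,
                    years = cycles_to_years(N, params$meals_per_day,
                                            params$chews_per_meal),
                    hazard = hazard_class(N, params$n_max),
                    sigma_drive = drive)
  attr(out, "criterion") <- criterion
  attr(out, "cycle_model") <- cycle_model
  class(out) <- c("life_field", "data.frame")
  out
}

#' Count disjoint hazard zones on a mesh
#'
#' Connected components (over mesh edges) of the node set whose hazard
#' class is `red` or `intermediate`. Multi-zone localization of potential
#' failure areas shows up as a component count above one.
#'
#' @param mesh a `labeled_mesh`.
#' @param life a `life_field` for the same mesh.
#' @param classes hazard classes counted as hazardous.
#' @return integer number of disjoint zones.
#' @export
hazard_zones <- function(mesh, life,
                         classes = c("red", "intermediate")) {
  haz <- which(life$hazard %in% classes)
  if (!length(haz)) return(0L)
  # adjacency over element corner edges restricted to hazardous nodes
  e4 <- mesh$elems[, 1:4, drop = FALSE]
  ed <- rbind(e4[, c(1, 2)], e4[, c(1, 3)], e4[, c(1, 4)],
              e4[, c(2, 3)], e4[, c(2, 4)], e4[, c(3, 4)])
  keep <- ed[, 1] %in% haz & ed[, 2] %in% haz
  if (!any(keep)) return(length(haz))
  idx <- match(ed[keep, , drop = FALSE], haz)
  g <- igraph::graph_from_edgelist(matrix(idx, ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(haz) - igraph::vcount(g)))
  igraph::components(g)$no
}
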