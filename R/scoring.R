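# Estimators: TLE kerma scoring, air-kerma-strength scoring in vacuo, and
# per-voxel statistical uncertainty.

#' Track-length-estimator contribution of one segment (reference version)
#'
#' Adds `w * E * (mu_en/rho)(E, material) * l / V` (converted to Gy per
#' history) to each traversed cell of a Cartesian accumulator.  The C++
#' engine applies the same estimator internally; this R implementation
#' exposes the arithmetic for direct use and testing.
#'
#' @param map a list with `value` array, `spacing_mm`, and `medium`
#' @param cells integer matrix (n x 3) of 1-based voxel indices
#' @param lengths_mm chord length per cell
#' @param energy_keV photon energy
#' @param weight statistical weight
#' @param material scoring medium (defaults to the map's)
#' @return the map with updated `value`
#' @export
tle_score <- function(map, cells, lengths_mm, energy_keV, weight = 1,
                      material = map$medium) {
  if (any(lengths_mm < 0)) stop("negative track length")
  if (!nrow(cells)) return(map)
  muen <- mu_over_rho(material, energy_keV, "energy_absorption")
  V <- prod(map$spacing_mm)
  contrib <- weight * energy_keV * muen * lengths_mm / V * 1.602176634e-11
  for (i in seq_len(nrow(cells))) {
    ix <- cells[i, ]
    if (any(ix < 1) || any(ix > dim(map$value))) next   # clipped, not an error
    map$value[ix[1], ix[2], ix[3]] <- map$value[ix[1], ix[2], ix[3]] + contrib[i]
  }
  map
}

#' Per-cell relative statistical uncertainty
#'
#' History-by-history estimator
#' `sigma_rel = sqrt((<x^2> - <x>^2) / (N - 1)) / <x>`; cells that never
#' scored report NA.
#'
#' @param map an `annular_map` or `dose_map` from [run_transport()]
#' @return array of relative sigmas matching `map$value`
#' @export
estimate_uncertainty <- function(map) {
  if (map$n_histories < 2) stop("need at least 2 histories")
  out <- sqrt(map$var) / map$value
  out[map$value == 0] <- NA_real_
  out
}

#' Air kerma strength per history, scored in vacuo
#'
#' Transports seed photons through the source materials into vacuum and
#' scores TLE air kerma in thin transverse rings at several distances,
#' ignoring photons below the delta cut (the low-energy contaminant cut of
#' the WAFAC convention, default 5 keV).  Returns the mean of K(d) * d^2
#' over the distances, in Gy cm^2 per history (numerically, U per unit
#' history rate).
#'
#' @param seed a [build_seed()] model
#' @param n_histories histories
#' @param rng_seed RNG seed
#' @param distances_cm transverse-axis scoring distances
#' @param delta_cut_keV low-energy cut
#' @param theta_halfwidth_deg half-width of the transverse ring
#' @param fluorescence simulate K fluorescence in the source materials
#'   (part of the physical emission; disable only for estimator diagnostics)
#' @return object of class `sk_result`: `S_K`, per-distance values, spread
#' @export
score_air_kerma_strength <- function(seed, n_histories, rng_seed = 1,
                                     distances_cm = c(5, 10),
                                     delta_cut_keV = 5,
                                     theta_halfwidth_deg = 1,
                                     fluorescence = TRUE) {
  outer <- seed$components[nrow(seed$components), ]
  ext_mm <- max(abs(seed$components$z_mm) + seed$components$half_mm +
                seed$components$r_mm)
  if (min(distances_cm) * 10 * 0.975 <= ext_mm)
    stop("scoring ring overlaps the seed")
  world <- world_homogeneous("vacuum", radius_cm = max(distances_cm) * 1.2,
                             seed = seed)
  sc <- scorer_annular(r_cm = distances_cm,
                       theta_deg = c(90 - theta_halfwidth_deg,
                                     90 + theta_halfwidth_deg),
                       quantity = "kerma", medium = "Air",
                       delta_cut_keV = delta_cut_keV)
  cfg <- sim_config(n_histories, rng_seed, fluorescence = fluorescence)
  res <- run_transport(world, source_seed(seed), cfg, list(sk = sc))
  k <- res$maps$sk$value[, 1]
  v <- res$maps$sk$var[, 1]
  kd2 <- k * distances_cm^2
  sd_kd2 <- sqrt(v) * distances_cm^2
  # rings at different distances see the same photons, so their estimates
  # are strongly correlated: the spread of the mean is taken conservatively
  # as the mean per-distance spread
  structure(list(S_K = mean(kd2), per_distance = kd2, sd = sd_kd2,
                 combined_sd = mean(sd_kd2),
                 distances_cm = distances_cm, delta_cut_keV = delta_cut_keV,
                 n_histories = n_histories),
            class = "sk_result")
}

#' @export
print.sk_result <- function(x, ...) {
  cat(sprintf("<sk_result> S_K = %.4e Gy cm2 / history (delta cut %g keV)\n",
              x$S_K, x$delta_cut_keV))
  for (i in seq_along(x$distances_cm))
    cat(sprintf("  d = %4.1f cm: K d^2 = %.4e +- %.2e\n",
                x$distances_cm[i], x$per_distance[i], x$sd[i]))
  invisible(x)
}

#' Annular kerma map of a seed in the reference water sphere
#'
#' Full in-water characterization geometry: the seed at the centre of a
#' water sphere (15 cm radius by default) with annular TLE scoring on the
#' standard (r, theta) grid.
#'
#' @inheritParams score_air_kerma_strength
#' @param radius_cm water sphere radius
#' @param r_cm,theta_deg scoring grid (see [scorer_annular()])
#' @return `annular_map` (Gy per history)
#' @export
simulate_seed_water <- function(seed, n_histories, rng_seed = 1,
                                radius_cm = 15, r_cm = default_r_cm(),
                                theta_deg = default_theta_deg()) {
  world <- world_homogeneous("Water", radius_cm = radius_cm, seed = seed)
  sc <- scorer_annular(r_cm = r_cm, theta_deg = theta_deg, medium = "Water")
  cfg <- sim_config(n_histories, rng_seed)
  res <- run_transport(world, source_seed(seed), cfg, list(annular = sc))
  res$maps$annular
}
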