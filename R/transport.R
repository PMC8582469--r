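# Photon transport driver: world / source / scorer constructors and the
# run_transport() entry point over the C++ engine.  Analytic ray-traced
# tracking in homogeneous worlds (with optional seed solids), Woodcock delta
# tracking in voxel phantoms; kerma approximation (no electron transport).

#' Homogeneous world: background material inside a bounding sphere
#'
#' @param material background material name, or `"vacuum"`
#' @param radius_cm bounding sphere radius
#' @param seed optional [build_seed()] model placed at the origin
#' @export
world_homogeneous <- function(material = "Water", radius_cm = 15, seed = NULL) {
  bg <- if (identical(material, "vacuum")) -1L
        else .material_index(material) - 1L
  structure(list(type = "homog", background = bg,
                 radius_mm = radius_cm * 10,
                 seed = if (is.null(seed)) NULL else seed$cpp,
                 material = material),
            class = "mc_world")
}

#' Voxel-phantom world (Woodcock tracking)
#' @param phantom a [voxel_phantom()]
#' @export
world_voxel <- function(phantom) {
  structure(list(type = "voxel", phantom = phantom$cpp, phantom_obj = phantom),
            class = "mc_world")
}

#' Sources
#'
#' `source_seed()` emits from the active region of the seed in the world;
#' `source_point()` is an isotropic point emitter of one or more lines;
#' `source_pencil()` a monodirectional beam; `source_phsp()` replays
#' phase-space records at one or more poses with per-entry sampling weights.
#'
#' @param seed a [build_seed()] model (must also be in the world)
#' @name sources
#' @export
source_seed <- function(seed) {
  structure(list(type = "seed"), class = "mc_source")
}

#' @rdname sources
#' @param energy_keV line energies (single value or vector)
#' @param weights line weights (default equal)
#' @param position emitter location, mm
#' @export
source_point <- function(energy_keV, position = c(0, 0, 0), weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(energy_keV))
  structure(list(type = "point", position = as.numeric(position),
                 lineE = as.numeric(energy_keV), lineW = as.numeric(weights)),
            class = "mc_source")
}

#' @rdname sources
#' @param direction beam direction (unit vector)
#' @export
source_pencil <- function(energy_keV, position = c(0, 0, 0),
                          direction = c(0, 0, 1), weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(energy_keV))
  structure(list(type = "pencil", position = as.numeric(position),
                 direction = as.numeric(direction),
                 lineE = as.numeric(energy_keV), lineW = as.numeric(weights)),
            class = "mc_source")
}

#' @rdname sources
#' @param phsp a phase-space object ([generate_phsp()] / [read_phsp()])
#' @param poses list of [pose()] objects (one per plan entry)
#' @param weights per-entry sampling weights (e.g. air kerma strengths)
#' @export
source_phsp <- function(phsp, poses = list(pose()), weights = NULL) {
  if (inherits(poses, "pose")) poses <- list(poses)
  if (is.null(weights)) weights <- rep(1, length(poses))
  stopifnot(length(weights) == length(poses), nrow(phsp$records) >= 1)
  cdf <- cumsum(weights) / sum(weights)
  structure(list(type = "phsp", records = phsp$records, entry_cdf = cdf,
                 poseR = lapply(poses, `[[`, "R"),
                 poseT = lapply(poses, `[[`, "t")),
            class = "mc_source")
}

#' Simulation configuration
#'
#' @param n_histories number of primary histories
#' @param rng_seed integer seed; the per-history counter-based RNG makes runs
#'   bit-reproducible independent of batch order
#' @param cutoff_keV tracking cutoff: photons below are deposited locally
#' @param fluorescence simulate K-shell fluorescence after photoabsorption
#' @export
sim_config <- function(n_histories, rng_seed = 1, cutoff_keV = 1,
                       fluorescence = TRUE) {
  stopifnot(n_histories >= 1)
  structure(list(n_histories = n_histories, rng_seed = rng_seed,
                 cutoff_keV = cutoff_keV, fluorescence = fluorescence),
            class = "sim_config")
}

# default TG-43 annular grid: shells of +-2.5% thickness at the standard
# radial distances, 5-degree polar bins with a 1-degree bin at 90 degrees
default_r_cm <- function() c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 7.5, 10)

default_theta_deg <- function() {
  c(seq(0, 85, by = 5), 89.5, 90.5, seq(95, 180, by = 5))
}

#' Annular (r, theta) scorer
#'
#' Spherical-shell / polar-cone cells around the origin with exact chord
#' lengths; scores collision kerma for the given medium via the track-length
#' estimator (or raw fluence).
#'
#' @param r_cm shell centre radii, cm; each shell spans the radius times
#'   (1 - half_rel) to (1 + half_rel)
#' @param theta_deg polar bin edges over [0, 180]
#' @param quantity `"kerma"` (Gy per history) or `"fluence"` (1/cm2 per history)
#' @param medium scoring medium for the fluence-to-kerma conversion
#' @param delta_cut_keV photons below this energy are not scored
#' @param half_rel fractional shell half-thickness
#' @export
scorer_annular <- function(r_cm = default_r_cm(),
                           theta_deg = default_theta_deg(),
                           quantity = "kerma", medium = "Water",
                           delta_cut_keV = 0, half_rel = 0.025) {
  r <- sort(r_cm) * 10
  structure(list(type = "annular",
                 r_lo_mm = r * (1 - half_rel), r_hi_mm = r * (1 + half_rel),
                 r_cm = sort(r_cm), theta_deg = theta_deg,
                 quantity = quantity,
                 medium = if (quantity == "kerma") .material_index(medium) - 1L else -1L,
                 medium_name = medium,
                 delta_cut = delta_cut_keV),
            class = "mc_scorer")
}

#' Cartesian voxel scorer
#'
#' `mode = "tle"` scores track-length-estimator collision kerma (for a fixed
#' medium in homogeneous worlds, or the local voxel material in phantoms);
#' `mode = "analog"` deposits the energy transferred at interaction sites.
#'
#' @param origin_mm,spacing_mm,dims grid geometry (corner origin)
#' @inheritParams scorer_annular
#' @param mode `"tle"` or `"analog"`
#' @export
scorer_cartesian <- function(origin_mm, spacing_mm, dims, mode = "tle",
                             medium = "Water", delta_cut_keV = 0) {
  structure(list(type = if (mode == "analog") "cart_analog" else "cart_tle",
                 origin = as.numeric(origin_mm),
                 spacing = as.numeric(spacing_mm), dims = as.integer(dims),
                 medium = if (identical(medium, "local")) -1L
                          else .material_index(medium) - 1L,
                 medium_name = medium,
                 delta_cut = delta_cut_keV),
            class = "mc_scorer")
}

.finish_annular <- function(sc, res, N) {
  nr <- length(sc$r_cm)
  nt <- length(sc$theta_deg) - 1
  dim_set <- function(v) matrix(v, nrow = nr, ncol = nt, byrow = TRUE)
  sum_ <- dim_set(res$sum); sum2 <- dim_set(res$sum2)
  value <- sum_ / N
  varm <- (sum2 / N - value^2) / (N - 1)
  varm[varm < 0] <- 0
  structure(list(r_cm = sc$r_cm,
                 theta_deg = (sc$theta_deg[-1] + sc$theta_deg[-length(sc$theta_deg)]) / 2,
                 theta_edges_deg = sc$theta_deg,
                 value = value, var = varm,
                 vol_mm3 = dim_set(res$vol_mm3),
                 quantity = sc$quantity, medium = sc$medium_name,
                 n_histories = N),
            class = "annular_map")
}

.finish_cart <- function(sc, res, N) {
  a <- array(res$sum, dim = sc$dims)
  a2 <- array(res$sum2, dim = sc$dims)
  value <- a / N
  varm <- (a2 / N - value^2) / (N - 1)
  varm[varm < 0] <- 0
  structure(list(origin_mm = sc$origin, spacing_mm = sc$spacing,
                 dims = sc$dims, value = value, var = varm,
                 n_histories = N, mode = sc$type, medium = sc$medium_name),
            class = "dose_map")
}

#' Run the Monte Carlo transport
#'
#' Tracks `config$n_histories` photon histories through the world, offering
#' every flight segment to the scorers (TLE) and every interaction to analog
#' scorers.  Results are bit-reproducible for a fixed `rng_seed`.
#'
#' @param world from [world_homogeneous()] or [world_voxel()]
#' @param source from one of the [sources]
#' @param config a [sim_config()]
#' @param scorers named list of scorers
#' @return list with `maps` (one per scorer), and `totals` (energy
#'   bookkeeping: emitted / deposited / escaped keV per run, escape counts)
#' @export
run_transport <- function(world, source, config, scorers) {
  stopifnot(inherits(world, "mc_world"), inherits(source, "mc_source"),
            inherits(config, "sim_config"))
  if (inherits(scorers, "mc_scorer")) scorers <- list(map = scorers)
  phys <- physics_library()
  if (identical(source$type, "seed") && is.null(world$seed) &&
      world$type == "homog")
    stop("source_seed() requires a seed in the world")
  res <- cpp_run(phys, unclass(world), unclass(source), unclass(config),
                 lapply(scorers, unclass))
  N <- config$n_histories
  maps <- vector("list", length(scorers))
  names(maps) <- names(scorers)
  for (i in seq_along(scorers)) {
    sc <- scorers[[i]]
    maps[[i]] <- if (sc$type == "annular") .finish_annular(sc, res$scorers[[i]], N)
                 else .finish_cart(sc, res$scorers[[i]], N)
  }
  list(maps = maps, totals = res$totals)
}

#' Sample Compton scattering (Klein-Nishina, Kahn's method)
#'
#' @param energy_keV incident photon energy
#' @param n draws
#' @param rng_seed RNG stream seed
#' @return data.frame with scattered `energy_keV` and `cos_theta`
#' @export
compton_scatter <- function(energy_keV, n = 1, rng_seed = 1) {
  m <- cpp_compton(energy_keV, n, rng_seed)
  data.frame(energy_keV = m[, 1], cos_theta = m[, 2])
}

#' Sample incoherent (bound-electron) Compton scattering in a material
#'
#' As [compton_scatter()] but with the atomic incoherent scattering function
#' S(x, Z) applied as an angular rejection, which suppresses small-angle
#' scattering at low energies.  This is the law the transport engine uses.
#'
#' @inheritParams compton_scatter
#' @param material material name or [material()]
#' @return data.frame with scattered `energy_keV` and `cos_theta`
#' @export
incoherent_scatter <- function(energy_keV, material = "Water", n = 1,
                               rng_seed = 1) {
  pw <- .phys_with_material(material)
  m <- cpp_incoh(pw$phys, pw$idx, energy_keV, n, rng_seed)
  data.frame(energy_keV = m[, 1], cos_theta = m[, 2])
}

#' Sample Rayleigh scattering angles
#'
#' Elastic: energy unchanged; the polar angle follows the Thomson law
#' modulated by the tabulated atomic form factors of the material's elements.
#'
#' @inheritParams compton_scatter
#' @param material material name or [material()]
#' @return cosines of the scattering angle
#' @export
rayleigh_scatter <- function(energy_keV, material = "Water", n = 1,
                             rng_seed = 1) {
  pw <- .phys_with_material(material)
  cpp_rayleigh(pw$phys, pw$idx, energy_keV, n, rng_seed)
}

#' Sample photoelectric absorption outcomes
#'
#' The photon terminates; if the absorbing element's K edge lies below the
#' photon energy, a K fluorescence photon is emitted with probability
#' (K-shell fraction) x (K yield).
#'
#' @inheritParams rayleigh_scatter
#' @param fluorescence logical
#' @return fluorescence photon energies in keV (0 = none)
#' @export
photoelectric_absorb <- function(energy_keV, material, n = 1, rng_seed = 1,
                                 fluorescence = TRUE) {
  pw <- .phys_with_material(material)
  cpp_photo(pw$phys, pw$idx, energy_keV, n, rng_seed, fluorescence)
}
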