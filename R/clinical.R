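# Heterogeneous-case pipeline: HU -> material conversion, voxel phantoms,
# the synthetic pelvis fixture with its 67-seed plan, plan simulation by
# phase-space replay, cDVHs, isodose masks and dose-map comparison metrics.

#' Voxel phantom
#'
#' @param material_ids integer 3D array of 1-based indices into `materials`
#' @param materials character vector of material names
#' @param spacing_mm,origin_mm grid geometry (corner origin)
#' @param densities optional per-material densities (g/cm3); defaults to the
#'   library's nominal densities
#' @return object of class `voxel_phantom`
#' @export
voxel_phantom <- function(material_ids, materials, spacing_mm,
                          origin_mm = -dim(material_ids) * spacing_mm / 2,
                          densities = NULL) {
  if (!length(material_ids)) stop("empty raster")
  phys <- physics_library()
  gidx <- vapply(materials, .material_index, integer(1))   # 1-based global
  if (is.null(densities))
    densities <- vapply(phys$materials[gidx], `[[`, 0, "density")
  nmat <- length(phys$materials)
  rho <- numeric(nmat)
  rho[gidx] <- densities
  cpp <- list(origin = as.numeric(origin_mm), spacing = as.numeric(spacing_mm),
              dims = dim(material_ids),
              mat = as.integer(gidx[material_ids] - 1L),   # 0-based global
              rho = rho)
  structure(list(material_ids = material_ids, materials = materials,
                 spacing_mm = spacing_mm, origin_mm = as.numeric(origin_mm),
                 dims = dim(material_ids), densities = densities, cpp = cpp),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("<voxel_phantom>", paste(x$dims, collapse = " x "), "voxels,",
      paste(signif(x$spacing_mm, 4), collapse = " x "), "mm\n")
  tab <- table(factor(x$materials[x$material_ids], levels = x$materials))
  print(round(100 * tab / sum(tab), 2))
  invisible(x)
}

#' Default HU-to-material map
#'
#' Four materials over the clinical HU span [-1050, 4000]: closed-open
#' intervals `[-1050,-600)` Lung, `[-600,100)` SoftTissue, `[100,300)`
#' ProstateICRU (only inside a declared prostate mask, else SoftTissue),
#' `[300,4000]` CorticalBone.
#'
#' @return data.frame with columns `lo`, `hi`, `material`
#' @export
default_hu_map <- function() {
  data.frame(lo = c(-1050, -600, 100, 300), hi = c(-600, 100, 300, 4000),
             material = c("Lung", "SoftTissue", "ProstateICRU", "CorticalBone"),
             stringsAsFactors = FALSE)
}

#' Convert a CT raster (HU) to a voxel phantom
#'
#' Assigns each voxel the material of the HU interval containing it
#' (closed-open intervals: a boundary value belongs to the upper interval).
#' HU outside the map span are clamped, with the clamp count reported as an
#' attribute.  Nominal per-material densities are used.
#'
#' @param hu 3D array of Hounsfield units
#' @param spacing_mm voxel spacing
#' @param hu_map interval table (see [default_hu_map()])
#' @param origin_mm grid corner, mm
#' @param prostate_mask optional logical array: the ProstateICRU interval
#'   applies only inside it (SoftTissue elsewhere)
#' @return a [voxel_phantom()]; attribute `n_clamped` counts out-of-span HU
#' @export
hu_to_phantom <- function(hu, spacing_mm, hu_map = default_hu_map(),
                          origin_mm = -dim(hu) * spacing_mm / 2,
                          prostate_mask = NULL) {
  if (!length(hu)) stop("empty raster")
  lo <- min(hu_map$lo); hi <- max(hu_map$hi)
  n_clamped <- sum(hu < lo | hu > hi)
  huc <- pmin(pmax(hu, lo), hi)
  idx <- findInterval(huc, c(hu_map$lo, hi), rightmost.closed = TRUE)
  mats <- unique(hu_map$material)
  mid <- match(hu_map$material, mats)[idx]
  dim(mid) <- dim(hu)
  ip <- match("ProstateICRU", mats)
  if (!is.na(ip)) {
    isoft <- match("SoftTissue", mats)
    if (is.null(prostate_mask)) {
      mid[mid == ip] <- isoft
    } else {
      mid[mid == ip & !prostate_mask] <- isoft
    }
  }
  ph <- voxel_phantom(mid, mats, spacing_mm, origin_mm)
  attr(ph, "n_clamped") <- n_clamped
  if (n_clamped > 0)
    message(n_clamped, " HU values outside [", lo, ", ", hi, "] clamped")
  ph
}

.ellipsoid_mask <- function(dims, spacing, centre_mm, semi_mm, origin_mm) {
  cx <- origin_mm[1] + (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- origin_mm[2] + (seq_len(dims[2]) - 0.5) * spacing[2]
  cz <- origin_mm[3] + (seq_len(dims[3]) - 0.5) * spacing[3]
  X <- (cx - centre_mm[1]) / semi_mm[1]
  Y <- (cy - centre_mm[2]) / semi_mm[2]
  Z <- (cz - centre_mm[3]) / semi_mm[3]
  outer(outer(X^2, Y^2, `+`), Z^2, `+`) <= 1
}

#' Synthetic pelvis phantom
#'
#' A deterministic stand-in for a clinical pelvic CT (the real patient data
#' are not distributable): ellipsoidal prostate, urethra, rectum and bladder
#' over the four clinical materials on the CT grid resolution of
#' 0.78125 x 0.78125 x 2.0 mm.  Returns the HU raster, the derived phantom
#' and per-organ masks.
#'
#' @param dims grid size in voxels (default 128 x 128 x 48; ~10 x 10 x 9.6 cm)
#' @param spacing_mm voxel spacing
#' @return list with `hu`, `phantom`, `masks` (prostate / urethra / rectum /
#'   bladder), `spacing_mm`, `origin_mm`
#' @export
make_pelvis_phantom <- function(dims = c(128, 128, 48),
                                spacing_mm = c(0.78125, 0.78125, 2.0)) {
  origin <- -dims * spacing_mm / 2
  hu <- array(35, dim = dims)                       # soft tissue background
  msk <- function(c_mm, s_mm) .ellipsoid_mask(dims, spacing_mm, c_mm, s_mm, origin)
  prostate <- msk(c(0, 0, 0), c(20, 17.5, 19))
  urethra <- msk(c(0, 0, 0), c(3, 3, 21))
  bladder <- msk(c(0, -32, 18), c(24, 18, 20))
  rectum <- msk(c(0, 30, 0), c(12, 11, 42))
  gas <- msk(c(0, 30, 6), c(7, 6, 18))
  bone_l <- msk(c(-42, 8, 0), c(12, 14, 40))
  bone_r <- msk(c(42, 8, 0), c(12, 14, 40))
  hu[prostate] <- 180
  hu[urethra] <- 40
  hu[bladder] <- 15
  hu[rectum] <- 25
  hu[gas] <- -800
  hu[bone_l | bone_r] <- 700
  ph <- hu_to_phantom(hu, spacing_mm, prostate_mask = prostate,
                      origin_mm = origin)
  list(hu = hu, phantom = ph,
       masks = list(prostate = prostate, urethra = urethra,
                    rectum = rectum, bladder = bladder),
       spacing_mm = spacing_mm, origin_mm = origin)
}

#' Synthetic 67-seed treatment plan
#'
#' Places 67 seed poses on a regular lattice clipped to the prostate mask
#' (lattice pitch chosen so at least 67 sites fall inside), all seeds along
#' +Z, equal air kerma strength per seed.  Deterministic.
#'
#' @param pelvis result of [make_pelvis_phantom()]
#' @param seed_id seed model identifier for every entry
#' @param sk_U per-seed air kerma strength in U
#' @param n_seeds number of seeds
#' @param prescription_Gy prescription dose stored with the plan
#' @return object of class `treatment_plan`: data.frame of entries with an
#'   attribute `prescription_Gy`
#' @export
make_plan_67 <- function(pelvis, seed_id = "AmershamOncoseed6711",
                         sk_U = 0.5, n_seeds = 67, prescription_Gy = 145) {
  m <- pelvis$masks$prostate
  sp <- pelvis$spacing_mm; org <- pelvis$origin_mm
  pitch <- 5   # mm lattice
  gx <- seq(org[1] + 4, -org[1] - 4, by = pitch)
  gy <- seq(org[2] + 4, -org[2] - 4, by = pitch)
  gz <- seq(org[3] + 4, -org[3] - 4, by = pitch)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  ijk <- cbind(floor((pts[, 1] - org[1]) / sp[1]) + 1,
               floor((pts[, 2] - org[2]) / sp[2]) + 1,
               floor((pts[, 3] - org[3]) / sp[3]) + 1)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dim(m)[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= dim(m)[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= dim(m)[3]
  inside <- rep(FALSE, nrow(pts))
  inside[ok] <- m[ijk[ok, , drop = FALSE]]
  pts <- pts[inside, , drop = FALSE]
  # order by distance from the plan centre for a stable, centred selection
  d2 <- rowSums(sweep(pts, 2, colMeans(pts))^2)
  pts <- pts[order(d2), , drop = FALSE]
  if (nrow(pts) < n_seeds)
    stop("prostate mask too small for ", n_seeds, " lattice sites")
  pts <- pts[seq_len(n_seeds), , drop = FALSE]
  plan <- data.frame(seed_id = seed_id, x = pts[, 1], y = pts[, 2],
                     z = pts[, 3], axis_x = 0, axis_y = 0, axis_z = 1,
                     angle_deg = 0, S_K = sk_U, stringsAsFactors = FALSE)
  structure(plan, prescription_Gy = prescription_Gy,
            class = c("treatment_plan", "data.frame"))
}

.plan_poses <- function(plan) {
  lapply(seq_len(nrow(plan)), function(i)
    pose(translation = c(plan$x[i], plan$y[i], plan$z[i]),
         axis = c(plan$axis_x[i], plan$axis_y[i], plan$axis_z[i]),
         angle_deg = plan$angle_deg[i]))
}

#' Monte Carlo simulation of a treatment plan in a voxel phantom
#'
#' Replays each entry's phase-space file at its pose (entries sampled
#' proportionally to S_K) through Woodcock transport with TLE scoring on the
#' phantom grid.  Seeds other than the emitter are not materialized in the
#' phantom (pure replay into tissue).
#'
#' @param plan a `treatment_plan`
#' @param phantom a [voxel_phantom()]
#' @param phsp a `phsp` object, or named list of `phsp` by seed id
#' @param n_histories total histories over the whole plan
#' @param rng_seed RNG seed
#' @return `dose_map` on the phantom grid, in Gy x U per source photon: the
#'   per-history dose is scaled by the plan's total air kerma strength, so
#'   doubling every entry's S_K doubles every voxel dose
#' @export
simulate_plan_mc <- function(plan, phantom, phsp, n_histories, rng_seed = 1) {
  ids <- unique(plan$seed_id)
  if (inherits(phsp, "phsp")) {
    if (length(ids) > 1)
      stop("plan uses several seed models; pass a named list of phsp objects")
    ph_for <- function(id) phsp
  } else {
    missing <- setdiff(ids, names(phsp))
    if (length(missing))
      stop("no phase-space file for seed model: ", paste(missing, collapse = ", "))
    ph_for <- function(id) phsp[[id]]
  }
  if (length(ids) > 1)
    stop("mixed-model plans are not supported in one replay run")
  src <- source_phsp(ph_for(ids[1]), poses = .plan_poses(plan),
                     weights = plan$S_K)
  world <- world_voxel(phantom)
  sc <- scorer_cartesian(phantom$origin_mm, phantom$spacing_mm, phantom$dims,
                         mode = "tle", medium = "local")
  res <- run_transport(world, src, sim_config(n_histories, rng_seed),
                       list(dose = sc))
  map <- res$maps$dose
  sk_tot <- sum(plan$S_K)
  map$value <- map$value * sk_tot
  map$var <- map$var * sk_tot^2
  map
}

#' Cumulative dose-volume histogram
#'
#' `volume_fraction(d)` = percentage of organ voxels with dose >= d.  On the
#' uniform grids used here physical-volume weighting equals voxel counting.
#'
#' @param map a `dose_map`
#' @param mask logical array on the same grid
#' @param edges dose edges (default: 200 from 0 to the mask maximum)
#' @return object of class `cdvh`: data.frame with `dose` and `volume_pct`
#' @export
compute_cdvh <- function(map, mask, edges = NULL) {
  if (!any(mask)) stop("empty organ mask")
  if (!all(dim(mask) == dim(map$value))) stop("mask grid mismatch")
  d <- map$value[mask]
  if (is.null(edges)) edges <- seq(0, max(d), length.out = 200)
  vol <- vapply(edges, function(e) 100 * mean(d >= e), 0)
  structure(data.frame(dose = edges, volume_pct = vol), class = c("cdvh", "data.frame"))
}

#' Isodose label masks
#'
#' One mask per threshold: voxels with dose strictly above `t`% of the
#' prescription.  Masks are nested by construction.
#'
#' @param map a `dose_map`
#' @param prescription prescription dose (same unit as the map)
#' @param thresholds_pct percentages, e.g. `c(50, 100, 150)`
#' @return named list of logical arrays
#' @export
isodose_masks <- function(map, prescription, thresholds_pct = c(50, 100, 150)) {
  stopifnot(prescription > 0)
  out <- lapply(thresholds_pct, function(t) map$value > t / 100 * prescription)
  names(out) <- paste0(thresholds_pct, "%")
  out
}

#' Compare two dose maps along a profile
#'
#' Relative difference `100 (a - b) / ((a + b)/2)` at profile points where
#' both maps' relative uncertainty is below `sigma_gate_pct`; reports the
#' average and maximum absolute difference and the combined per-point sigma.
#'
#' @param a,b `dose_map`s on the same grid
#' @param profile list(axis = "x"|"y"|"z", index = c(j, k)) selecting a grid
#'   line; default: the x row through the centre voxel
#' @param sigma_gate_pct gate on relative uncertainty, percent
#' @return object of class `map_comparison`
#' @export
compare_maps <- function(a, b, profile = NULL, sigma_gate_pct = 5) {
  if (!all(dim(a$value) == dim(b$value))) stop("grid mismatch")
  dims <- dim(a$value)
  if (is.null(profile))
    profile <- list(axis = "x", index = ceiling(dims[2:3] / 2))
  ax <- match(profile$axis, c("x", "y", "z"))
  idx <- switch(ax,
    cbind(seq_len(dims[1]), profile$index[1], profile$index[2]),
    cbind(profile$index[1], seq_len(dims[2]), profile$index[2]),
    cbind(profile$index[1], profile$index[2], seq_len(dims[3])))
  va <- a$value[idx]; vb <- b$value[idx]
  sa <- sqrt(a$var[idx]); sb <- sqrt(b$var[idx])
  ra <- ifelse(va > 0, sa / va, Inf)
  rb <- ifelse(vb > 0, sb / vb, Inf)
  use <- ra <= sigma_gate_pct / 100 & rb <= sigma_gate_pct / 100
  mid <- (va + vb) / 2
  diff_pct <- ifelse(use, 100 * (va - vb) / mid, NA_real_)
  comb <- ifelse(use, 100 * sqrt(sa^2 + sb^2) / mid, NA_real_)
  pos_mm <- a$origin_mm[ax] + (seq_len(dims[ax]) - 0.5) * a$spacing_mm[ax]
  ok <- !is.na(diff_pct)
  structure(list(profile = profile, position_mm = pos_mm,
                 diff_pct = diff_pct, combined_sd_pct = comb, used = use,
                 average_pct = if (any(ok)) mean(abs(diff_pct[ok])) else NA_real_,
                 maximum_pct = if (any(ok)) max(abs(diff_pct[ok])) else NA_real_),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("<map_comparison> %d/%d profile points pass the sigma gate\n",
              sum(x$used), length(x$used)))
  cat(sprintf("  average |diff| = %.2f%%, maximum = %.2f%%\n",
              x$average_pct, x$maximum_pct))
  invisible(x)
}
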