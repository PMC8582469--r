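# TG-43 formalism: line/point geometry factors, extraction of the dose rate
# constant, radial dose function and anisotropy function from Monte Carlo
# annular maps, and the forward 2D dose engine with multi-seed superposition.
#
# Conventions: r in cm, theta in degrees from +Z (source tip); reference
# point r0 = 1 cm, theta0 = 90 deg; the line-source geometry factor
# G_L(r, theta) = beta / (L r sin theta) is the default.

#' TG-43 geometry factor
#'
#' Point model: `1/r^2`.  Line model: `beta / (L r sin theta)` with `beta`
#' the angle subtended by the active line at the point; on the long axis the
#' limit `1 / (r^2 - L^2/4)` applies.
#'
#' @param r_cm radial distance(s), cm
#' @param theta_deg polar angle(s), degrees in [0, 180]
#' @param L_cm active length, cm
#' @param model `"line"` or `"point"`
#' @return geometry factor in 1/cm^2
#' @export
geometry_factor <- function(r_cm, theta_deg, L_cm, model = c("line", "point")) {
  model <- match.arg(model)
  if (any(r_cm <= 0)) stop("r must be > 0")
  if (model == "point") return(1 / r_cm^2)
  n <- max(length(r_cm), length(theta_deg))
  r <- rep_len(r_cm, n); th <- rep_len(theta_deg, n) * pi / 180
  L <- L_cm
  out <- numeric(n)
  on_axis <- sin(th) < 1e-9
  if (any(on_axis)) {
    if (any(r[on_axis] <= L / 2))
      stop("point on the long axis inside the active line (r <= L/2)")
    out[on_axis] <- 1 / (r[on_axis]^2 - L^2 / 4)
  }
  i <- !on_axis
  if (any(i)) {
    z <- r[i] * cos(th[i]); y <- r[i] * sin(th[i])
    beta <- atan2(z + L / 2, y) - atan2(z - L / 2, y)
    out[i] <- beta / (L * y)                 # y = r sin(theta)
  }
  out
}

.GL <- function(r, th, L) geometry_factor(r, th, L, "line")

#' Extract TG-43 parameters from an annular map and an S_K result
#'
#' Dose rate constant `Lambda = D(r0, theta0) / S_K`; radial dose function
#' `g_L(r) = [D(r,90)/D(1,90)] [G_L(1,90)/G_L(r,90)]`; anisotropy function
#' `F(r,theta) = [D(r,theta)/D(r,90)] [G_L(r,90)/G_L(r,theta)]`.
#' Uncertainties are propagated in quadrature from the map variances.
#'
#' @param annular an `annular_map` from [simulate_seed_water()]
#' @param sk an `sk_result` (or a bare S_K value in Gy cm2 per history)
#' @param L_cm active length in cm
#' @param seed_id label stored with the parameters
#' @return object of class `tg43_parameters`
#' @export
extract_parameters <- function(annular, sk, L_cm, seed_id = "") {
  r <- annular$r_cm
  th <- annular$theta_deg
  i0 <- which(abs(r - 1) < 1e-9)
  j0 <- which(abs(th - 90) < 1e-9)
  if (!length(i0) || !length(j0))
    stop("annular map lacks the reference cell (r = 1 cm, theta = 90 deg)")
  D <- annular$value
  V <- annular$var
  if (D[i0, j0] <= 0) stop("zero dose at the reference cell (1 cm, 90 deg)")
  SK <- if (inherits(sk, "sk_result")) sk$S_K else sk
  if (SK <= 0) stop("S_K must be > 0")
  D0 <- D[i0, j0]
  lambda <- D0 / SK
  lambda_sd <- lambda * sqrt(V[i0, j0] / D0^2 +
    (if (inherits(sk, "sk_result")) (sk$combined_sd / sk$S_K)^2 else 0))
  if (any(D[, j0] <= 0))
    stop("zero dose on the transverse axis at r = ",
         paste(r[D[, j0] <= 0], collapse = ", "), " cm")
  Gl <- .GL(r, 90, L_cm)
  g <- (D[, j0] / D0) * (.GL(1, 90, L_cm) / Gl)
  g_sd <- g * sqrt(V[, j0] / D[, j0]^2 + V[i0, j0] / D0^2)
  g_sd[i0] <- 0
  Fm <- matrix(NA_real_, length(r), length(th))
  F_sd <- matrix(NA_real_, length(r), length(th))
  for (i in seq_along(r)) {
    Gth <- .GL(r[i], th, L_cm)
    Fm[i, ] <- (D[i, ] / D[i, j0]) * (Gl[i] / Gth)
    F_sd[i, ] <- Fm[i, ] * sqrt(V[i, ] / pmax(D[i, ], 1e-300)^2 +
                                V[i, j0] / D[i, j0]^2)
    F_sd[i, j0] <- 0
  }
  structure(list(seed_id = seed_id, Lambda = lambda, Lambda_sd = lambda_sd,
                 L_cm = L_cm, r0_cm = 1, theta0_deg = 90,
                 r_cm = r, theta_deg = th,
                 g = g, g_sd = g_sd, F = Fm, F_sd = F_sd),
            class = "tg43_parameters")
}

#' @export
print.tg43_parameters <- function(x, ...) {
  cat(sprintf("<tg43_parameters> %s: Lambda = %.4f +- %.4f cGy/(h U), L = %g cm\n",
              x$seed_id, x$Lambda, x$Lambda_sd, x$L_cm))
  cat("g_L(r):\n")
  print(round(stats::setNames(x$g, paste0(x$r_cm, "cm")), 4))
  invisible(x)
}

# g interpolation: linear in (r, log g); nearest-slope extrapolation limited
# to 20% beyond the table, else NA (flagged)
.interp_g <- function(params, r) {
  rt <- params$r_cm; lg <- log(params$g)
  out <- rep(NA_real_, length(r))
  inside <- r >= rt[1] & r <= rt[length(rt)]
  out[inside] <- exp(stats::approx(rt, lg, r[inside])$y)
  lo <- r < rt[1] & r >= 0.8 * rt[1]
  if (any(lo)) {
    s <- (lg[2] - lg[1]) / (rt[2] - rt[1])
    out[lo] <- exp(lg[1] + s * (r[lo] - rt[1]))
  }
  n <- length(rt)
  hi <- r > rt[n] & r <= 1.2 * rt[n]
  if (any(hi)) {
    s <- (lg[n] - lg[n - 1]) / (rt[n] - rt[n - 1])
    out[hi] <- exp(lg[n] + s * (r[hi] - rt[n]))
  }
  out
}

# F interpolation: bilinear in (r, theta); constant beyond theta ends;
# radial policy as for g
.interp_F <- function(params, r, th) {
  rt <- params$r_cm; tt <- params$theta_deg
  n <- length(r)
  rr <- pmin(pmax(r, rt[1]), rt[length(rt)])
  flag_r <- r < 0.8 * rt[1] | r > 1.2 * rt[length(rt)]
  thc <- pmin(pmax(th, tt[1]), tt[length(tt)])
  i <- findInterval(rr, rt, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), length(rt) - 1)
  j <- findInterval(thc, tt, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1), length(tt) - 1)
  fr <- (rr - rt[i]) / (rt[i + 1] - rt[i])
  ft <- (thc - tt[j]) / (tt[j + 1] - tt[j])
  v <- (1 - fr) * (1 - ft) * params$F[cbind(i, j)] +
       fr * (1 - ft) * params$F[cbind(i + 1, j)] +
       (1 - fr) * ft * params$F[cbind(i, j + 1)] +
       fr * ft * params$F[cbind(i + 1, j + 1)]
  v[flag_r] <- NA_real_
  v
}

#' Forward TG-43 2D dose rate
#'
#' `D(r, theta) = S_K Lambda [G_L(r,theta)/G_L(r0,theta0)] g_L(r) F(r,theta)`
#' with g interpolated log-linearly in r and F bilinearly in (r, theta).
#' Points beyond the documented extrapolation policy (20% past the radial
#' table) return NA rather than a silent extrapolation.
#'
#' @param params a `tg43_parameters` object
#' @param S_K air kerma strength in U
#' @param r_cm,theta_deg evaluation points (recycled to a common length)
#' @return dose rates in cGy/h
#' @export
forward_dose <- function(params, S_K, r_cm, theta_deg = 90) {
  n <- max(length(r_cm), length(theta_deg))
  r <- rep_len(r_cm, n); th <- rep_len(theta_deg, n)
  G <- geometry_factor(r, th, params$L_cm, "line")
  G0 <- geometry_factor(params$r0_cm, params$theta0_deg, params$L_cm, "line")
  S_K * params$Lambda * (G / G0) * .interp_g(params, r) *
    .interp_F(params, r, th)
}

#' Superpose a multi-seed TG-43 plan on a grid
#'
#' Sums [forward_dose()] over all plan entries, each evaluated in its seed's
#' local frame via the entry pose.  Water-only: TG-43 superposition carries
#' no tissue heterogeneity and no interseed attenuation.
#'
#' @param params `tg43_parameters` (single object used for all entries)
#' @param plan list of entries, each `list(pose = pose(), S_K = <U>)`
#' @param grid either a list(origin_mm, spacing_mm, dims) or an n x 3 matrix
#'   of points in mm
#' @return for a grid list, a `dose_map`-like object (cGy/h per voxel);
#'   for points, a vector of dose rates with NA at flagged cells
#' @export
superpose_plan <- function(params, plan, grid) {
  if (!length(plan)) stop("plan must be nonempty")
  if (is.matrix(grid)) {
    pts <- grid
    as_map <- FALSE
  } else {
    gx <- grid$origin_mm[1] + (seq_len(grid$dims[1]) - 0.5) * grid$spacing_mm[1]
    gy <- grid$origin_mm[2] + (seq_len(grid$dims[2]) - 0.5) * grid$spacing_mm[2]
    gz <- grid$origin_mm[3] + (seq_len(grid$dims[3]) - 0.5) * grid$spacing_mm[3]
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    as_map <- TRUE
  }
  dose <- numeric(nrow(pts))
  for (entry in plan) {
    p <- entry$pose
    local <- sweep(pts, 2, p$t) %*% p$R      # R^T (x - t), as columns of R
    r <- sqrt(rowSums(local^2)) / 10         # cm
    costh <- ifelse(r > 0, local[, 3] / (10 * r), 1)
    th <- acos(pmin(pmax(costh, -1), 1)) * 180 / pi
    d <- forward_dose(params, entry$S_K, r, th)
    d[r < 1e-6] <- NA_real_                  # coincident with the seed origin
    dose <- dose + d
  }
  if (!as_map) return(dose)
  structure(list(origin_mm = grid$origin_mm, spacing_mm = grid$spacing_mm,
                 dims = grid$dims,
                 value = array(dose, dim = grid$dims),
                 var = array(0, dim = grid$dims),
                 n_histories = NA, mode = "tg43", medium = "Water"),
            class = "dose_map")
}

#' Full Monte Carlo TG-43 characterization of a seed
#'
#' Runs the in-water annular simulation and the in-vacuo air-kerma-strength
#' scoring, then extracts (Lambda, g_L, F).
#'
#' @param seed_id one of the six model identifiers (or a `seed_model`)
#' @param n_histories histories for the water map and the S_K run (vacuum
#'   transport is far cheaper per history)
#' @param rng_seed RNG seed (the S_K run uses `rng_seed + 1`)
#' @param ... passed to [simulate_seed_water()]
#' @return `tg43_parameters`
#' @export
characterize_seed <- function(seed_id, n_histories = 1e6, rng_seed = 1, ...) {
  seed <- if (inherits(seed_id, "seed_model")) seed_id else build_seed(seed_id)
  ann <- simulate_seed_water(seed, n_histories, rng_seed, ...)
  sk <- score_air_kerma_strength(seed, n_histories, rng_seed + 1)
  extract_parameters(ann, sk, seed$L_mm / 10, seed_id = seed$id)
}
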