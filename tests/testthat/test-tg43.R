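# Geometry factors, parameter extraction, forward dose, superposition.

test_that("line geometry factor: point limit, quadrature, symmetry, domain", {
  r <- c(0.7, 1, 2.3); th <- c(25, 90, 140)
  expect_equal(geometry_factor(r, th, 1e-7), 1 / r^2, tolerance = 1e-9)
  # quadrature oracle: G = (1/L) * int ds / s^2 along the active line
  L <- 0.3
  for (th0 in c(30, 90, 120)) {
    zs <- seq(-L / 2, L / 2, length.out = 200001)
    p <- c(sin(th0 * pi / 180), 0, cos(th0 * pi / 180))   # r = 1
    s2 <- (p[1])^2 + (p[3] - zs)^2
    G_quad <- mean(1 / s2)
    expect_equal(geometry_factor(1, th0, L), G_quad, tolerance = 1e-6)
  }
  expect_equal(geometry_factor(r, th, 0.5), geometry_factor(r, 180 - th, 0.5),
               tolerance = 1e-12)
  expect_equal(geometry_factor(1, 0, 0.4), 1 / (1 - 0.04), tolerance = 1e-9)
  expect_error(geometry_factor(0.1, 0, 0.4), "inside the active line")
  expect_error(geometry_factor(0, 90, 0.4), "r must be")
})

test_that("extraction from a synthetic TG-43 map recovers the generators", {
  p0 <- synthetic_params()
  SK <- 2.5e-14
  ann <- synthetic_annular(p0, SK)
  p1 <- extract_parameters(ann, SK, p0$L_cm, seed_id = "synthetic")
  expect_equal(p1$Lambda, p0$Lambda, tolerance = 1e-9)
  expect_equal(p1$g, p0$g, tolerance = 1e-9)
  expect_equal(p1$F, p0$F, tolerance = 1e-9)
})

test_that("extracted tables are normalized exactly at the reference point", {
  p1 <- extract_parameters(synthetic_annular(synthetic_params()), 2.5e-14, 0.35)
  expect_identical(p1$g[p1$r_cm == 1], 1)
  expect_identical(unname(p1$F[, p1$theta_deg == 90]),
                   rep(1, length(p1$r_cm)))
  # also on a real (tiny) Monte Carlo map
  ann <- simulate_seed_water(seed_6711(), 2e4, rng_seed = 5)
  sk <- score_air_kerma_strength(seed_6711(), 2e4, rng_seed = 6)
  pr <- extract_parameters(ann, sk, 0.3)
  expect_equal(pr$g[pr$r_cm == 1], 1)
  expect_equal(unname(pr$F[, pr$theta_deg == 90]), rep(1, length(pr$r_cm)))
})

test_that("extraction errors name the offending cell", {
  p0 <- synthetic_params()
  ann <- synthetic_annular(p0)
  ann$value[ann$r_cm == 1, ann$theta_deg == 90] <- 0
  expect_error(extract_parameters(ann, 1e-14, 0.35), "reference cell")
  ann2 <- synthetic_annular(p0)
  ann2$r_cm[ann2$r_cm == 1] <- 1.01
  expect_error(extract_parameters(ann2, 1e-14, 0.35), "reference cell")
  expect_error(extract_parameters(synthetic_annular(p0), -1, 0.35), "S_K")
})

test_that("forward dose: reference identity, inverse square, round trip", {
  p <- synthetic_params()
  SK <- 1.7
  expect_equal(forward_dose(p, SK, 1, 90), SK * p$Lambda, tolerance = 1e-12)
  # g == 1, F == 1, tiny L: pure inverse square
  pu <- p
  pu$g[] <- 1; pu$F[] <- 1; pu$L_cm <- 1e-7
  d <- forward_dose(pu, SK, c(1, 2), 90)
  expect_equal(d[1] / d[2], 4, tolerance = 1e-6)
  # dense-grid round trip at 1e-6
  rg <- p$r_cm; tg <- p$theta_deg
  D <- outer(seq_along(rg), seq_along(tg),
             function(i, j) forward_dose(p, 1, rg[i], tg[j]))
  ann <- synthetic_annular(p, 1)
  expect_equal(unname(D), unname(ann$value / 1), tolerance = 1e-9)
  p2 <- extract_parameters(
    structure(list(r_cm = rg, theta_deg = tg, value = D, var = 0 * D),
              class = "annular_map"), 1, p$L_cm)
  expect_equal(p2$Lambda, p$Lambda, tolerance = 1e-6)
  expect_equal(p2$g, p$g, tolerance = 1e-6)
  expect_equal(p2$F, p$F, tolerance = 1e-6)
})

test_that("radial extrapolation is bounded and flagged beyond the policy", {
  p <- synthetic_params()
  expect_false(is.na(forward_dose(p, 1, 11.5, 90)))   # within 20% of 10 cm
  expect_true(is.na(forward_dose(p, 1, 12.5, 90)))    # beyond -> flagged
  expect_true(is.na(forward_dose(p, 1, 0.15, 90)))
})

test_that("plan superposition is linear and matches a brute-force loop", {
  p <- synthetic_params()
  one <- list(list(pose = pose(), S_K = 0.6))
  pts <- cbind(runif(40, -30, 30), runif(40, -30, 30), runif(40, -30, 30))
  d1 <- superpose_plan(p, one, pts)
  r <- sqrt(rowSums(pts^2)) / 10
  th <- acos(pts[, 3] / (10 * r)) * 180 / pi
  expect_equal(d1, forward_dose(p, 0.6, r, th), tolerance = 1e-12)
  # two co-located seeds double the dose exactly
  d2 <- superpose_plan(p, c(one, one), pts)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  expect_error(superpose_plan(p, list(), pts), "nonempty")

  # 67-seed fixture against a naive double loop
  pel <- fixture("pelvis", make_pelvis_phantom(dims = c(64, 64, 24),
                                               spacing_mm = c(1.5625, 1.5625, 4)))
  plan <- make_plan_67(pel)
  entries <- lapply(seq_len(nrow(plan)), function(i)
    list(pose = pose(c(plan$x[i], plan$y[i], plan$z[i])), S_K = plan$S_K[i]))
  grid <- list(origin_mm = c(-20, -20, -8), spacing_mm = c(8, 8, 8),
               dims = c(5, 5, 2))
  dm <- superpose_plan(p, entries, grid)
  # naive reference: loop over grid points and seeds
  gx <- grid$origin_mm[1] + (1:5 - 0.5) * 8
  gy <- grid$origin_mm[2] + (1:5 - 0.5) * 8
  gz <- grid$origin_mm[3] + (1:2 - 0.5) * 8
  ref <- array(0, c(5, 5, 2))
  for (i in 1:5) for (j in 1:5) for (k in 1:2) {
    tot <- 0
    for (e in entries) {
      v <- c(gx[i], gy[j], gz[k]) - e$pose$t
      rr <- sqrt(sum(v^2)) / 10
      tt <- acos(v[3] / (10 * rr)) * 180 / pi
      tot <- tot + forward_dose(p, e$S_K, rr, tt)
    }
    ref[i, j, k] <- tot
  }
  expect_equal(dm$value, ref, tolerance = 1e-9)
})

test_that("extracted g is stable under doubled radial bin resolution", {
  # voxel-averaging guard on a smooth synthetic field: halving the shell
  # thickness changes g by far less than 1%
  p <- synthetic_params()
  r <- p$r_cm
  shell_g <- function(half) {
    # analytic shell average of the forward dose over [r(1-h), r(1+h)]
    gavg <- vapply(r, function(ri) {
      rs <- seq(ri * (1 - half), ri * (1 + half), length.out = 101)
      mean(forward_dose(p, 1, rs, 90) * rs^2) / ri^2
    }, 0)
    gavg / gavg[r == 1]
  }
  g1 <- shell_g(0.05)
  g2 <- shell_g(0.025)
  expect_lt(max(abs(g2 / g1 - 1)), 0.01)
})
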