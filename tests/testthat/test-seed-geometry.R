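# Seed models: construction, emission sampling, ray tracing.

test_that("all six seed ids build distinct, valid models", {
  ids <- c("AmershamOncoseed6711", "BebigIsoseedI25S06", "NucletronMHDRv1",
           "VarianVS2000", "SpecM19", "NucletronMPDRv2")
  models <- lapply(ids, build_seed)
  sigs <- vapply(models, function(m)
    paste(m$components$kind, m$components$r_mm, m$components$half_mm,
          m$components$material, collapse = "|"), "")
  expect_equal(length(unique(sigs)), 6)
  for (m in models) {
    expect_gt(m$L_mm, 0)
    expect_true(m$active_component %in% m$components$name)
    # every emission position lies inside the outer solid
    em <- sample_emission(m, 500, rng_seed = 3)
    d <- brachymc:::cpp_outer_surface_distance(m$cpp, em$position)
    expect_true(all(d < 1e-9), label = m$id)
  }
  expect_error(build_seed("NoSuchSeed"), "unknown seed id")
})

test_that("nuclides follow the source listing", {
  expect_equal(seed_6711()$nuclide, "I125")
  expect_equal(build_seed("BebigIsoseedI25S06")$nuclide, "I125")
  expect_equal(seed_mhdr()$nuclide, "Ir192")
  expect_equal(build_seed("VarianVS2000")$nuclide, "Ir192")
  expect_equal(build_seed("NucletronMPDRv2")$nuclide, "Ir192")
})

test_that("active-region volume matches a rejection-sampling estimate", {
  # Monte Carlo point-in-solid oracle on the bounding box of the Ir core
  sd <- seed_mhdr()
  row <- sd$components[sd$components$name == "core", ]
  n <- 4e4
  set.seed(5)
  pts <- cbind(runif(n, -row$r_mm, row$r_mm), runif(n, -row$r_mm, row$r_mm),
               runif(n, -row$half_mm, row$half_mm))
  vbox <- (2 * row$r_mm)^2 * (2 * row$half_mm)
  inside <- brachymc:::cpp_component_at(sd$cpp, pts) == 1
  vol_mc <- vbox * mean(inside)
  se <- vbox * sqrt(mean(inside) * (1 - mean(inside)) / n)
  expect_within_sigma(vol_mc, component_volume(sd, "core"), se)
})

test_that("emission positions fill the active region correctly", {
  # volume mode: z uniform over [-L/2, L/2] (KS test), marker volume excluded
  sd <- seed_bebig()
  em <- sample_emission(sd, 1e4, rng_seed = 9)
  comp <- brachymc:::cpp_component_at(sd$cpp, em$position)
  active_idx <- match(sd$active_component, sd$components$name)
  expect_true(all(comp == active_idx))
  ks <- suppressWarnings(
    stats::ks.test(em$position[, 3], "punif", -sd$L_mm / 2, sd$L_mm / 2))
  expect_gt(ks$p.value, 0.01)
  # directions isotropic: mean vector ~ 0 within 3 sigma per component
  for (a in 1:3)
    expect_within_sigma(mean(em$direction[, a]), 0, sqrt(1 / 3 / 1e4))
  # surface mode (6711): all positions at the silver rod radius
  em2 <- sample_emission(seed_6711(), 2000, rng_seed = 4)
  r <- sqrt(em2$position[, 1]^2 + em2$position[, 2]^2)
  expect_true(all(abs(r - 0.25) < 2e-6))
  expect_true(all(abs(em2$position[, 3]) <= 1.5 + 2e-6))
})

test_that("axial trace reproduces the hand-computed material stack", {
  # 6711 data file: 1.5 mm silver + 0.7 mm air + 0.05 mm titanium along +Z
  tr <- trace_ray(seed_6711(), c(0, 0, 0), c(0, 0, 1))
  expect_equal(tr$material, c("Silver", "Air", "Titanium"))
  expect_equal(tr$length_mm, c(1.5, 0.7, 0.05), tolerance = 1e-9)
  expect_equal(sum(tr$length_mm), 2.25, tolerance = 1e-9)
})

test_that("rays outside pointing away see nothing; chords are conserved", {
  s <- seed_6711()
  tr <- trace_ray(s, c(5, 0, 0), c(1, 0, 0))
  expect_equal(nrow(tr), 0)
  # random interior rays: segment sum lands exactly on the outer surface
  set.seed(21)
  for (i in 1:50) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    o <- c(0, 0, runif(1, -1, 1))
    tr <- trace_ray(s, o, u)
    pt <- matrix(o + sum(tr$length_mm) * u, 1, 3)
    d <- brachymc:::cpp_outer_surface_distance(s$cpp, pt)
    expect_lt(abs(d), 1e-6)
  }
  expect_error(trace_ray(s, c(0, 0, 0), c(1, 1, 0)), "unit vector")
})

test_that("segment lengths are invariant under a common rotation", {
  s <- seed_6711()
  R <- pose(axis = c(1, 2, 3), angle_deg = 37)$R
  rot <- s
  rot$cpp$solids <- lapply(s$cpp$solids, function(sl) {
    sl$rot <- R
    sl$tr <- as.numeric(R %*% sl$tr)
    sl
  })
  set.seed(8)
  for (i in 1:25) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    o <- c(0, 0, runif(1, -1.5, 1.5))
    t1 <- brachymc:::cpp_trace(s$cpp, o, u)
    t2 <- brachymc:::cpp_trace(rot$cpp, as.numeric(R %*% o), as.numeric(R %*% u))
    expect_equal(t2, t1, tolerance = 1e-8)
  }
})

test_that("poses are orthonormal rigid transforms", {
  p <- pose(translation = c(1, 2, 3), axis = c(0, 1, 0), angle_deg = 90)
  expect_equal(det(p$R), 1, tolerance = 1e-12)
  expect_equal(t(p$R) %*% p$R, diag(3), tolerance = 1e-12)
  out <- apply_pose(p, points = matrix(c(1, 0, 0), 1, 3),
                    directions = matrix(c(1, 0, 0), 1, 3))
  expect_equal(as.numeric(out$points), c(1, 2, 2), tolerance = 1e-12)
  expect_equal(as.numeric(out$directions), c(0, 0, -1), tolerance = 1e-12)
})
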