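# HU conversion, synthetic pelvis fixture, plan simulation, cDVH, isodose,
# map comparison, MetaImage IO.

test_that("HU conversion assigns materials by closed-open intervals", {
  hu <- array(0, c(4, 4, 2))
  ph <- hu_to_phantom(hu, c(1, 1, 1))
  expect_true(all(ph$materials[ph$material_ids] == "SoftTissue"))
  # boundary values belong to the upper interval
  hu2 <- array(c(-600, 99.9, 100, 300, 4000, -1050, 0, 150), c(2, 2, 2))
  msk <- array(TRUE, c(2, 2, 2))
  ph2 <- hu_to_phantom(hu2, c(1, 1, 1), prostate_mask = msk)
  got <- ph2$materials[ph2$material_ids]
  expect_equal(got[1], "SoftTissue")       # -600 -> upper interval
  expect_equal(got[3], "ProstateICRU")     # 100 boundary -> prostate
  expect_equal(got[4], "CorticalBone")     # 300 boundary -> bone
  expect_equal(got[5], "CorticalBone")     # top edge included
  expect_equal(got[6], "Lung")
  # without a prostate mask the prostate interval falls back to soft tissue
  ph3 <- hu_to_phantom(hu2, c(1, 1, 1))
  expect_equal(ph3$materials[ph3$material_ids][3], "SoftTissue")
  # clamping is counted
  hu4 <- array(c(-2000, 5000, 0, 0), c(2, 2, 1))
  expect_message(ph4 <- hu_to_phantom(hu4, c(1, 1, 1)), "clamped")
  expect_equal(attr(ph4, "n_clamped"), 2)
  expect_error(hu_to_phantom(array(0, c(0, 0, 0)), c(1, 1, 1)), "empty")
})

test_that("pelvis fixture fractions follow its own HU construction", {
  pel <- fixture("pelvis", make_pelvis_phantom(dims = c(64, 64, 24),
                                               spacing_mm = c(1.5625, 1.5625, 4)))
  ph <- pel$phantom
  got <- table(ph$materials[ph$material_ids])
  hu <- pel$hu
  map <- default_hu_map()
  expect_equal(unname(got[["Lung"]]), sum(hu >= -1050 & hu < -600))
  expect_equal(unname(got[["CorticalBone"]]), sum(hu >= 300))
  expect_equal(unname(got[["ProstateICRU"]]),
               sum(hu >= 100 & hu < 300 & pel$masks$prostate))
  expect_true(all(pel$masks$urethra | !pel$masks$urethra))
  expect_gt(sum(pel$masks$prostate), 500)
})

test_that("cDVH matches a brute-force sort-and-count and is monotone", {
  set.seed(31)
  v <- array(stats::rexp(4^3), c(4, 4, 4))
  map <- list(value = v, var = 0 * v, n_histories = 10)
  mask <- array(stats::runif(4^3) < 0.6, c(4, 4, 4))
  edges <- seq(0, max(v), length.out = 37)
  cd <- compute_cdvh(map, mask, edges)
  naive <- vapply(edges, function(e) 100 * sum(v[mask] >= e) / sum(mask), 0)
  expect_equal(cd$volume_pct, naive)
  expect_equal(cd$volume_pct[1], 100)
  expect_true(all(diff(cd$volume_pct) <= 0))
  # uniform dose: step function
  mapu <- list(value = array(2, c(2, 2, 2)), var = array(0, c(2, 2, 2)))
  cdu <- compute_cdvh(mapu, array(TRUE, c(2, 2, 2)), edges = c(0, 1, 2, 3))
  expect_equal(cdu$volume_pct, c(100, 100, 100, 0))
  expect_error(compute_cdvh(map, array(FALSE, c(4, 4, 4))), "empty")
  expect_error(compute_cdvh(map, array(TRUE, c(2, 2, 2))), "mismatch")
})

test_that("isodose masks are strict, nested, and count-exact", {
  set.seed(7)
  v <- array(stats::runif(6^3, 0, 2), c(6, 6, 6))
  map <- list(value = v)
  iso <- isodose_masks(map, prescription = 1, thresholds_pct = c(50, 100, 150))
  expect_true(all(iso[["150%"]] <= iso[["100%"]]))
  expect_true(all(iso[["100%"]] <= iso[["50%"]]))
  expect_equal(sum(iso[["50%"]]), sum(v > 0.5))
  expect_equal(sum(iso[["100%"]]), sum(v > 1.0))
  # uniform map at exactly 100% of prescription: strict > empties 100/150
  mapu <- list(value = array(1, c(3, 3, 3)))
  isou <- isodose_masks(mapu, 1)
  expect_equal(sum(isou[["50%"]]), 27)
  expect_equal(sum(isou[["100%"]]), 0)
  expect_equal(sum(isou[["150%"]]), 0)
  # invariant under a monotone transform of dose + prescription scale
  iso2 <- isodose_masks(list(value = v * 3), prescription = 3)
  expect_identical(iso, iso2)
})

test_that("map comparison has the stated closed forms", {
  v <- array(stats::runif(5^3, 1, 2), c(5, 5, 5))
  a <- list(value = v, var = 0 * v, origin_mm = c(0, 0, 0),
            spacing_mm = c(1, 1, 1), dims = c(5, 5, 5))
  b <- a
  cmp <- compare_maps(a, b, sigma_gate_pct = 5)
  expect_equal(cmp$average_pct, 0)
  expect_equal(cmp$maximum_pct, 0)
  b$value <- 1.1 * a$value
  cmp2 <- compare_maps(a, b)
  expect_equal(cmp2$diff_pct[!is.na(cmp2$diff_pct)],
               rep(-100 * 0.1 / 1.05, 5), tolerance = 1e-9)
  expect_equal(cmp2$average_pct, 100 * 0.1 / 1.05, tolerance = 1e-9)
  expect_gte(cmp2$maximum_pct, cmp2$average_pct)
  # the sigma gate excludes noisy points
  a2 <- a; a2$var <- (0.2 * a$value)^2
  cmp3 <- compare_maps(a2, b, sigma_gate_pct = 5)
  expect_true(all(is.na(cmp3$diff_pct)))
  bbad <- list(value = array(1, c(4, 4, 4)), var = array(0, c(4, 4, 4)))
  expect_error(compare_maps(a, bbad), "mismatch")
})

test_that("plan dose scales linearly with S_K and matches direct simulation", {
  pel <- fixture("pelvis_small", {
    p <- make_pelvis_phantom(dims = c(40, 40, 16), spacing_mm = c(2.5, 2.5, 5))
    p
  })
  s <- seed_6711()
  ph <- fixture("phsp_6711_mid", generate_phsp(s, 2e4, rng_seed = 72))
  plan <- make_plan_67(pel, n_seeds = 8)
  d1 <- simulate_plan_mc(plan, pel$phantom, ph, n_histories = 2e4, rng_seed = 5)
  plan2 <- plan; plan2$S_K <- plan$S_K * 2
  d2 <- simulate_plan_mc(plan2, pel$phantom, ph, n_histories = 2e4, rng_seed = 5)
  expect_equal(d2$value, 2 * d1$value, tolerance = 1e-12)
  expect_error(simulate_plan_mc(plan, pel$phantom,
                                list(Other = ph), 100, 1), "no phase-space")

  # one seed replayed into an all-water phantom vs direct seed-in-water
  dims <- c(25, 25, 25); sp <- c(2, 2, 2); org <- -dims * sp / 2
  wat <- voxel_phantom(array(1L, dims), "Water", sp, org)
  plan1 <- data.frame(seed_id = s$id, x = 0, y = 0, z = 0, axis_x = 0,
                      axis_y = 0, axis_z = 1, angle_deg = 0, S_K = 1)
  n <- 2e5
  esc <- ph$header$n_records / ph$header$n_primary
  dv <- simulate_plan_mc(plan1, wat, ph, n_histories = n, rng_seed = 31)
  wd <- world_homogeneous("Water", radius_cm = 15, seed = s)
  sc <- scorer_cartesian(org, sp, dims, medium = "Water")
  rd <- run_transport(wd, source_seed(s), sim_config(round(n / esc), 32),
                      list(d = sc))
  sa <- estimate_uncertainty(rd$maps$d); sv <- estimate_uncertainty(dv)
  ok <- !is.na(sa) & !is.na(sv) & sa < 0.05 & sv < 0.05
  expect_gt(sum(ok), 50)
  # latent noise of the finite record file enters the combined sigma
  z <- (rd$maps$d$value[ok] / esc - dv$value[ok]) /
    sqrt(rd$maps$d$var[ok] / esc^2 + dv$var[ok] +
         (0.05 * dv$value[ok])^2)
  expect_lt(mean(abs(z) > 3), 0.02)
})

test_that("MetaImage volumes round-trip through .mhd/.raw", {
  set.seed(9)
  v <- array(stats::runif(24), c(4, 3, 2))
  f <- file.path(tempdir(), "vol.mhd")
  write_mhd(v, f, spacing_mm = c(1, 2, 3), origin_mm = c(-2, 0, 1))
  back <- read_mhd(f)
  expect_equal(back$data, v, tolerance = 1e-6)      # float32 storage
  expect_equal(back$spacing_mm, c(1, 2, 3))
  expect_equal(back$origin_mm, c(-2, 0, 1))
  unlink(c(f, sub("mhd$", "raw", f)))
})
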