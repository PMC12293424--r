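test_that("standard ROI pairs reproduce the template layout", {
  pairs <- standard_roi_pairs()
  expect_identical(nrow(pairs), 9L)
  expect_identical(nrow(unique(pairs[, c("y", "z")])), 9L)
  expect_true(all(pairs$proj_x == -26))
  expect_true(all(pairs$assoc_x == -37))
  expect_setequal(unique(pairs$y), c(-17, -27, -29))
  expect_setequal(unique(pairs$z), c(29, 30, 31))
  expect_true(all(pairs$proj_x < 0 & pairs$assoc_x < 0))  # left hemisphere
  expect_true(all(pairs$edge_nominal >= pairs$edge_refined))
  p <- pairs[pairs$y == -27 & pairs$z == 29, ]
  expect_identical(c(p$proj_x, p$y, p$z), c(-26, -27, 29))
  expect_identical(c(p$assoc_x, p$y, p$z), c(-37, -27, 29))
  # right hemisphere mirrors x; both concatenates
  expect_true(all(standard_roi_pairs("right")$proj_x == 26))
  expect_identical(nrow(standard_roi_pairs("both")), 18L)
})

test_that("ROI voxelization follows the half-open cube convention", {
  aff <- diag(c(1, 1, 1, 1)); aff[1:3, 4] <- -2  # 1 mm voxels, centers -2..2
  vox <- voxelize_roi(c(0, 0, 0), 2, aff, c(5L, 5L, 5L))
  expect_identical(nrow(vox), 8L)
  mm <- t(apply(vox, 1, function(v) v - 1 - 2))
  expect_true(all(mm >= -1 & mm < 1))

  aff2 <- diag(c(2, 2, 2, 1)); aff2[1:3, 4] <- -4  # 2 mm voxels
  vox2 <- voxelize_roi(c(0, 0, 0), 2, aff2, c(5L, 5L, 5L))
  expect_identical(nrow(vox2), 1L)
  expect_identical(as.vector(vox2), c(3L, 3L, 3L))
})

test_that("voxelization equals a brute-force inclusion scan for random affines", {
  set.seed(42)
  for (r in 1:10) {
    # random rotation, anisotropic scale, translation
    qrd <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qrd) %*% diag(runif(3, 0.8, 2.5))
    aff <- rbind(cbind(R, rnorm(3, sd = 3)), c(0, 0, 0, 1))
    dim3 <- c(7L, 6L, 5L)
    center <- rnorm(3, sd = 2)
    edge <- runif(1, 1, 5)
    got <- voxelize_roi(center, edge, aff, dim3)
    want <- oracle_voxels_in_cube(center, edge, aff, dim3)
    got <- got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE]
    want <- want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE]
    expect_equal(unname(as.matrix(got)) * 1.0, unname(as.matrix(want)) * 1.0)
  }
})

test_that("refinement keeps well-placed ROIs and rejects misaligned ones", {
  spec <- small_spec()
  tv <- build_phantom(spec)
  em <- eigen_decompose(tv)
  pairs <- refine_and_validate(standard_roi_pairs(), em)
  expect_true(all(pairs$status == "active"))
  expect_true(all(pairs$shift_x == 0 & pairs$shift_y == 0))
  expect_true(all(pairs$score_proj == 1 & pairs$score_assoc == 1))

  # an ROI pair fully in isotropic background is excluded
  bg <- standard_roi_pairs()
  bg$y <- bg$y - 30  # outside the fiber blocks (y in [-34,-12))
  bg <- refine_and_validate(bg, em)
  expect_true(all(bg$status == "excluded(misaligned)"))
})

test_that("refinement picks the shift a brute-force candidate scan selects", {
  spec <- small_spec()
  tv <- build_phantom(spec)
  em <- eigen_decompose(tv)
  # displace a pair so its projection ROI lands just outside the block:
  # at shift 0 the cube [-34.5, -32.5) only covers an association voxel
  pairs <- standard_roi_pairs()[5, , drop = FALSE]
  pairs$proj_x <- -33.5
  pairs$assoc_x <- -40.5
  got <- refine_and_validate(pairs, em)
  # independent 9-candidate evaluation
  best <- c(score = -Inf, sx = NA, sy = NA)
  for (sx in c(-1, 0, 1)) for (sy in c(-1, 0, 1)) {
    score <- min(
      mean(apply(voxelize_roi(c(pairs$proj_x + sx, pairs$y + sy, pairs$z), 2,
                              em$affine, dim(em$flags)), 1,
                 function(v) which.max(abs(em$v1[v[1], v[2], v[3], ])) == 3)),
      mean(apply(voxelize_roi(c(pairs$assoc_x + sx, pairs$y + sy, pairs$z), 2,
                              em$affine, dim(em$flags)), 1,
                 function(v) which.max(abs(em$v1[v[1], v[2], v[3], ])) == 2)))
    better <- score > best["score"] + 1e-12 ||
      (abs(score - best["score"]) <= 1e-12 &&
         sx^2 + sy^2 < best["sx"]^2 + best["sy"]^2)
    if (better) best <- c(score = score, sx = sx, sy = sy)
  }
  expect_equal(got$shift_x, unname(best["sx"]))
  expect_equal(got$shift_y, unname(best["sy"]))
  expect_true(startsWith(got$status, "adjusted"))
})

test_that("quad extraction: uniform fields, explicit means, oracle fields", {
  tv <- uniform_tensor_volume(c(1.1e-3, 0.5e-3, 0.3e-3),
                              dim = c(30L, 10L, 10L),
                              affine = {
                                a <- diag(c(2, 2, 2, 1))
                                a[1:3, 4] <- c(-50, -30, 24); a
                              })
  pair <- data.frame(pair_id = "p", proj_x = -26, assoc_x = -37, y = -27,
                     z = 29, edge_nominal = 3, edge_refined = 2,
                     status = "active", shift_x = 0, shift_y = 0)
  q <- extract_quad(tv, pair)
  expect_equal(c(q$Dxx_proj, q$Dxx_assoc, q$Dyy_proj, q$Dzz_assoc),
               c(1.1e-3, 1.1e-3, 0.5e-3, 0.3e-3))

  # two-voxel ROI arithmetic: 1 mm voxels along x -> the 2 mm cube holds 2
  aff <- diag(c(1, 2, 2, 1)); aff[1:3, 4] <- c(-50, -30, 24)
  tv2 <- uniform_tensor_volume(c(0, 0, 0), dim = c(40L, 10L, 10L),
                               affine = aff)
  vox <- voxelize_roi(c(-26, -27, 29), 2, aff, dim(tv2$D)[1:3])
  expect_identical(nrow(vox), 2L)
  tv2$D[vox[1, 1], vox[1, 2], vox[1, 3], 1] <- 1.0e-3
  tv2$D[vox[2, 1], vox[2, 2], vox[2, 3], 1] <- 1.2e-3
  tv2$D[, , , 2:3] <- 1e-3
  q2 <- extract_quad(tv2, pair)
  expect_equal(q2$Dxx_proj, 1.1e-3)

  # random field vs per-voxel accumulation oracle
  set.seed(7)
  tv3 <- uniform_tensor_volume(c(0, 0, 0), dim = c(30L, 10L, 10L),
                               affine = {
                                 a <- diag(c(2, 2, 2, 1))
                                 a[1:3, 4] <- c(-50, -30, 24); a
                               })
  tv3$D <- array(abs(rnorm(length(tv3$D), 1e-3, 2e-4)), dim(tv3$D))
  pv <- voxelize_roi(c(-26, -27, 29), 2, tv3$affine, dim(tv3$D)[1:3])
  av <- voxelize_roi(c(-37, -27, 29), 2, tv3$affine, dim(tv3$D)[1:3])
  q3 <- extract_quad(tv3, pair)
  want <- oracle_quad(tv3, pv, av)
  expect_equal(c(q3$Dxx_proj, q3$Dxx_assoc, q3$Dyy_proj, q3$Dzz_assoc),
               unname(want), tolerance = 1e-12)
})

test_that("flagged voxels are excluded and empty ROIs error", {
  tv <- uniform_tensor_volume(c(1e-3, 1e-3, 1e-3), dim = c(30L, 10L, 10L),
                              affine = {
                                a <- diag(c(2, 2, 2, 1))
                                a[1:3, 4] <- c(-50, -30, 24); a
                              })
  pair <- data.frame(pair_id = "p", proj_x = -26, assoc_x = -37, y = -27,
                     z = 29, edge_nominal = 3, edge_refined = 2,
                     status = "active", shift_x = 0, shift_y = 0)
  flags <- array(TRUE, dim(tv$D)[1:3])
  expect_error(extract_quad(tv, pair, flags = flags), "empty_roi")
})

test_that("the ALPS ratio: identity, calibration, invariances", {
  expect_equal(alps_index(c(7e-4, 7e-4, 7e-4, 7e-4)), 1)
  expect_equal(round(alps_index(c(1.000e-3, 1.000e-3, 0.699e-3, 0.699e-3)), 4),
               1.4306)
  q <- c(1.1e-3, 0.9e-3, 0.6e-3, 0.8e-3)
  expect_equal(alps_index(q * 3.3), alps_index(q))
  expect_equal(alps_index(q[c(2, 1, 3, 4)]), alps_index(q))  # numerator symmetry
  expect_error(alps_index(c(1e-3, 1e-3, -1e-3, 0)), "denominator")
})

test_that("percent change against the awake baseline", {
  ser <- data.frame(subject = "S1", pair_id = "p",
                    time = c("awake", "14.46", "19.46"),
                    minutes = c(-9, 14.46, 19.46),
                    alps = c(1.43, 1.43, 1.43 * 1.1057 / 0.9196))
  pc <- percent_change_series(ser)
  expect_equal(pc$pct_change[pc$time == "14.46"], 0)
  expect_equal(round(100 * pc$pct_change[pc$time == "19.46"], 2), 20.24)
  expect_lt(abs(pc$pct_change[pc$time == "19.46"] - 0.2023), 2e-4)

  only_awake <- ser[1, , drop = FALSE]
  expect_identical(nrow(percent_change_series(only_awake)), 0L)
  expect_error(percent_change_series(ser[-1, ]), "awake")
})

test_that("component decomposition satisfies the exact ratio identity", {
  quads <- data.frame(time = c("awake", "19.46"),
                      Dxx_proj = c(1e-3, 1e-3 * 1.0351),
                      Dxx_assoc = c(1e-3, 1e-3 * 1.0351),
                      Dyy_proj = c(0.699e-3, 0.699e-3 * 0.8568),
                      Dzz_assoc = c(0.699e-3, 0.699e-3 * 0.8568))
  dec <- decompose_components(quads)
  expect_equal(round(100 * dec$d_index, 2), 20.81)
  expect_equal(dec$d_num, 0.0351, tolerance = 1e-12)
  expect_equal(dec$d_den, -0.1432, tolerance = 1e-12)

  same <- quads; same[2, -1] <- same[1, -1]
  dec0 <- decompose_components(same)
  expect_equal(unlist(dec0[, c("d_num", "d_den", "d_index")]),
               c(d_num = 0, d_den = 0, d_index = 0))

  set.seed(11)
  for (r in 1:20) {
    q <- data.frame(time = c("awake", "t"),
                    Dxx_proj = runif(2, 5e-4, 2e-3),
                    Dxx_assoc = runif(2, 5e-4, 2e-3),
                    Dyy_proj = runif(2, 5e-4, 2e-3),
                    Dzz_assoc = runif(2, 5e-4, 2e-3))
    d <- decompose_components(q)
    expect_equal((1 + d$d_index) * (1 + d$d_den), 1 + d$d_num,
                 tolerance = 1e-12)
  }
})

test_that("index change is approximately the component-change difference", {
  traj <- default_state_trajectory()
  for (t in seq_len(nrow(traj))) {
    dn <- traj$a[t]; dd <- traj$b[t]
    di <- (1 + dn) / (1 + dd) - 1
    expect_lte(abs(di - (dn - dd)), abs(dn * dd) + 2 * dd^2)
  }
})

test_that("noiseless end-to-end pipeline reproduces the configured ratio", {
  spec <- small_spec()
  tv <- build_phantom(spec)
  dwi <- synthesize_dwi(tv, build_gradient_scheme(30L, c(800, 2800), 8L,
                                                  seed = 1L),
                        S0 = spec$S0, noise = "none")
  ft <- fit_tensor(select_shell(dwi, 800))
  em <- eigen_decompose(ft)
  pairs <- refine_and_validate(standard_roi_pairs(), em)
  expect_true(all(pairs$status == "active"))
  target <- (spec$lambda_radial + spec$pvs_dx) / spec$lambda_radial
  for (r in seq_len(nrow(pairs))) {
    idx <- alps_index(extract_quad(ft, pairs[r, , drop = FALSE]))
    expect_lt(abs(idx - target) / target, 1e-6)
  }
})
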