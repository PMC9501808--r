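test_that("rigid transforms validate their structure", {
  expect_error(rigid_transform(diag(c(1, 1, 2))), "proper orthogonal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper orthogonal")
  m <- rigid_transform(rot_z(30), c(1, 2, 3))
  expect_equal(m[4, ], c(0, 0, 0, 1))
  expect_equal(transform_translation(m), c(1, 2, 3))
  inv <- transform_inverse(m)
  expect_equal(unclass(inv %*% m), diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("superposition recovers a known transform", {
  set.seed(71)
  ref <- matrix(runif(30, -10, 10), ncol = 3)
  expect_equal(attr(superposition_transform(ref, ref), "rmsd"), 0,
               tolerance = 1e-10)
  sup0 <- superposition_transform(ref, ref)
  expect_equal(transform_rotation(sup0), diag(3), tolerance = 1e-9)
  for (i in 1:10) {
    tr <- rigid_transform(rand_rot(), runif(3, -15, 15))
    conf <- map_geometry(tr, points = ref)$points
    got <- superposition_transform(ref, conf)
    expect_equal(unclass(got), unclass(tr), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # collinear reference points are rejected
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superposition_transform(line, line), "collinear")
})

test_that("superposition tolerates coordinate noise", {
  set.seed(73)
  ref <- matrix(runif(60, -10, 10), ncol = 3)
  for (i in 1:5) {
    tr <- rigid_transform(rand_rot(), runif(3, -15, 15))
    conf <- map_geometry(tr, points = ref)$points +
      matrix(rnorm(length(ref), 0, 0.1), ncol = 3)
    got <- superposition_transform(ref, conf)
    rel <- t(transform_rotation(got)) %*% transform_rotation(tr)
    ang <- acos(pmin(1, (sum(diag(rel)) - 1) / 2)) * 180 / pi
    expect_lt(ang, 1)
  }
})

test_that("geometry mapping respects the rigid-motion group", {
  set.seed(79)
  t1 <- rigid_transform(rand_rot(), runif(3, -10, 10))
  t2 <- rigid_transform(rand_rot(), runif(3, -10, 10))
  pts <- matrix(runif(15, -5, 5), ncol = 3)
  vecs <- matrix(runif(15, -1, 1), ncol = 3)
  # pure translation leaves weight-0 vectors unchanged
  shift <- rigid_transform(diag(3), c(3, -4, 5))
  expect_equal(map_geometry(shift, vectors = vecs)$vectors, vecs)
  # composition as matrix product
  g12 <- map_geometry(t1 %*% t2, points = pts, vectors = vecs)
  g2 <- map_geometry(t2, points = pts, vectors = vecs)
  g1 <- map_geometry(t1, points = g2$points, vectors = g2$vectors)
  expect_equal(g12$points, g1$points, tolerance = 1e-10)
  expect_equal(g12$vectors, g1$vectors, tolerance = 1e-10)
  # inverse restores the originals
  back <- map_geometry(transform_inverse(t1),
                       points = map_geometry(t1, points = pts)$points)
  expect_equal(back$points, pts, tolerance = 1e-10)
})

test_that("transform flat files round trip", {
  set.seed(83)
  trs <- lapply(1:7, function(i) rigid_transform(rand_rot(), runif(3, -20, 20)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_transforms(trs, path)
  back <- read_transforms(path)
  expect_length(back, 7)
  for (i in 1:7) expect_equal(unclass(back[[i]]), unclass(trs[[i]]),
                              tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(read_transforms(textConnection("1 2 3")), "12 numbers")
})

test_that("prediction-matrix rows equal direct forward prediction", {
  sc <- small_scenario()
  sim <- simulate_restraints(sc, noiseless = TRUE)
  mob <- sim$mobile
  idx <- c(1, 5, 40, 77, 123, 200, 250, 299, 300, 150)
  pm <- build_prediction_matrix(sc$pool[idx], sc$tensors, sc$metal_position,
                                sc$mobile, mob, sc$conditions)
  for (j in seq_along(idx)) {
    moved <- sc$mobile
    moved[, c("x", "y", "z")] <-
      map_geometry(sc$pool[[idx[j]]],
                   points = as.matrix(sc$mobile[, c("x", "y", "z")]))$points
    direct <- predict_observables(moved, sc$metal_position, sc$tensors, mob,
                                  sc$conditions)
    expect_equal(pm[j, ], as.numeric(direct), tolerance = 1e-9)
  }
  # identity transform reproduces the untransformed reference
  pm1 <- build_prediction_matrix(list(rigid_transform()), sc$tensors,
                                 sc$metal_position, sc$mobile, mob,
                                 sc$conditions)
  ref <- predict_observables(sc$mobile, sc$metal_position, sc$tensors, mob,
                             sc$conditions)
  expect_equal(pm1[1, ], as.numeric(ref), tolerance = 1e-12)
})

test_that("RDC predictions are translation-invariant, PCS fall off as r^-3", {
  sc <- small_scenario()
  sim <- simulate_restraints(sc, noiseless = TRUE)
  mob <- sim$mobile
  R <- rand_rot()
  ta <- rigid_transform(R, c(5, -3, 2))
  tb <- rigid_transform(R, c(-8, 14, 6))
  pm <- build_prediction_matrix(list(ta, tb), sc$tensors, sc$metal_position,
                                sc$mobile, mob, sc$conditions)
  rdc_cols <- grepl("^RDC", mob$type)
  expect_equal(pm[1, rdc_cols], pm[2, rdc_cols], tolerance = 1e-12)

  # doubling the distance of a small far-away conformer scales PCS by ~1/8
  sc2 <- make_scenario(n_fixed = 4, n_mobile = 2, pool_size = 2,
                       planted_size = 1, metals = "Tb", shell = c(30, 30),
                       seed = 31)
  sim2 <- simulate_restraints(sc2, noiseless = TRUE)
  mob2 <- sim2$mobile
  # compact the domain so every nucleus sits close to the centroid and the
  # translation is a nearly pure radial move for all of them
  xyz <- as.matrix(sc2$mobile[, c("x", "y", "z")])
  com0 <- colMeans(xyz)
  sc2$mobile[, c("x", "y", "z")] <- sweep(sweep(xyz, 2, com0) * 0.2, 2, com0, "+")
  com <- colMeans(as.matrix(sc2$mobile[, c("x", "y", "z")]))
  t1 <- rigid_transform(diag(3), c(30, 0, 0) - com)
  t2 <- rigid_transform(diag(3), c(60, 0, 0) - com)
  pm2 <- build_prediction_matrix(list(t1, t2), sc2$tensors,
                                 sc2$metal_position, sc2$mobile, mob2,
                                 sc2$conditions,
                                 options = predict_options(rcsa = FALSE))
  pcs_cols <- mob2$type == "PCS"
  ratio <- pm2[1, pcs_cols] / pm2[2, pcs_cols]
  expect_true(all(ratio > 5.5 & ratio < 11))
  expect_equal(mean(ratio), 8, tolerance = 0.15)
})

test_that("the memory guard refuses oversized matrices unless overridden", {
  sc <- small_scenario()
  sim <- simulate_restraints(sc, noiseless = TRUE)
  expect_error(build_prediction_matrix(sc$pool, sc$tensors, sc$metal_position,
                                       sc$mobile, sim$mobile, sc$conditions,
                                       max_entries = 100),
               "max_entries")
})

test_that("optimal pivot recovers a common rotation center", {
  set.seed(89)
  center <- c(4, -7, 2)
  # pure rotations about `center`: t = (I - R) c
  trs <- lapply(1:6, function(i) {
    R <- rand_rot()
    rigid_transform(R, drop((diag(3) - R) %*% center))
  })
  piv <- optimal_pivot(trs)
  expect_equal(piv$origin, center, tolerance = 1e-8)
  expect_true(all(piv$residual_lengths < 1e-8))
  # a single rotating transform is always exactly solvable
  one <- optimal_pivot(trs[1])
  expect_lt(one$residual_lengths, 1e-8)
  # identity-only ensembles have no defined pivot
  expect_error(optimal_pivot(list(rigid_transform())), "indeterminate")
})

test_that("no pivot removes 15 A of incoherent translation", {
  set.seed(97)
  center <- c(2, 3, -1)
  trs <- lapply(1:8, function(i) {
    R <- rand_rot()
    eps <- rnorm(3)
    eps <- eps / sqrt(sum(eps^2)) * 15
    rigid_transform(R, drop((diag(3) - R) %*% center) + eps)
  })
  piv <- optimal_pivot(trs)
  expect_gt(piv$mean_residual, 11)
  expect_lt(piv$mean_residual, 17)
  # the fitted origin beats 100 random alternatives
  obj <- function(o) {
    mean(vapply(trs, function(m) {
      sum((transform_translation(m) +
             drop((transform_rotation(m) - diag(3)) %*% o))^2)
    }, numeric(1)))
  }
  base <- obj(piv$origin)
  for (i in 1:100) expect_gte(obj(piv$origin + runif(3, -10, 10)), base - 1e-9)
})
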