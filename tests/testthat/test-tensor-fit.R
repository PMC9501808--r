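# Shared fixture: one-metal restraint set from the standard small scenario.
fit_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- small_scenario()
      sim <- simulate_restraints(sc, noiseless = TRUE)
      sub <- sim$fixed[sim$fixed$metal == "Tb", ]
      rownames(sub) <- NULL
      cache <<- list(sc = sc, restraints = sub, truth = sc$tensors$Tb)
    }
    cache
  }
})

test_that("the linear system reproduces forward predictions for any tensor", {
  fx <- fit_fixture()
  sys <- assemble_linear_system(fx$sc$fixed, fx$sc$metal_position,
                                fx$restraints, fx$sc$conditions)
  set.seed(51)
  for (i in 1:20) {
    v <- runif(5, -5, 5)
    chi <- chi_tensor(v[1], v[2], v[3], v[4], v[5], convention = "element")
    direct <- predict_observables(fx$sc$fixed, fx$sc$metal_position, chi,
                                  fx$restraints, fx$sc$conditions)
    expect_equal(drop(sys$A %*% v), as.numeric(direct), tolerance = 1e-9)
  }
  # a duplicated record yields an identical row
  dup <- rbind(fx$restraints, fx$restraints[4, ])
  sys2 <- assemble_linear_system(fx$sc$fixed, fx$sc$metal_position, dup,
                                 fx$sc$conditions)
  expect_equal(sys2$A[nrow(sys2$A), ], sys2$A[4, ])
  expect_error(assemble_linear_system(fx$sc$fixed, fx$sc$metal_position,
                                      fx$restraints[0, ], fx$sc$conditions),
               "empty")
})

test_that("noiseless data recover the tensor exactly with Q = 0", {
  fx <- fit_fixture()
  fit <- fit_tensor(fx$sc$fixed, fx$sc$metal_position, fx$restraints,
                    fx$sc$conditions)
  expect_lt(max(abs(fit$chi$components - fx$truth$components)), 1e-8)
  expect_lt(fit$Q, 1e-10)
  expect_true(all(fit$Q_group < 1e-10))
  # predicting zeros corresponds to Q = 1
  expect_equal(q_factor(fx$restraints$value, 0 * fx$restraints$value), 1)
})

test_that("the fit is order-independent and weight-consistent", {
  fx <- fit_fixture()
  sim <- simulate_restraints(fx$sc)
  sub <- sim$fixed[sim$fixed$metal == "Tb", ]
  f1 <- fit_tensor(fx$sc$fixed, fx$sc$metal_position, sub, fx$sc$conditions)
  set.seed(53)
  perm <- sample(nrow(sub))
  f2 <- fit_tensor(fx$sc$fixed, fx$sc$metal_position, sub[perm, ],
                   fx$sc$conditions)
  expect_equal(f1$chi$components, f2$chi$components, tolerance = 1e-10)
  expect_equal(f1$Q, f2$Q, tolerance = 1e-12)
  f3 <- fit_tensor(fx$sc$fixed, fx$sc$metal_position, sub, fx$sc$conditions,
                   weights = 2.5)
  expect_equal(f1$chi$components, f3$chi$components, tolerance = 1e-10)
  expect_equal(f1$Q, f3$Q, tolerance = 1e-12)
  # stored residuals reproduce the stored Q
  expect_equal(f1$Q, q_factor(f1$values, f1$fitted, f1$weights),
               tolerance = 1e-12)
})

test_that("rank-deficient geometry is rejected with a named error", {
  fx <- fit_fixture()
  sub <- fx$restraints[fx$restraints$residue == fx$restraints$residue[1], ]
  sub <- sub[sub$type == "PCS", ][1:5, ]
  sub <- sub[!is.na(sub$metal), ]
  expect_error(fit_tensor(fx$sc$fixed, fx$sc$metal_position,
                          rbind(sub, sub, sub)[1:6, ], fx$sc$conditions),
               "rank-deficient")
})

test_that("tensor recovery at experimental noise stays within 3 bootstrap sigmas", {
  fx <- fit_fixture()
  sim <- simulate_restraints(fx$sc)
  sub <- sim$fixed[sim$fixed$metal == "Tb", ]
  scales <- estimate_group_scales(fx$sc$fixed, fx$sc$metal_position, sub,
                                  fx$sc$conditions)
  fit <- scales$fit
  sig <- bootstrap_tensor(fx$sc$fixed, fx$sc$metal_position, sub,
                          fx$sc$conditions, n_resamples = 400, seed = 5,
                          weights = scales$weights)
  dev <- abs(fit$chi$components - fx$truth$components)
  expect_true(all(dev <= 3 * sig))
})

test_that("group-scale iteration is scale-equivariant and recovers known noise", {
  fx <- fit_fixture()
  sim <- simulate_restraints(fx$sc)
  sub <- sim$fixed[sim$fixed$metal == "Tb", ]
  est <- estimate_group_scales(fx$sc$fixed, fx$sc$metal_position, sub,
                               fx$sc$conditions)
  # injected noise: 44 ppb PCS, 4.6 Hz RDC (pooled), recovered within 20%
  expect_equal(unname(est$sigma[["PCS"]]), 0.044, tolerance = 0.2)
  expect_equal(unname(est$sigma[["RDC"]]), 4.6, tolerance = 0.2)
  # scaling all data by 10 scales every sigma by exactly 10
  sub10 <- sub
  sub10$value <- sub$value * 10
  est10 <- estimate_group_scales(fx$sc$fixed, fx$sc$metal_position, sub10,
                                 fx$sc$conditions)
  expect_equal(est10$sigma / est$sigma, c(PCS = 10, RDC = 10),
               tolerance = 1e-6)
  # a single group converges in one step to the unweighted residual RMSD
  pcs_only <- sub[sub$type == "PCS", ]
  est1 <- estimate_group_scales(fx$sc$fixed, fx$sc$metal_position, pcs_only,
                                fx$sc$conditions)
  f <- fit_tensor(fx$sc$fixed, fx$sc$metal_position, pcs_only,
                  fx$sc$conditions)
  expect_equal(unname(est1$sigma[["PCS"]]), sqrt(mean(f$residuals^2)),
               tolerance = 1e-6)
  expect_error(estimate_group_scales(fx$sc$fixed, fx$sc$metal_position,
                                     sub[1:12, ], fx$sc$conditions),
               "at least 10")
})

test_that("metal-position refinement recovers a 0.6 A displacement", {
  # position information comes mostly from proximal PCS of a large tensor,
  # so use the strongest lanthanide with a realistic record count
  sc <- make_scenario(n_fixed = 60, n_mobile = 4, pool_size = 5,
                      planted_size = 1, metals = "Dy", seed = 22)
  sim <- simulate_restraints(sc)
  init <- sc$metal_position + c(0.36, -0.36, 0.3464)  # |shift| = 0.6
  res <- optimize_metal_position(sc$fixed, sim$fixed, sc$conditions, init)
  expect_equal(res$displacement, 0.6, tolerance = 0.05 / 0.6)
  expect_lt(res$q_pcs_final, res$q_pcs_init)
  # starting at the true position, the optimizer stays put
  res0 <- optimize_metal_position(sc$fixed, sim$fixed, sc$conditions,
                                  sc$metal_position)
  expect_lt(res0$displacement, 0.05)
})

test_that("bootstrap uncertainties are seeded, vanish without noise, and scale", {
  fx <- fit_fixture()
  s0 <- bootstrap_tensor(fx$sc$fixed, fx$sc$metal_position, fx$restraints,
                         fx$sc$conditions, n_resamples = 150, seed = 2)
  expect_true(all(s0 < 1e-8))
  expect_error(bootstrap_tensor(fx$sc$fixed, fx$sc$metal_position,
                                fx$restraints, fx$sc$conditions,
                                n_resamples = 50), "at least 100")
  sim <- simulate_restraints(fx$sc)
  sub <- sim$fixed[sim$fixed$metal == "Tb", ]
  b1 <- bootstrap_tensor(fx$sc$fixed, fx$sc$metal_position, sub,
                         fx$sc$conditions, n_resamples = 300, seed = 7)
  b1b <- bootstrap_tensor(fx$sc$fixed, fx$sc$metal_position, sub,
                          fx$sc$conditions, n_resamples = 300, seed = 7)
  expect_identical(as.numeric(b1), as.numeric(b1b))
  # doubling the noise roughly doubles every component sigma
  truth <- attr(sim$fixed, "truth")[sim$fixed$metal == "Tb"]
  sub2 <- sub
  sub2$value <- truth + 2 * (sub$value - truth)
  b2 <- bootstrap_tensor(fx$sc$fixed, fx$sc$metal_position, sub2,
                         fx$sc$conditions, n_resamples = 300, seed = 7)
  expect_true(all(abs(b2 / b1 - 2) < 0.5))
})

test_that("component estimator is nearly unbiased at experimental noise", {
  fx <- fit_fixture()
  sys <- assemble_linear_system(fx$sc$fixed, fx$sc$metal_position,
                                fx$restraints, fx$sc$conditions)
  truth <- fx$truth$components
  noiseless <- drop(sys$A %*% truth)
  sig <- ifelse(fx$restraints$type == "PCS", 0.044, 4.6)
  w <- 1 / sig
  set.seed(61)
  est <- replicate(100, {
    b <- noiseless + rnorm(length(noiseless), 0, sig)
    qr.coef(qr(sys$A * w), b * w)
  })
  bias <- rowMeans(est) - truth
  expect_true(all(abs(bias) < 0.05 * pmax(abs(truth), 1)))
})
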