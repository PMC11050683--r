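test_that("variance fractions are normalized and match planted ratios", {
  g <- generate_ensemble(ensemble_spec(n_traces = 15, n_residues = 20,
                                       amplitudes = c(2, 1),
                                       noise_sigma = 0.1,
                                       pose_jitter = FALSE, seed = 21))
  m <- essential_dynamics(g$ensemble)
  expect_equal(sum(m$variance_fractions), 1, tolerance = 1e-10)
  expect_true(all(diff(m$singular_values) <= 1e-12))

  # noise-free rank-2 ensemble with mode variances 9:1 -> fractions (.9, .1)
  # up to the finite-sample coefficient draw: with orthonormal modes the
  # exact spectrum is that of the centered coefficient cross-product
  g2 <- generate_ensemble(ensemble_spec(n_traces = 40, n_residues = 25,
                                        amplitudes = c(3, 1), noise_sigma = 0,
                                        pose_jitter = FALSE, seed = 22))
  m2 <- essential_dynamics(g2$ensemble)
  cc <- scale(g2$truth$coefficients, scale = FALSE)
  planted <- eigen(crossprod(cc), symmetric = TRUE)$values
  planted <- planted / sum(planted)
  expect_equal(m2$variance_fractions[1:2], planted, tolerance = 1e-8)
  expect_equal(planted, c(0.9, 0.1), tolerance = 0.15)  # sampling wiggle
  expect_lt(sum(m2$variance_fractions[-(1:2)]), 1e-8)
})

test_that("fractions and component span agree with a covariance eigendecomposition", {
  for (seed in c(31, 32, 33)) {
    g <- generate_ensemble(ensemble_spec(n_traces = 12, n_residues = 15,
                                         amplitudes = c(2, 1, 0.5),
                                         noise_sigma = 0.2,
                                         pose_jitter = FALSE, seed = seed))
    mat <- g$ensemble$matrix
    m <- essential_dynamics(mat)
    # independent oracle: eigendecomposition of the covariance matrix
    centered <- scale(mat, scale = FALSE)
    ev <- eigen(crossprod(centered), symmetric = TRUE)
    k <- min(nrow(mat) - 1, ncol(mat))
    oracle_fracs <- ev$values[1:k] / sum(pmax(ev$values, 0))
    expect_equal(m$variance_fractions, oracle_fracs, tolerance = 1e-8)
    # principal angles between leading well-separated eigenvectors
    for (i in 1:3) {
      cosang <- abs(sum(m$components[i, ] * ev$vectors[, i]))
      expect_gt(cosang, cos(1e-6))
    }
  }
})

test_that("parameter recovery: fractions and mode directions over 20 seeds", {
  fracs <- matrix(NA_real_, nrow = 20, ncol = 2)
  cosines <- matrix(NA_real_, nrow = 20, ncol = 2)
  for (s in 1:20) {
    spec <- ensemble_spec(n_traces = 200, n_residues = 20,
                          amplitudes = c(3, 1), noise_sigma = 0,
                          pose_jitter = FALSE, seed = 400 + s)
    g <- generate_ensemble(spec)
    m <- essential_dynamics(g$ensemble)
    fracs[s, ] <- m$variance_fractions[1:2]
    for (k in 1:2)
      cosines[s, k] <- abs(sum(m$components[k, ] * spec$modes[k, ]))
  }
  # analytic fractions 9/10 and 1/10; the mean over seeds must sit within
  # 3 standard errors
  for (k in 1:2) {
    se <- sd(fracs[, k]) / sqrt(nrow(fracs))
    expect_lt(abs(mean(fracs[, k]) - c(0.9, 0.1)[k]), 3 * se + 1e-12)
  }
  expect_true(all(cosines > 0.99))
})

test_that("projection and reconstruction invert each other on fitted rows", {
  g <- generate_ensemble(ensemble_spec(n_traces = 10, n_residues = 12,
                                       amplitudes = c(1.5, 0.7),
                                       noise_sigma = 0.2,
                                       pose_jitter = FALSE, seed = 41))
  m <- essential_dynamics(g$ensemble)
  # average trace projects to zero
  expect_equal(drop(predict(m, m$average_trace)),
               setNames(rep(0, length(m$singular_values)),
                        colnames(m$scores)),
               tolerance = 1e-8)
  # average + c * component1 projects to (c, 0, ...)
  probe <- m$average_trace + 2.5 * m$components[1, ]
  p <- drop(predict(m, probe))
  expect_equal(unname(p[1]), 2.5, tolerance = 1e-8)
  expect_lt(max(abs(p[-1])), 1e-8)
  # zero projection reconstructs the average trace
  expect_equal(reconstruct(m, rep(0, 3)), m$average_trace, tolerance = 1e-10)
  # full-rank round trip is the identity on fitted rows
  sc <- predict(m, g$ensemble$matrix)
  back <- reconstruct(m, sc)
  expect_lt(max(abs(back - g$ensemble$matrix)), 1e-6)
})

test_that("top-1 reconstruction of a noise-free rank-1 ensemble is exact", {
  g <- generate_ensemble(ensemble_spec(n_traces = 8, n_residues = 10,
                                       amplitudes = c(2), noise_sigma = 0,
                                       pose_jitter = FALSE, seed = 51))
  m <- essential_dynamics(g$ensemble)
  sc <- predict(m, g$ensemble$matrix, m = 1)
  back <- reconstruct(m, sc)
  expect_lt(max(abs(back - g$ensemble$matrix)), 1e-8)
})

test_that("reconstruction-error curves are nonincreasing and vanish at full rank", {
  g <- generate_ensemble(ensemble_spec(n_traces = 9, n_residues = 14,
                                       amplitudes = c(2, 1, 0.5),
                                       noise_sigma = 0.3,
                                       pose_jitter = FALSE, seed = 61))
  m <- essential_dynamics(g$ensemble)
  full <- length(m$singular_values)
  curves <- reconstruction_error(m, g$ensemble, max_m = full)
  for (id in unique(curves$trace_id)) {
    r <- curves$rmsd[curves$trace_id == id]
    expect_true(all(diff(r) <= 1e-10))
  }
  expect_lt(max(curves$rmsd[curves$m == full]), 1e-8)
})

test_that("cumulative variance is nondecreasing and reaches 100", {
  g <- generate_ensemble(ensemble_spec(n_traces = 7, n_residues = 10,
                                       amplitudes = c(1, 0.5),
                                       noise_sigma = 0.1,
                                       pose_jitter = FALSE, seed = 71))
  m <- essential_dynamics(g$ensemble)
  cv <- vapply(seq_along(m$singular_values),
               function(k) cumulative_variance(m, k), 0)
  expect_true(all(diff(cv) >= -1e-12))
  expect_equal(cv[length(cv)], 100, tolerance = 1e-8)
  expect_error(cumulative_variance(m, 0), "must be in")
})

test_that("pose jitter changes no variance fraction after alignment", {
  base_spec <- ensemble_spec(n_traces = 15, n_residues = 18,
                             amplitudes = c(2, 1), noise_sigma = 0.1,
                             pose_jitter = FALSE, seed = 81)
  jit_spec <- ensemble_spec(n_traces = 15, n_residues = 18,
                            amplitudes = c(2, 1), noise_sigma = 0.1,
                            pose_jitter = TRUE, seed = 81)
  clean <- align_ensemble(generate_ensemble(base_spec)$ensemble, "SYN:1")
  posed <- align_ensemble(generate_ensemble(jit_spec)$ensemble, "SYN:1")
  f1 <- essential_dynamics(clean)$variance_fractions
  f2 <- essential_dynamics(posed)$variance_fractions
  expect_lt(max(abs(f1 - f2)), 1e-6)
})

test_that("displacement profiles are unit-norm and localize planted modes", {
  R <- 100
  mode <- localized_mode(R, c(40, 60), seed = 91)
  spec <- ensemble_spec(n_traces = 30, n_residues = R,
                        modes = matrix(mode, nrow = 1), amplitudes = c(2),
                        noise_sigma = 0.02, pose_jitter = FALSE, seed = 92)
  m <- essential_dynamics(generate_ensemble(spec)$ensemble)
  prof <- displacement_profile(m, 1)
  expect_equal(sum(prof$magnitude^2), 1, tolerance = 1e-8)
  expect_equal(nrow(prof), R)
  top10 <- prof$resno[order(prof$magnitude, decreasing = TRUE)[1:10]]
  expect_true(all(top10 >= 40 & top10 <= 60))
  # a component with all loading on one residue's x maps to a delta profile
  fake <- m
  fake$components[1, ] <- 0
  fake$components[1, 3 * (5 - 1) + 1] <- 1
  p2 <- displacement_profile(fake, 1)
  expect_equal(p2$magnitude, as.numeric(seq_len(R) == 5))
  expect_error(displacement_profile(m, 999), "pc must be")
})

test_that("an all-identical ensemble yields a zero spectrum with a warning", {
  mat <- matrix(rep(rnorm(12), each = 5), nrow = 5)
  expect_warning(m <- essential_dynamics(mat), "identical")
  expect_true(all(m$variance_fractions == 0))
})
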