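test_that("control model stores per-edge values, means and bandwidths", {
  vals <- matrix(rep(c(0.1, 0.5, 0.9), 10), nrow = 3)
  conns <- mk_model(vals)
  m <- suppressWarnings(fit_control_model(conns))  # zero-variance edges
  expect_equal(m$m, c(0.1, 0.5, 0.9))
  expect_true(all(m$h >= 1e-6))
  # order invariance
  m2 <- suppressWarnings(fit_control_model(rev(conns)))
  expect_equal(m$m, m2$m)
  expect_equal(m$h, m2$h)
  # bimodal edge: mean is the arithmetic mean
  vals2 <- rbind(c(rep(0.1, 5), rep(0.9, 5)),
                 matrix(runif(20), nrow = 2))
  m3 <- fit_control_model(mk_model(vals2))
  expect_equal(m3$m[1], 0.5)
  expect_error(fit_control_model(mk_model(vals[, 1:4])), "at least 5")
})

test_that("edge extremeness matches a quadrature oracle and tail limits", {
  set.seed(31)
  vals <- matrix(rnorm(3 * 200, mean = 0.5, sd = 0.1), nrow = 3)
  model <- fit_control_model(mk_model(vals))
  v <- vals[1, ]
  h <- model$h[1]
  # quadrature oracle: integrate the same Gaussian-mixture KDE on a grid
  grid <- seq(min(v) - 6 * h, max(v) + 6 * h, length.out = 40000)
  dens <- rowMeans(sapply(v, function(m0) dnorm(grid, m0, h)))
  cdf_at <- function(c) sum(dens[grid <= c]) * diff(grid[1:2])
  c_star <- mean(v) + 3 * sd(v)
  p_oracle <- 2 * min(cdf_at(c_star), 1 - cdf_at(c_star))
  expect_equal(edge_extremeness(model, 1, c_star), p_oracle,
               tolerance = 0.02)
  # median -> p = 1, far tail -> p -> 0
  med <- uniroot(function(c) mean(pnorm((c - v) / h)) - 0.5,
                 range(v), tol = 1e-12)$root
  expect_equal(edge_extremeness(model, 1, med), 1, tolerance = 1e-6)
  expect_lt(edge_extremeness(model, 1, max(v) + 10), 1e-6)
  expect_error(edge_extremeness(model, "No|Edge", 0.5), "unknown edge")
  # one-sided literal mode returns the CDF itself
  expect_equal(edge_extremeness(model, 1, med, two_sided = FALSE), 0.5,
               tolerance = 1e-6)
})

test_that("residual arithmetic, sign convention and kappa monotonicity", {
  set.seed(32)
  vals <- matrix(rnorm(3 * 200, 0.5, 0.1), nrow = 3)
  model <- fit_control_model(mk_model(vals))
  # find c with two-sided extremeness 0.01 (above the mean) and check
  # |r| = 1 - 0.01^kappa
  c01 <- uniroot(function(c) edge_extremeness(model, 1, c) - 0.01,
                 c(model$m[1], model$m[1] + 1))$root
  r <- residual(model, 1, c01, kappa = 0.25)
  expect_equal(abs(r), 1 - 0.01^0.25, tolerance = 1e-6)
  expect_equal(1 - 0.01^0.25, 0.6838, tolerance = 1e-4)
  expect_lt(r, 0)  # value above the control mean: negative sign
  expect_gt(residual(model, 1, model$m[1] - 0.5, kappa = 0.25), 0)
  expect_lt(abs(residual(model, 1, model$m[1])), 0.05)
  expect_error(residual(model, 1, 0.5, kappa = 0), "kappa")
  expect_error(residual(model, 1, 0.5, kappa = 1.2), "kappa")
  # smaller kappa emphasizes rare values more than typical ones
  r_rare <- function(k) abs(residual(model, 1, c01, kappa = k))
  c50 <- uniroot(function(c) edge_extremeness(model, 1, c) - 0.5,
                 c(model$m[1], model$m[1] + 1))$root
  r_typ <- function(k) abs(residual(model, 1, c50, kappa = k))
  expect_gt(r_rare(0.25) / r_typ(0.25), r_rare(1) / r_typ(1))
  # p^kappa decreases in kappa on (0,1): smaller kappa shrinks |r|
  # globally while (above) emphasizing rare values relatively
  expect_lte(r_rare(0.25), r_rare(1))
  expect_lte(r_typ(0.25), r_typ(1))
})

test_that("residual networks are symmetric, bounded and sum correctly", {
  controls <- lapply(1:12, function(s) rand_connectome(s))
  model <- fit_control_model(controls)
  subj <- rand_connectome(99)
  rn <- residual_network(subj, model, kappa = 0.25)
  expect_true(isSymmetric(rn$r))
  expect_equal(diag(rn$r), rep(0, 13), ignore_attr = TRUE)
  expect_true(all(abs(rn$r) <= 1))
  expect_equal(sum_abs_residuals(rn),
               sum(abs(rn$r[upper.tri(rn$r)])))
  all5 <- rn
  all5$r <- matrix(0.5, 13, 13); diag(all5$r) <- 0
  expect_equal(sum_abs_residuals(all5), 0.5 * 78)
  bad <- rand_connectome(1, nodes = roi_schema()$roi_names[1:5])
  expect_error(residual_network(bad, model), "mismatch")
})

test_that("control split is seeded, disjoint and exhaustive", {
  x <- as.list(1:46)
  sp <- split_controls(x, n_holdout = 10, seed = 4)
  expect_length(sp$fit, 36)
  expect_length(sp$holdout, 10)
  expect_setequal(c(unlist(sp$fit), unlist(sp$holdout)), 1:46)
  expect_identical(sp, split_controls(x, n_holdout = 10, seed = 4))
  expect_error(split_controls(x, n_holdout = 46), "smaller")
})

test_that("welch_compare matches stats::t.test and calibrates type I", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  got <- welch_compare(a, b)
  ref <- t.test(a, b)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
  expect_equal(got$p, ref$p.value)
  same <- welch_compare(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(welch_compare(rep(1, 3), rep(1, 4))$p, 1)
  set.seed(77)
  rej <- mean(replicate(200, {
    welch_compare(rnorm(20), rnorm(20, sd = 2))$p < 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
})

test_that("group residual contrast highlights the manipulated edge", {
  controls <- lapply(1:12, function(s) rand_connectome(s))
  model <- fit_control_model(controls)
  rnA <- lapply(13:18, function(s)
    residual_network(rand_connectome(s), model, kappa = 0.5))
  expect_true(all(group_residual_contrast(rnA, rnA) == 0))
  # inject an effect on one edge only
  shifted <- lapply(19:24, function(s) {
    cn <- rand_connectome(s)
    cn$C[2, 5] <- cn$C[5, 2] <- cn$C[2, 5] + 1.2
    cn
  })
  rnB <- lapply(shifted, residual_network, model = model, kappa = 0.5)
  ctr <- group_residual_contrast(rnB, rnA)
  ut <- which(upper.tri(ctr), arr.ind = TRUE)
  best <- ut[which.max(ctr[ut]), ]
  expect_equal(sort(unname(best)), c(2, 5))
  expect_equal(group_residual_contrast(rev(rnB), rnA), ctr)
})
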