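test_that("ROI schema matches the 13 canonical meta-organs and is total", {
  sch <- roi_schema()
  expect_length(sch$roi_names, 13)
  expect_identical(sch$roi_names[c(1, 13)], c("Axial Skeleton", "Pancreas"))
  expect_true(all(sch$organ_to_roi %in% sch$roi_names))
  expect_false(anyDuplicated(names(sch$organ_to_roi)) > 0)
  # single-organ ROIs of the canonical table
  expect_identical(unname(sch$organ_to_roi[c("liver", "spleen", "brain")]),
                   c("Liver", "Spleen", "Brain"))
  expect_identical(sort(names(sch$organ_to_roi)[sch$organ_to_roi == "Heart Right"]),
                   c("heart_atrium_right", "heart_ventricle_right"))
  expect_identical(expand_labels("Heart Right"),
                   c("heart_atrium_right", "heart_ventricle_right"))
  expect_error(expand_labels("no_such_organ"), "neither")
  expect_error(roi_schema(c(liver = "NotAnROI")), "unknown ROI")
})

test_that("generate_subject is a pure seeded function with labeled voxels", {
  specs <- default_organ_specs()
  s1 <- generate_subject(specs, seed = 7)
  s2 <- generate_subject(specs, seed = 7)
  expect_identical(s1, s2)
  s3 <- generate_subject(specs, seed = 8)
  expect_false(identical(s1$suv, s3$suv))
  expect_true(all(is.finite(s1$suv)) && all(s1$suv >= 0))
  expect_false(anyNA(s1$labels))
  expect_setequal(unique(s1$labels),
                  vapply(specs, `[[`, character(1), "label"))
  # every organ has >= 50 voxels
  expect_true(all(table(s1$labels) >= 50))
})

test_that("degenerate lognormal sigma = 0 yields constant SUV", {
  sp <- organ_spec("liver", c(20, 20, 20), c(24, 24, 24),
                   suv_params = list(meanlog = 0, sdlog = 0))
  s <- generate_subject(list(sp), jitter = c(location = 0, scale = 0),
                        seed = 1)
  expect_equal(s$suv, rep(exp(0), length(s$suv)))
})

test_that("SUV families and spatial gradient behave as specified", {
  mk <- function(...) generate_subject(list(organ_spec(
    "liver", c(20, 20, 20), c(24, 24, 40), ...)),
    jitter = c(location = 0, scale = 0), seed = 3)
  g <- mk(suv_params = list(meanlog = 1, sdlog = 0.2), spatial_gradient = 0.8)
  z <- g$positions[, 3]
  lo <- mean(g$suv[z < quantile(z, 0.3)])
  hi <- mean(g$suv[z > quantile(z, 0.7)])
  expect_gt(hi / lo, 1.2)  # multiplicative drift along the axis
  gam <- mk(suv_family = "gamma", suv_params = list(shape = 4, rate = 2))
  expect_true(all(is.finite(gam$suv)) && all(gam$suv >= 0))
  expect_equal(mean(gam$suv), 2, tolerance = 0.1)
  gm <- mk(suv_family = "gaussian-mixture",
           suv_params = list(weights = c(.7, .3), means = c(0.3, 3),
                             sds = c(0.3, 0.5)))
  expect_true(all(gm$suv >= 0))  # truncated at zero
  expect_gt(mean(gm$suv > 2), 0.1)
})

test_that("overlapping organ boxes error naming the colliding pair", {
  a <- organ_spec("liver", c(0, 0, 0), c(24, 24, 24))
  b <- organ_spec("spleen", c(10, 0, 0), c(24, 24, 24))
  expect_error(generate_subject(list(a, b), seed = 1), "liver.*spleen")
  # touching faces are fine
  b2 <- organ_spec("spleen", c(24, 0, 0), c(24, 24, 24))
  expect_silent(generate_subject(list(a, b2), seed = 1))
})

test_that("boundary voxels of two adjacent boxes match the exhaustive scan", {
  cl <- two_box_cloud(5, 5, 5)
  got <- find_boundary_voxels(cl, k = 10)
  expect_identical(got, boundary_oracle(cl$positions, cl$labels, 10))
  expect_gt(sum(got), 0)
})

test_that("generate_cohort sizes, group labels and null effect", {
  spec <- cohort_spec(46, 22, seed = 3)
  coh <- generate_cohort(spec)
  expect_length(coh$subjects, 68)
  expect_identical(sum(coh$groups == "control"), 46L)
  expect_identical(sum(coh$groups == "patient"), 22L)
  # null effect: a patient subject equals a control draw at the same seed
  specs <- default_organ_specs()
  null_eff <- effect_spec("Heart Right", mean_shift = 1,
                          variance_inflation = 1)
  p <- generate_subject(specs, seed = 11, effect = null_eff)
  c0 <- generate_subject(specs, seed = 11, effect = NULL)
  expect_equal(p$suv, c0$suv)
})

test_that("patient mean shift is recovered by Monte Carlo at n >= 20", {
  spec <- cohort_spec(20, 20, seed = 21,
                      subject_variability = c(location = 0.05, scale = 0.05),
                      effect = effect_spec("Heart Right", mean_shift = 1.5,
                                           variance_inflation = 1))
  coh <- generate_cohort(spec)
  mean_hr <- vapply(coh$subjects, function(s)
    mean(s$suv[s$labels == "heart_ventricle_right"]), numeric(1))
  ratio <- mean(mean_hr[coh$groups == "patient"]) /
    mean(mean_hr[coh$groups == "control"])
  expect_gt(ratio, 1.5 * 0.95)
  expect_lt(ratio, 1.5 * 1.05)
})

test_that("latent coupling induces positional rank correlation, none without", {
  specs <- list(
    organ_spec("liver", c(20, 20, 20), c(56, 56, 64),
               suv_params = list(meanlog = 1, sdlog = 0.3)),
    organ_spec("spleen", c(100, 20, 20), c(56, 56, 64),
               suv_params = list(meanlog = 0.6, sdlog = 0.3))
  )
  paired <- function(cloud) {
    # pair organs by matched axial quantiles, as the MI estimator does
    per_organ <- lapply(c("liver", "spleen"), function(org) {
      oc <- organ_cloud(cloud, org)
      z <- oc$positions[, 3]
      v <- oc$suv[order(z, seq_along(z))]
      v
    })
    do.call(cbind, per_organ)
  }
  eff <- effect_spec(character(0), coupling = list(c("liver", "spleen")),
                     coupling_strength = 0.4)
  rs_c <- vapply(1:4, function(sd0) {
    s <- generate_subject(specs, seed = sd0, effect = eff)
    pv <- paired(s)
    cor(pv[, 1], pv[, 2], method = "spearman")
  }, numeric(1))
  rs_0 <- vapply(1:4, function(sd0) {
    s <- generate_subject(specs, seed = sd0)
    pv <- paired(s)
    cor(pv[, 1], pv[, 2], method = "spearman")
  }, numeric(1))
  expect_gt(length(organ_cloud(generate_subject(specs, seed = 1),
                               "liver")$suv), 3000)
  expect_true(all(rs_c > 0.3))
  expect_true(all(abs(rs_0) < 0.1))
})
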