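test_that("boundary detection: single label, oracle match, k monotonicity", {
  set.seed(41)
  pos <- matrix(runif(300, 0, 40), ncol = 3)
  uni <- labeled_point_cloud(pos, rlnorm(100), rep("liver", 100))
  expect_false(any(find_boundary_voxels(uni, k = 15)))
  cl <- two_box_cloud(4, 4, 4)
  for (k in c(5, 15)) {
    expect_identical(find_boundary_voxels(cl, k),
                     boundary_oracle(cl$positions, cl$labels, k))
  }
  m5 <- find_boundary_voxels(cl, 5)
  m20 <- find_boundary_voxels(cl, 20)
  expect_true(all(m20[m5]))  # growing k never shrinks the mask
  expect_error(find_boundary_voxels(uni, k = 100), "smaller")
})

test_that("perturbation: B = 0 identity, core preservation, swap law", {
  cl <- two_box_cloud(5, 5, 5, seed = 2)
  p0 <- perturb_labels(cl, perturbation_config(blur_ratio = 0, seed = 1))
  expect_identical(p0, cl)
  uni <- labeled_point_cloud(cl$positions, cl$suv, rep("liver", length(cl$suv)))
  expect_identical(perturb_labels(uni, perturbation_config(blur_ratio = 1,
                                                           seed = 1)), uni)
  p1 <- perturb_labels(cl, perturbation_config(blur_ratio = 0.8, seed = 3))
  # positions and SUVs untouched; only boundary labels may change
  expect_identical(p1$positions, cl$positions)
  expect_identical(p1$suv, cl$suv)
  boundary <- find_boundary_voxels(cl, 15)
  changed <- p1$labels != cl$labels
  expect_true(all(changed[!boundary] == FALSE))
  expect_gt(sum(changed), 0)
  # swapped labels come from the foreign neighbourhood (two-label cloud)
  expect_true(all(p1$labels[changed] != cl$labels[changed]))
  # swap law: change fraction among boundary voxels ~ B (binomial error)
  frac <- mean(vapply(1:60, function(s) {
    p <- perturb_labels(cl, perturbation_config(blur_ratio = 0.5, seed = s))
    mean((p$labels != cl$labels)[boundary])
  }, numeric(1)))
  se <- sqrt(0.25 / (sum(boundary) * 60))
  expect_lt(abs(frac - 0.5), 4 * se + 0.01)
})

test_that("subject stability is a rank correlation with tie handling", {
  b <- rand_connectome(51)
  expect_equal(subject_stability(b, b), 1)
  mono <- b
  mono$C <- b$C^3  # strictly increasing transform
  expect_equal(subject_stability(b, mono), 1)
  set.seed(52)
  pert <- rand_connectome(52)
  a <- b$C[upper.tri(b$C)]
  p <- pert$C[upper.tri(pert$C)]
  expect_equal(subject_stability(b, pert), spearman_oracle(a, p))
  # hand-built 4-node example with a tie
  n4 <- c("A", "B", "C", "D")
  mk4 <- function(v) {
    C <- diag(4); C[upper.tri(C)] <- v
    C <- C + t(C) - diag(diag(C)); diag(C) <- 1
    connectome(n4, matrix(0, 4, 4), matrix(0, 4, 4), 0, "roi", "s", C = C)
  }
  v1 <- c(.1, .2, .3, .4, .5, .6)
  v2 <- c(.2, .1, .3, .3, .5, .6)   # swapped pair + tie
  expect_equal(subject_stability(mk4(v1), mk4(v2)),
               cor(v1, v2, method = "spearman"))
  expect_error(subject_stability(b, rand_connectome(1, nodes = c("A", "B"))),
               "node set")
})

test_that("edge stability across subjects and replicates", {
  base <- lapply(1:10, function(s) rand_connectome(60 + s))
  ones <- edge_stability(base, list(base, base))
  expect_true(all(abs(ones - 1) < 1e-12))
  # pure-noise replicates: per-edge mean rho hovers near 0
  noise_reps <- lapply(1:20, function(r)
    lapply(1:10, function(s) rand_connectome(1000 * r + s)))
  es <- edge_stability(base, noise_reps)
  expect_true(all(abs(es[upper.tri(es)]) < 0.25))
  expect_error(edge_stability(base[1:2], list(base[1:2])), "3 subjects")
})

test_that("noise attribution partitions the total variation", {
  nodes <- roi_schema()$roi_names
  M0 <- matrix(0.2, 13, 13, dimnames = list(nodes, nodes))
  expect_equal(unname(noise_attribution(M0, M0, list(Brain = "Brain"))),
               0)
  M1 <- M0
  M1["Brain", ] <- M1[, "Brain"] <- 0.5   # change only Brain-incident edges
  fr <- noise_attribution(M0, M1, list(Brain = "Brain",
                                       Rest = setdiff(nodes, "Brain")))
  expect_equal(unname(fr["Brain"] + fr["Rest"]), 1)
  expect_equal(unname(fr["Brain"]), 0.5)  # half-weight to each endpoint
  # a partition into singletons sums to 1
  singles <- setNames(as.list(nodes), nodes)
  set.seed(3)
  P <- matrix(runif(169), 13, dimnames = list(nodes, nodes))
  P <- (P + t(P)) / 2
  expect_equal(sum(noise_attribution(M0, P, singles)), 1)
})

test_that("rerun_pipeline at B = 0 reproduces baseline connectomes", {
  specs <- list(
    organ_spec("liver", c(20, 20, 20), c(32, 32, 32),
               suv_params = list(meanlog = 1, sdlog = 0.3)),
    organ_spec("spleen", c(52, 20, 20), c(32, 32, 32),
               suv_params = list(meanlog = 0.5, sdlog = 0.3)),
    organ_spec("brain", c(20, 20, 60), c(32, 32, 32),
               suv_params = list(meanlog = 1.8, sdlog = 0.3))
  )
  clouds <- lapply(1:3, function(s) generate_subject(specs, seed = s))
  base <- suppressWarnings(lapply(clouds, function(cl)
    reduce_to_roi(build_connectome(cl, alpha = 1))))
  rr <- suppressWarnings(rerun_pipeline(
    clouds, perturbation_config(blur_ratio = 0), alpha = 1))
  expect_length(rr$errors, 0)
  for (i in 1:3) expect_equal(rr$connectomes[[i]]$C, base[[i]]$C)
  # per-subject failures are isolated
  clouds_bad <- clouds
  clouds_bad[[2]]$labels[] <- "liver"   # single organ: pipeline error
  rr2 <- suppressWarnings(rerun_pipeline(
    clouds_bad, perturbation_config(blur_ratio = 0), alpha = 1))
  expect_length(rr2$errors, 1)
  expect_null(rr2$connectomes[[2]])
  expect_false(is.null(rr2$connectomes[[1]]))
})
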