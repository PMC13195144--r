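sep_graphs <- function(n_subj = 24, seed = 1) {
  # connectomes with a large single-edge class effect
  base <- rand_connectome(1000)$C
  y <- rep(c(0, 1), length.out = n_subj)
  graphs <- lapply(seq_len(n_subj), function(i) {
    cn <- rand_connectome(2000 + i, base = -log(pmax(base, 1e-6)),
                          noise = 0.02)
    if (y[i] == 1) {
      cn$C[3, 9] <- cn$C[9, 3] <- pmin(cn$C[3, 9] + 0.5, 1)
    }
    cn
  })
  list(graphs = graphs, y = y)
}

test_that("dead network outputs exactly 0.5 and zero saliency", {
  cfg <- gcn_config(seed = 1)
  params <- petconn:::gcn_init_params(cfg, 13)
  zero <- lapply(params, function(p) p * 0)
  cn <- rand_connectome(5)
  expect_equal(gcn_forward(cn, zero), 0.5)
  sal <- edge_saliency(list(params = zero), cn)
  expect_true(all(sal$importance == 0))
})

test_that("forward pass matches a hand-unrolled computation on 3 nodes", {
  A <- matrix(c(0, .5, .2, .5, 0, .8, .2, .8, 0), 3)
  cfg <- gcn_config(channels = c(2L, 2L), mlp_units = c(2L, 1L), seed = 1)
  params <- list(W1 = matrix(c(.1, -.2, .3, .05, -.1, .2), 3, 2),
                 b1 = c(.01, -.02),
                 W2 = matrix(c(.2, -.1, .1, .3), 2, 2), b2 = c(0, .05),
                 W3 = matrix(c(.4, .1, -.2, .2), 2, 2), b3 = c(.1, 0),
                 W4 = c(.5, -.3), b4 = .02)
  # independent unrolling
  At <- A + diag(3)
  Ah <- diag(1 / sqrt(rowSums(At))) %*% At %*% diag(1 / sqrt(rowSums(At)))
  Z1 <- tanh(Ah %*% params$W1 + rep(1, 3) %*% t(params$b1))
  Z2 <- tanh(Ah %*% Z1 %*% params$W2 + rep(1, 3) %*% t(params$b2))
  g <- colMeans(Z2)
  H <- tanh(t(params$W3) %*% g + params$b3)
  p_hand <- 1 / (1 + exp(-(sum(params$W4 * H) + params$b4)))
  expect_equal(gcn_forward(A, list(params = params)), p_hand,
               tolerance = 1e-12)
  expect_error(gcn_forward(matrix(c(0, 1, 0, 0), 2), list(params = params)),
               "symmetric")
})

test_that("R backprop matches finite differences", {
  set.seed(4)
  graphs <- lapply(1:5, function(i) {
    M <- matrix(runif(16), 4); M <- (M + t(M)) / 2; diag(M) <- 0; M
  })
  y <- c(0, 1, 0, 1, 1)
  prep <- petconn:::gcn_prepare(graphs)
  cfg <- gcn_config(channels = c(3L, 4L), mlp_units = c(3L, 1L), seed = 2)
  params <- petconn:::gcn_init_params(cfg, 4)
  fw <- petconn:::gcn_forward_internal(prep, params, NULL)
  gr <- petconn:::gcn_gradients(prep, params, fw, y, 0)
  lossfn <- function(pp) {
    f <- petconn:::gcn_forward_internal(prep, pp, NULL)
    -mean(y * log(f$p) + (1 - y) * log(1 - f$p))
  }
  eps <- 1e-6
  for (nm in names(params)) {
    num <- params[[nm]] * 0
    pp <- params
    for (i in seq_along(params[[nm]])) {
      pp[[nm]][i] <- params[[nm]][i] + eps
      up <- lossfn(pp)
      pp[[nm]][i] <- params[[nm]][i] - eps
      dn <- lossfn(pp)
      pp[[nm]][i] <- params[[nm]][i]
      num[i] <- (up - dn) / (2 * eps)
    }
    expect_equal(as.numeric(gr[[nm]]), as.numeric(num), tolerance = 1e-6)
  }
})

test_that("training is seeded-deterministic and fits separable data", {
  sg <- sep_graphs()
  cfg <- gcn_config(epochs = 300L, seed = 11)
  m1 <- train_gcn(sg$graphs, sg$y, cfg)
  m2 <- train_gcn(sg$graphs, sg$y, cfg)
  expect_identical(m1$final_loss, m2$final_loss)
  p <- gcn_predict(m1, sg$graphs)
  expect_gte(mean((p > 0.5) == (sg$y == 1)), 0.95)
  expect_error(train_gcn(sg$graphs[sg$y == 1], sg$y[sg$y == 1], cfg),
               "both classes")
})

test_that("inference and saliency are invariant to node permutation", {
  sg <- sep_graphs(12)
  m <- train_gcn(sg$graphs, sg$y, gcn_config(epochs = 100L, seed = 2))
  cn <- sg$graphs[[1]]
  A <- cn$C
  set.seed(6)
  perm <- sample(13)
  Ap <- A[perm, perm]
  expect_equal(gcn_forward(A, m), gcn_forward(Ap, m), tolerance = 1e-12)
  s1 <- edge_saliency(m, A)
  s2 <- edge_saliency(m, Ap)
  expect_equal(s1$importance, s2$importance, tolerance = 1e-12)
})

test_that("edge saliency equals independent re-evaluation, zero edges get 0", {
  sg <- sep_graphs(12)
  m <- train_gcn(sg$graphs, sg$y, gcn_config(epochs = 100L, seed = 3))
  A <- sg$graphs[[3]]$C
  A[2, 4] <- A[4, 2] <- 0   # absent edge
  nm <- rownames(A)
  sal <- edge_saliency(m, A)
  expect_equal(unname(sal$importance[nm[2], nm[4]]), 0)
  p_full <- gcn_forward(A, m)
  for (pair in list(c(1, 2), c(5, 13), c(6, 7))) {
    A0 <- A
    A0[pair[1], pair[2]] <- A0[pair[2], pair[1]] <- 0
    expect_equal(unname(sal$importance[nm[pair[1]], nm[pair[2]]]),
                 abs(gcn_forward(A0, m) - p_full), tolerance = 1e-12)
  }
})

test_that("saliency aggregation weights by accuracy", {
  M <- matrix(runif(169), 13); M <- (M + t(M)) / 2; diag(M) <- 0
  maps <- list(M, 2 * M)
  expect_equal(aggregate_saliency(maps, c(1, 1))$importance, 1.5 * M)
  expect_equal(aggregate_saliency(maps, c(1, 0))$importance, M)
  expect_equal(aggregate_saliency(maps, c(0.5, 1))$importance,
               (0.5 * M + 2 * M) / 1.5)
  expect_warning(agg <- aggregate_saliency(maps, c(0, 0)), "uniform")
  expect_equal(agg$importance, 1.5 * M)
})

test_that("stratified repeated folds: 27 splits, proportions, partition", {
  y <- c(rep(1, 22), rep(0, 46))
  plan <- cv_plan(seed = 13)
  splits <- make_folds(y, plan)
  expect_length(splits, 27)
  for (sp in splits) {
    expect_setequal(c(sp$train, sp$test), seq_along(y))
    n_pat <- sum(y[sp$test] == 1)
    expect_true(abs(n_pat - 22 / 3) <= 1)
    expect_true(abs(length(sp$test) - 68 / 3) <= 1 + 1)
  }
  # each subject appears in exactly one test fold per repeat
  for (r in 1:9) {
    reps <- Filter(function(sp) sp$repeat_id == r, splits)
    expect_equal(sort(unlist(lapply(reps, `[[`, "test"))), seq_along(y))
  }
  expect_error(make_folds(c(0, 0, 0, 1, 1), cv_plan()), "too small")
})
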