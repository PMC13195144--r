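# Upper-triangle edge feature matrix (subjects x edges) from connectomes.
edge_features <- function(graphs) {
  mats <- lapply(graphs, as_adjacency)   # canonical node order
  n <- nrow(mats[[1]])
  nodes <- rownames(mats[[1]]) %||% as.character(seq_len(n))
  X <- t(vapply(mats, function(M) M[upper.tri(M)],
                numeric(n * (n - 1) / 2)))
  colnames(X) <- edge_index(nodes)$name
  list(X = X, nodes = nodes)
}

#' Regularized logistic-regression baseline
#'
#' Benchmarks the graph classifier with a low-complexity linear model on
#' the standardized upper-triangle edge vector (78 features for 13 ROIs).
#' Modes: `"ridge"`, `"lasso"`, or `"stability_weighted_lasso"`, where each
#' edge's L1 penalty is scaled by `1 / max(rho_l, 0.1)` with `rho_l` the
#' edge's mean stability (Spearman matrix from the robustness module) — so
#' unstable edges are penalized more. Balanced accuracy (mean of per-class
#' recalls) is cross-validated under the same repeated stratified plan as
#' the GCN; an optional label-permutation test yields a p-value for the
#' observed balanced accuracy.
#'
#' @param graphs List of [connectome()] / adjacency matrices.
#' @param labels Binary labels.
#' @param plan A [cv_plan()].
#' @param mode Penalty mode.
#' @param stability Symmetric per-edge stability matrix (required for
#'   `stability_weighted_lasso`).
#' @param n_perm Number of label permutations for the p-value (0 = skip).
#' @param seed Seed for inner fold assignment and permutations.
#' @return An object of class `logistic_result`: `balanced_accuracy`,
#'   `per_split`, `p_value` (or `NA`), `coefficients` (symmetric mean
#'   |coefficient| map), `mode`.
#' @export
logistic_baseline <- function(graphs, labels, plan = cv_plan(),
                              mode = c("ridge", "lasso",
                                       "stability_weighted_lasso"),
                              stability = NULL, n_perm = 0L, seed = 1L) {
  mode <- match.arg(mode)
  ef <- edge_features(graphs)
  X <- ef$X
  y <- as_binary_labels(labels)
  if (mode == "stability_weighted_lasso") {
    if (is.null(stability)) {
      stop("stability matrix required for stability_weighted_lasso")
    }
    rho <- stability[upper.tri(stability)]
    pen <- 1 / pmax(rho, 0.1)
  } else {
    pen <- rep(1, ncol(X))
  }
  alpha <- if (mode == "ridge") 0 else 1
  run_cv <- function(yy, collect_coef = FALSE, seed_offset = 0L) {
    splits <- make_folds(yy, plan)
    bacc <- numeric(length(splits))
    coef_sum <- numeric(ncol(X))
    for (s in seq_along(splits)) {
      sp <- splits[[s]]
      Xtr <- X[sp$train, , drop = FALSE]
      keep <- apply(Xtr, 2, sd) > 0
      if (!all(keep) && collect_coef) {
        warning("constant feature(s) dropped: ",
                paste(colnames(X)[!keep], collapse = ", "))
      }
      mu <- colMeans(Xtr[, keep, drop = FALSE])
      sg <- apply(Xtr[, keep, drop = FALSE], 2, sd)
      Ztr <- scale(Xtr[, keep, drop = FALSE], mu, sg)
      Zte <- scale(X[sp$test, keep, drop = FALSE], mu, sg)
      ytr <- yy[sp$train]
      if (min(table(ytr)) >= 4) {
        foldid <- integer(length(ytr))
        with_seed(child_seed(seed + seed_offset, "glmnet", s), {
          for (cl in unique(ytr)) {   # stratified inner folds
            idx <- sample(which(ytr == cl))
            foldid[idx] <- rep_len(1:3, length(idx))
          }
        })
        # inner folds on ~20 subjects trip glmnet's small-class warnings
        fit <- suppressWarnings(
          glmnet::cv.glmnet(Ztr, ytr, family = "binomial",
                            alpha = alpha, nfolds = 3, foldid = foldid,
                            penalty.factor = pen[keep], standardize = FALSE)
        )
        s_use <- "lambda.min"
      } else {
        # cohort too small for nested selection: fixed mild penalty
        fit <- suppressWarnings(
          glmnet::glmnet(Ztr, ytr, family = "binomial", alpha = alpha,
                         penalty.factor = pen[keep], standardize = FALSE)
        )
        s_use <- 0.05
      }
      p <- as.numeric(predict(fit, Zte, s = s_use, type = "response"))
      pred <- as.integer(p > 0.5)
      yt <- yy[sp$test]
      rec <- vapply(c(0, 1), function(cl) {
        if (!any(yt == cl)) return(NA_real_)
        mean(pred[yt == cl] == cl)
      }, numeric(1))
      bacc[s] <- mean(rec, na.rm = TRUE)
      if (collect_coef) {
        cf <- numeric(ncol(X))
        cf[keep] <- abs(as.numeric(coef(fit, s = s_use))[-1])
        coef_sum <- coef_sum + cf
      }
    }
    list(mean = mean(bacc), per_split = bacc,
         coef = coef_sum / length(splits))
  }
  obs <- run_cv(y, collect_coef = TRUE)
  p_value <- NA_real_
  if (n_perm > 0) {
    perms <- with_seed(seed, replicate(n_perm, sample(y), simplify = FALSE))
    null_acc <- vapply(seq_len(n_perm), function(b)
      run_cv(perms[[b]], seed_offset = b)$mean, numeric(1))
    p_value <- (1 + sum(null_acc >= obs$mean)) / (n_perm + 1)
  }
  nodes <- ef$nodes
  coef_map <- vec_to_sym(obs$coef, nodes, 0)
  structure(list(balanced_accuracy = obs$mean, per_split = obs$per_split,
                 p_value = p_value, coefficients = coef_map, mode = mode),
            class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat("<logistic_result>", x$mode, "| balanced accuracy:",
      sprintf("%.3f", x$balanced_accuracy),
      if (!is.na(x$p_value)) sprintf("| permutation p: %.4f", x$p_value)
      else "", "\n")
  invisible(x)
}
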