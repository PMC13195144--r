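# Edge index helpers: edges are the unordered off-diagonal node pairs,
# stored in strict upper-triangle order.
edge_index <- function(nodes) {
  n <- length(nodes)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(i = ut[, 1], j = ut[, 2],
             name = paste(nodes[ut[, 1]], nodes[ut[, 2]], sep = "|"),
             stringsAsFactors = FALSE)
}

upper_vec <- function(M) M[upper.tri(M)]

vec_to_sym <- function(v, nodes, diag_value = 0) {
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  M[upper.tri(M)] <- v
  M <- M + t(M)
  diag(M) <- diag_value
  M
}

#' Fit the control-cohort edge density model
#'
#' For every off-diagonal edge of the ROI connectome, stores the control
#' values, a Gaussian-kernel density bandwidth (Silverman's rule with a
#' robust spread estimate, floored at 1e-6) and the control mean. This is
#' the normative model against which individual connectomes are scored.
#'
#' @param controls List of at least 5 [connectome()] objects with identical
#'   node sets (the control cohort).
#' @return An object of class `edge_density_model`.
#' @export
fit_control_model <- function(controls) {
  if (length(controls) < 5L) stop("need at least 5 control connectomes")
  nodes <- controls[[1]]$nodes
  for (cn in controls) {
    if (!identical(cn$nodes, nodes)) stop("control connectomes must share the node set")
  }
  ed <- edge_index(nodes)
  vals <- vapply(controls, function(cn) upper_vec(cn$C),
                 numeric(nrow(ed)))           # n_edges x n_controls
  vals <- matrix(vals, nrow = nrow(ed))
  nctl <- length(controls)
  h <- numeric(nrow(ed))
  degenerate <- FALSE
  for (l in seq_len(nrow(ed))) {
    v <- vals[l, ]
    sig <- min(sd(v), diff(quantile(v, c(0.25, 0.75), names = FALSE)) / 1.34)
    bw <- 1.06 * sig * nctl^(-1 / 5)
    if (!is.finite(bw) || bw < 1e-6) {
      bw <- 1e-6
      degenerate <- TRUE
    }
    h[l] <- bw
  }
  if (degenerate) warning("degenerate edge(s): bandwidth floored at 1e-6")
  structure(list(nodes = nodes, edges = ed, values = vals, h = h,
                 m = rowMeans(vals), n_controls = nctl),
            class = "edge_density_model")
}

kde_cdf <- function(model, l, c) {
  mean(pnorm((c - model$values[l, ]) / model$h[l]))
}

resolve_edge <- function(model, edge) {
  if (is.character(edge)) {
    l <- match(edge, model$edges$name)
    if (is.na(l)) {
      rev_name <- paste(rev(strsplit(edge, "|", fixed = TRUE)[[1]]),
                        collapse = "|")
      l <- match(rev_name, model$edges$name)
    }
    if (is.na(l)) stop("unknown edge: ", edge)
    l
  } else {
    l <- as.integer(edge)
    if (l < 1L || l > nrow(model$edges)) stop("unknown edge index: ", edge)
    l
  }
}

#' Extremeness probability of an edge value under the control model
#'
#' The Gaussian-kernel KDE CDF \eqn{\hat F_l(c)} has the closed form
#' `mean(pnorm((c - values)/h))`. By default the two-sided extremeness
#' `p = 2 min(F, 1 - F)` (clipped to `[0, 1]`) is returned: 1 at the KDE
#' median, tending to 0 in both tails. `two_sided = FALSE` gives the
#' literal one-sided CDF.
#'
#' @param model An [fit_control_model()] result.
#' @param edge Edge name (`"ROI_A|ROI_B"`) or index.
#' @param c Subject's edge value.
#' @param two_sided Use the two-sided extremeness (default `TRUE`).
#' @return Probability in `[0, 1]`.
#' @export
edge_extremeness <- function(model, edge, c, two_sided = TRUE) {
  stopifnot(inherits(model, "edge_density_model"))
  l <- resolve_edge(model, edge)
  Fc <- kde_cdf(model, l, c)
  if (!two_sided) return(min(max(Fc, 0), 1))
  min(max(2 * min(Fc, 1 - Fc), 0), 1)
}

#' Signed residual of an edge value
#'
#' `r = sign(m_l - c) * (1 - p^kappa)` with `p` the extremeness probability
#' and `m_l` the control mean: positive when the subject value lies below
#' the control mean, with magnitude growing as the value becomes less
#' likely under the control KDE. The smoothing exponent `kappa` in `(0, 1]`
#' emphasizes rare values (small `p`); `kappa = 1` is the unsmoothed case.
#'
#' @inheritParams edge_extremeness
#' @param kappa Smoothing exponent in `(0, 1]`.
#' @return Signed residual in `[-1, 1]`.
#' @export
residual <- function(model, edge, c, kappa = 1, two_sided = TRUE) {
  if (kappa <= 0 || kappa > 1) stop("kappa must lie in (0, 1]")
  l <- resolve_edge(model, edge)
  p <- edge_extremeness(model, l, c, two_sided = two_sided)
  sign(model$m[l] - c) * (1 - p^kappa)
}

#' Residual network of a subject against the control model
#'
#' Applies [residual()] to every off-diagonal edge of the subject's
#' connectome; symmetric with zero diagonal.
#'
#' @param subject A [connectome()] whose node set equals the model's.
#' @param model An [fit_control_model()] result.
#' @param kappa Smoothing exponent in `(0, 1]`.
#' @param two_sided Extremeness convention (see [edge_extremeness()]).
#' @return An object of class `residual_network` with fields `nodes`, `r`
#'   (signed matrix in `[-1, 1]`), `kappa`, `subject_id`.
#' @export
residual_network <- function(subject, model, kappa = 1, two_sided = TRUE) {
  stopifnot(inherits(subject, "connectome"),
            inherits(model, "edge_density_model"))
  if (!identical(subject$nodes, model$nodes)) {
    stop("ROI mismatch; missing from model: ",
         paste(setdiff(subject$nodes, model$nodes), collapse = ", "),
         "; missing from subject: ",
         paste(setdiff(model$nodes, subject$nodes), collapse = ", "))
  }
  cv <- upper_vec(subject$C)
  rv <- vapply(seq_along(cv), function(l)
    residual(model, l, cv[l], kappa = kappa, two_sided = two_sided),
    numeric(1))
  structure(list(nodes = subject$nodes,
                 r = vec_to_sym(rv, subject$nodes, 0),
                 kappa = kappa, subject_id = subject$subject_id),
            class = "residual_network")
}

#' @export
print.residual_network <- function(x, ...) {
  cat("<residual_network> subject:", x$subject_id, "| kappa:", x$kappa,
      "| sum |r|:", round(sum_abs_residuals(x), 3), "\n")
  invisible(x)
}

#' Sum of absolute residuals
#'
#' Sum of `|r_l|` over the unordered off-diagonal node pairs (each pair
#' counted once): the per-subject scalar divergence from the control group.
#'
#' @param rn A [residual_network()].
#' @return Non-negative scalar.
#' @export
sum_abs_residuals <- function(rn) {
  sum(abs(upper_vec(rn$r)))
}

#' Leave-one-out residual networks for the control cohort
#'
#' Scoring a control subject against a model fitted on a sample that
#' includes it underestimates its extremeness (KDE in-sample optimism),
#' which at small cohort sizes biases control-versus-held-out comparisons.
#' This scores every control against the model fitted on the remaining
#' controls, making control residuals exchangeable with those of held-out
#' subjects.
#'
#' @param controls List of at least 6 [connectome()] (so each leave-one-out
#'   model keeps >= 5 controls).
#' @param kappa Smoothing exponent in `(0, 1]`.
#' @param two_sided Extremeness convention (see [edge_extremeness()]).
#' @return List of [residual_network()] objects, one per control.
#' @export
control_residuals_loo <- function(controls, kappa = 1, two_sided = TRUE) {
  if (length(controls) < 6L) stop("need at least 6 controls for LOO scoring")
  lapply(seq_along(controls), function(k) {
    residual_network(controls[[k]], fit_control_model(controls[-k]),
                     kappa = kappa, two_sided = two_sided)
  })
}

#' Seeded split of the control cohort
#'
#' Splits the controls into a fitting set and a held-out "other controls"
#' set of size `n_holdout` (disjoint, exhaustive, reproducible).
#'
#' @param controls List (e.g. of connectomes) to split.
#' @param n_holdout Held-out size (default 10), must be `< length(controls)`.
#' @param seed Integer seed.
#' @return `list(fit = , holdout = )`.
#' @export
split_controls <- function(controls, n_holdout = 10L, seed = 1L) {
  n <- length(controls)
  if (n_holdout >= n) stop("n_holdout must be smaller than the cohort size")
  idx <- with_seed(seed, sample.int(n, n_holdout))
  list(fit = controls[-idx], holdout = controls[idx])
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and
#' a two-tailed p-value, computed from the closed form. Degenerate case
#' (both variances ~ 0, equal means) returns `t = 0, p = 1` by convention.
#'
#' @param a,b Numeric samples of size at least 2.
#' @return `list(t = , df = , p = )`.
#' @export
welch_compare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  if (se2 <= 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, df = na + nb - 2, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = na + nb - 2, p = 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Squared difference of group-average residual networks
#'
#' `(mean_A - mean_B)^2` elementwise over the residual matrices of two
#' groups; highlights the edges whose extremeness pattern differs most
#' between groups.
#'
#' @param groupA,groupB Lists of [residual_network()] with identical node
#'   sets.
#' @return Symmetric non-negative matrix.
#' @export
group_residual_contrast <- function(groupA, groupB) {
  nodes <- groupA[[1]]$nodes
  for (rn in c(groupA, groupB)) {
    if (!identical(rn$nodes, nodes)) stop("mismatched node sets")
  }
  mA <- Reduce(`+`, lapply(groupA, `[[`, "r")) / length(groupA)
  mB <- Reduce(`+`, lapply(groupB, `[[`, "r")) / length(groupB)
  (mA - mB)^2
}
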