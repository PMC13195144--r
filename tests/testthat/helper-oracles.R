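# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# O(n^2) weighted energy-distance V-statistic (double loop via outer)
energy_oracle <- function(x, y, wx = rep(1, length(x)), wy = rep(1, length(y))) {
  p <- wx / sum(wx)
  q <- wy / sum(wy)
  2 * sum(outer(p, q) * abs(outer(x, y, "-"))) -
    sum(outer(p, p) * abs(outer(x, x, "-"))) -
    sum(outer(q, q) * abs(outer(y, y, "-")))
}

# exhaustive k-NN boundary scan: voxel i is boundary iff one of its k
# nearest neighbours (ties by index) has a different label
boundary_oracle <- function(pos, labels, k) {
  n <- nrow(pos)
  vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(pos) - pos[i, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    any(labels[nb] != labels[i])
  }, logical(1))
}

# textbook Spearman with average-rank ties
spearman_oracle <- function(a, b) {
  ra <- rank(a)
  rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# random symmetric connectome object (for residual / GCN / stability tests
# that do not need the full voxel pipeline)
rand_connectome <- function(seed, nodes = roi_schema()$roi_names,
                            subject_id = paste0("s", seed),
                            base = NULL, noise = 0.05) {
  n <- length(nodes)
  set.seed(seed)
  D <- if (is.null(base)) {
    M <- matrix(runif(n * n, 0.2, 2), n)
    (M + t(M)) / 2
  } else {
    P <- matrix(rnorm(n * n, sd = noise), n)
    pmax(base + (P + t(P)) / 2, 0.01)
  }
  diag(D) <- 0
  MI <- matrix(0, n, n)
  connectome(nodes, D, MI, alpha = 0, level = "roi", subject_id = subject_id)
}

# connectomes whose upper-triangle edge values are given column-wise
mk_model <- function(edge_values, nodes = c("A Node", "B Node", "C Node")) {
  lapply(seq_len(ncol(edge_values)), function(k) {
    C <- diag(length(nodes))
    C[upper.tri(C)] <- edge_values[, k]
    C <- C + t(C) - diag(diag(C))
    diag(C) <- 1
    connectome(nodes, matrix(0, length(nodes), length(nodes)),
               matrix(0, length(nodes), length(nodes)), 0, "roi",
               paste0("c", k), C = C)
  })
}

# small two-box cloud on a lattice (shared face along x)
two_box_cloud <- function(nx = 6, ny = 6, nz = 6, pitch = 4, seed = 1,
                          labels = c("liver", "spleen")) {
  g <- expand.grid(x = seq_len(2 * nx), y = seq_len(ny), z = seq_len(nz))
  pos <- as.matrix(g) * pitch
  lab <- ifelse(g$x <= nx, labels[1], labels[2])
  set.seed(seed)
  labeled_point_cloud(pos, rlnorm(nrow(pos), 0.5, 0.3), lab, "twobox")
}
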