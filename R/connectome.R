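#' Connectome object
#'
#' Symmetric organ- or ROI-level similarity graph of one subject: raw
#' energy-distance matrix `D`, normalized mutual-information matrix `MI`,
#' correction strength `alpha`, and the adjacency
#' `C = exp(-D * (1 - alpha * MI))` with unit diagonal.
#'
#' @param nodes Ordered node names.
#' @param D Symmetric non-negative distance matrix.
#' @param MI Symmetric matrix in `[0, 1]`.
#' @param alpha Correction strength.
#' @param level `"organ"` or `"roi"`.
#' @param subject_id Subject identifier.
#' @param C Optional adjacency; recomputed from `D`, `MI`, `alpha` when
#'   omitted (ROI-level reductions store their averaged `C` explicitly).
#' @return An object of class `connectome`.
#' @export
connectome <- function(nodes, D, MI, alpha, level = c("organ", "roi"),
                       subject_id = "subject", C = NULL) {
  level <- match.arg(level)
  n <- length(nodes)
  stopifnot(is.matrix(D), all(dim(D) == n), is.matrix(MI), all(dim(MI) == n))
  if (!isSymmetric(unname(D)) || !isSymmetric(unname(MI))) {
    stop("D and MI must be symmetric")
  }
  if (is.null(C)) {
    C <- exp(-D * (1 - alpha * MI))
    diag(C) <- 1
  }
  if (!all(is.finite(C))) stop("adjacency contains non-finite entries")
  dimnames(D) <- dimnames(MI) <- dimnames(C) <- list(nodes, nodes)
  structure(list(nodes = nodes, D = D, MI = MI, alpha = alpha, C = C,
                 level = level, subject_id = subject_id),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome>", x$level, "level | subject:", x$subject_id,
      "| nodes:", length(x$nodes), "| alpha:", x$alpha, "\n")
  invisible(x)
}

#' Recompute the adjacency of a connectome at a different alpha
#'
#' Cheap: reuses the stored distance and mutual-information matrices. Only
#' defined for organ-level connectomes (ROI-level adjacencies are averages
#' of organ similarities, so they are re-reduced instead).
#'
#' @param conn An organ-level [connectome()].
#' @param alpha New correction strength.
#' @param allow_alpha_one Accept `alpha = 1` with MI clipped below 1.
#' @return A new `connectome` at the requested alpha.
#' @export
recompute_similarity <- function(conn, alpha, allow_alpha_one = TRUE) {
  MI <- conn$MI
  if (alpha == 1) {
    if (!allow_alpha_one) stop("alpha = 1 requires allow_alpha_one = TRUE")
    MI <- pmin(MI, 1 - 1e-6)
  } else if (alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]")
  }
  connectome(conn$nodes, conn$D, MI, alpha, conn$level, conn$subject_id)
}

#' Build an organ-level connectome from a labeled point cloud
#'
#' The full per-subject pipeline: split voxels by fine organ label, compress
#' each organ ([compress()]), compute the pairwise weighted energy distance
#' between compressed SUV samples, estimate normalized mutual information on
#' axially paired samples ([mutual_information()]), apply the correction
#' `D* = D (1 - alpha MI)` and the exponential similarity `exp(-D*)`.
#'
#' @param cloud A [labeled_point_cloud()] with at least two organs known to
#'   the schema. Organs absent from the schema are dropped with a warning.
#' @param schema [roi_schema()].
#' @param alpha Mutual-information correction strength in `[0, 1)`;
#'   `alpha = 1` allowed when `allow_alpha_one = TRUE` (MI is then clipped
#'   to `1 - 1e-6`).
#' @param target Compression size per organ (default 3500).
#' @param lambda Spatial weight of the compression feature space.
#' @param seed Seed threaded to [compress()] (deterministic anyway).
#' @param allow_alpha_one Accept the `alpha = 1` setting used by
#'   group-average analyses.
#' @param mi_grid,mi_bins Mutual-information estimator settings.
#' @return An organ-level [connectome()].
#' @export
build_connectome <- function(cloud, schema = roi_schema(), alpha = 1,
                             target = 3500L, lambda = 1, seed = NULL,
                             allow_alpha_one = TRUE,
                             mi_grid = 1024L, mi_bins = 16L) {
  stopifnot(inherits(cloud, "labeled_point_cloud"))
  if (alpha < 0 || alpha > 1 || (alpha == 1 && !allow_alpha_one)) {
    stop("alpha must lie in [0, 1); alpha = 1 requires allow_alpha_one = TRUE")
  }
  present <- unique(cloud$labels)
  unknown <- setdiff(present, names(schema$organ_to_roi))
  if (length(unknown)) {
    warning("dropping organs absent from the ROI schema: ",
            paste(unknown, collapse = ", "))
  }
  organs <- intersect(names(schema$organ_to_roi), present)
  if (length(organs) < 2L) stop("need at least 2 schema organs in the cloud")
  dists <- lapply(organs, function(org) {
    cd <- compress(organ_cloud(cloud, org), target = target, lambda = lambda,
                   seed = seed)
    as_organ_distribution(cd$values, cd$weights, cd$positions, org)
  })
  names(dists) <- organs
  n <- length(organs)
  D <- matrix(0, n, n)
  MI <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    D[i, j] <- D[j, i] <- energy_distance(
      dists[[i]]$values, dists[[j]]$values,
      wx = dists[[i]]$weights, wy = dists[[j]]$weights
    )
    MI[i, j] <- MI[j, i] <- mutual_information(dists[[i]], dists[[j]],
                                               n_grid = mi_grid,
                                               bins = mi_bins)
  }
  if (alpha == 1) MI <- pmin(MI, 1 - 1e-6)
  connectome(organs, D, MI, alpha, "organ", cloud$subject_id)
}

#' Reduce an organ-level connectome to the 13-ROI level
#'
#' The edge between two ROIs is the mean similarity over all distinct organ
#' pairs crossing the two ROIs. Within-ROI organ pairs contribute only to
#' the (unit) diagonal; single-organ ROIs keep their organ edges unchanged.
#' Output rows/columns follow the canonical ROI order, restricted to ROIs
#' present in the subject.
#'
#' @param organ_level Organ-level [connectome()].
#' @param schema [roi_schema()].
#' @return A ROI-level [connectome()] (D and MI reduced by the same
#'   averaging, provided for reference).
#' @export
reduce_to_roi <- function(organ_level, schema = roi_schema()) {
  stopifnot(inherits(organ_level, "connectome"), organ_level$level == "organ")
  mapped <- schema$organ_to_roi[organ_level$nodes]
  if (anyNA(mapped)) {
    stop("organ(s) not mapped to any ROI: ",
         paste(organ_level$nodes[is.na(mapped)], collapse = ", "))
  }
  rois <- intersect(schema$roi_names, unique(mapped))
  missing <- setdiff(schema$roi_names, rois)
  if (length(missing)) {
    warning("ROIs with no organs present dropped: ",
            paste(missing, collapse = ", "))
  }
  m <- length(rois)
  reduce_mat <- function(M, fill_diag) {
    out <- matrix(fill_diag, m, m)
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (a == b) next
      ia <- which(mapped == rois[a])
      ib <- which(mapped == rois[b])
      out[a, b] <- mean(M[ia, ib, drop = FALSE])
    }
    out
  }
  C <- reduce_mat(organ_level$C, 1)
  D <- reduce_mat(organ_level$D, 0)
  MI <- reduce_mat(organ_level$MI, 0)
  connectome(rois, D, MI, organ_level$alpha, "roi", organ_level$subject_id,
             C = C)
}

#' Per-node variability across a cohort of connectomes
#'
#' For each node, the sum over its incident edges of the across-subject
#' standard deviation of that edge's weight.
#'
#' @param cohort List of [connectome()] with identical node sets.
#' @return Named numeric vector of per-node variability scores.
#' @export
node_variability <- function(cohort) {
  if (length(cohort) < 2L) stop("need at least 2 connectomes")
  nodes <- cohort[[1]]$nodes
  for (cn in cohort) {
    if (!identical(cn$nodes, nodes)) stop("mismatched node sets across cohort")
  }
  n <- length(nodes)
  arr <- vapply(cohort, function(cn) cn$C, matrix(0, n, n))
  sds <- apply(arr, c(1, 2), sd)
  diag(sds) <- 0
  setNames(rowSums(sds), nodes)
}

#' Mutual-information effect map between two groups
#'
#' For each group, the variation induced by the MI correction on the group
#' average ROI connectome is `Delta_g = mean C(alpha = 0) - mean
#' C(alpha = alpha_high)`. The map is the elementwise squared difference
#' `(Delta_A - Delta_B)^2`, optionally scaled for reporting.
#'
#' @param groupA,groupB Lists of organ-level [connectome()].
#' @param schema [roi_schema()].
#' @param alpha_high High-correction setting (default 1, with MI clipping).
#' @param scale Reporting scale factor (default 1000).
#' @return Symmetric non-negative matrix in canonical ROI order.
#' @export
mi_effect_map <- function(groupA, groupB, schema = roi_schema(),
                          alpha_high = 1, scale = 1000) {
  if (!length(groupA) || !length(groupB)) stop("both groups must be non-empty")
  delta <- function(group) {
    mats0 <- lapply(group, function(cn)
      reduce_to_roi(recompute_similarity(cn, 0), schema)$C)
    mats1 <- lapply(group, function(cn)
      reduce_to_roi(recompute_similarity(cn, alpha_high), schema)$C)
    Reduce(`+`, mats0) / length(mats0) - Reduce(`+`, mats1) / length(mats1)
  }
  dA <- delta(groupA)
  dB <- delta(groupB)
  scale * (dA - dB)^2
}
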