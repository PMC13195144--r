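#' Segmentation-boundary perturbation configuration
#'
#' @param k_neighbors Neighborhood size of the spatial k-nearest-neighbour
#'   search (default 15).
#' @param blur_ratio Blur ratio `B` in `[0, 1]`: probability that a
#'   boundary voxel's label is swapped to a neighboring foreign class.
#' @param seed Seed of the stochastic swaps.
#' @return An object of class `perturbation_config`.
#' @export
perturbation_config <- function(k_neighbors = 15L, blur_ratio = 0.5,
                                seed = 1L) {
  stopifnot(k_neighbors >= 1, blur_ratio >= 0, blur_ratio <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 blur_ratio = blur_ratio, seed = as.integer(seed)),
            class = "perturbation_config")
}

#' Boundary voxel detection
#'
#' A voxel is a boundary voxel iff its spatial k-nearest neighborhood
#' (Euclidean distance, self excluded, ties at the k-th neighbor broken by
#' voxel index) contains at least one voxel of a different anatomical
#' class.
#'
#' @param cloud A [labeled_point_cloud()] with more than `k` voxels.
#' @param k Neighborhood size (default 15).
#' @return Logical mask over voxels.
#' @export
find_boundary_voxels <- function(cloud, k = 15L) {
  n <- length(cloud$suv)
  if (k >= n) stop("k must be smaller than the number of voxels")
  nb <- cpp_knn(cloud$positions, as.integer(k))
  lab <- cloud$labels
  nb_lab <- matrix(lab[nb], nrow = n)
  rowSums(nb_lab != lab) > 0
}

#' Stochastic boundary label swapping
#'
#' Each boundary voxel independently, with probability `blur_ratio`,
#' receives a label drawn uniformly from the foreign labels in its
#' k-neighborhood. All decisions use the ORIGINAL label field (single
#' pass, no cascading), so the output is order-independent. Positions and
#' SUVs are untouched; non-boundary voxels never change.
#'
#' @param cloud A [labeled_point_cloud()].
#' @param config A [perturbation_config()].
#' @return A perturbed [labeled_point_cloud()].
#' @export
perturb_labels <- function(cloud, config = perturbation_config()) {
  n <- length(cloud$suv)
  k <- config$k_neighbors
  if (k >= n) stop("k must be smaller than the number of voxels")
  nb <- cpp_knn(cloud$positions, as.integer(k))
  lab <- cloud$labels
  nb_lab <- matrix(lab[nb], nrow = n)
  foreign <- nb_lab != lab
  boundary <- which(rowSums(foreign) > 0)
  new_lab <- lab
  if (length(boundary) && config$blur_ratio > 0) {
    with_seed(config$seed, {
      swap <- boundary[runif(length(boundary)) < config$blur_ratio]
      for (i in swap) {
        cand <- nb_lab[i, foreign[i, ]]
        new_lab[i] <- cand[sample.int(length(cand), 1L)]
      }
    })
  }
  labeled_point_cloud(cloud$positions, cloud$suv, new_lab, cloud$subject_id)
}

#' Re-run the connectome pipeline on perturbed labels
#'
#' Applies [perturb_labels()] to every subject, then re-executes
#' compression, energy distances, mutual information, similarity and ROI
#' reduction. Per-subject failures are recorded without aborting the
#' cohort.
#'
#' @param clouds List of [labeled_point_cloud()].
#' @param perturbation A [perturbation_config()]; each subject perturbs
#'   with a seed derived from `perturbation$seed` and its index.
#' @param schema,alpha,target,lambda Pipeline settings, as in
#'   [build_connectome()].
#' @param reduce Reduce to ROI level (default `TRUE`).
#' @return `list(connectomes = , errors = )`; failed subjects carry `NULL`
#'   in `connectomes` and a message in `errors`.
#' @export
rerun_pipeline <- function(clouds, perturbation, schema = roi_schema(),
                           alpha = 1, target = 3500L, lambda = 1,
                           reduce = TRUE) {
  out <- vector("list", length(clouds))
  errors <- list()
  for (i in seq_along(clouds)) {
    res <- tryCatch({
      pc <- perturbation
      pc$seed <- as.integer(child_seed(perturbation$seed, "perturb", i) %%
                              2147483647)
      pert <- perturb_labels(clouds[[i]], pc)
      cn <- build_connectome(pert, schema = schema, alpha = alpha,
                             target = target, lambda = lambda)
      if (reduce) reduce_to_roi(cn, schema) else cn
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[clouds[[i]]$subject_id]] <- conditionMessage(res)
      out[i] <- list(NULL)
    } else {
      out[[i]] <- res
    }
  }
  list(connectomes = out, errors = errors)
}

#' Per-subject connectome stability
#'
#' Spearman rank correlation (average-rank ties) between the strict upper
#' triangles of a subject's baseline and perturbed adjacency matrices.
#'
#' @param baseline,perturbed [connectome()] objects with identical node
#'   sets and at least 3 edges.
#' @return Correlation in `[-1, 1]`.
#' @export
subject_stability <- function(baseline, perturbed) {
  if (!identical(baseline$nodes, perturbed$nodes)) {
    stop("connectomes must share the node set")
  }
  a <- upper_vec(baseline$C)
  b <- upper_vec(perturbed$C)
  if (length(a) < 3L) stop("need at least 3 edges")
  cor(a, b, method = "spearman")
}

#' Per-edge stability across subjects
#'
#' For each edge and each perturbed replicate cohort, the Spearman
#' correlation across subjects between baseline and perturbed edge values;
#' the returned matrix is the mean over replicates.
#'
#' @param baseline List of baseline [connectome()] (>= 3 subjects).
#' @param replicates List of perturbed cohorts, each aligned to `baseline`
#'   (same subjects, same order).
#' @return Symmetric matrix of mean per-edge Spearman correlations.
#' @export
edge_stability <- function(baseline, replicates) {
  if (length(baseline) < 3L) stop("need at least 3 subjects")
  nodes <- baseline[[1]]$nodes
  base_mat <- vapply(baseline, function(cn) upper_vec(cn$C),
                     numeric(length(nodes) * (length(nodes) - 1) / 2))
  acc <- 0
  for (rep_cohort in replicates) {
    stopifnot(length(rep_cohort) == length(baseline))
    pert_mat <- vapply(rep_cohort, function(cn) upper_vec(cn$C),
                       numeric(nrow(base_mat)))
    rho <- vapply(seq_len(nrow(base_mat)), function(l)
      cor(base_mat[l, ], pert_mat[l, ], method = "spearman"), numeric(1))
    acc <- acc + rho
  }
  vec_to_sym(acc / length(replicates), nodes, diag_value = 1)
}

#' Attribution of contrast variation to ROI groups
#'
#' Sums the elementwise absolute change between a baseline and a perturbed
#' contrast matrix over the edges incident to each named ROI group
#' (half-weight to each endpoint's group; full weight if both endpoints lie
#' in the same group) and divides by the total change over all edges. Over
#' a disjoint exhaustive partition the fractions sum to 1.
#'
#' @param baseline,perturbed Symmetric contrast matrices of equal shape
#'   with matching dimnames.
#' @param roi_groups Named list of character vectors of ROI names.
#' @return Named numeric vector of fractions (0 when there is no change).
#' @export
noise_attribution <- function(baseline, perturbed, roi_groups) {
  stopifnot(all(dim(baseline) == dim(perturbed)))
  d <- abs(perturbed - baseline)
  nodes <- rownames(baseline) %||% as.character(seq_len(nrow(baseline)))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  total <- sum(d[ut])
  vapply(roi_groups, function(gr) {
    if (total == 0) return(0)
    w <- (nodes[ut[, 1]] %in% gr) * 0.5 + (nodes[ut[, 2]] %in% gr) * 0.5
    sum(d[ut] * w) / total
  }, numeric(1))
}
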