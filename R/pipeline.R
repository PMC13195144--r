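#' Experiment configuration
#'
#' Single declarative description of a full experiment: cohort source,
#' connectome settings, residual and classification settings, perturbation
#' levels, and a master seed from which all stage seeds are derived.
#'
#' @param cohort A [cohort_spec()] (synthetic phantom) or a path to a
#'   cohort `manifest.json`.
#' @param alpha Mutual-information correction strength (default 1).
#' @param target Compression size per organ (default 3500).
#' @param lambda Compression spatial weight (default 1).
#' @param kappa Vector of residual smoothing exponents (default 0.25).
#' @param n_holdout Held-out "other controls" size (default 10).
#' @param plan A [cv_plan()].
#' @param gcn A [gcn_config()].
#' @param blur_ratios Perturbation levels to evaluate (default
#'   `c(0.5, 0.75)`).
#' @param k_neighbors Boundary neighborhood size (default 15).
#' @param replicates Perturbed replicates per level (default 1).
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param run_classification,run_robustness Stage toggles.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort, alpha = 1, target = 3500L, lambda = 1,
                              kappa = 0.25, n_holdout = 10L,
                              plan = cv_plan(), gcn = gcn_config(),
                              blur_ratios = c(0.5, 0.75), k_neighbors = 15L,
                              replicates = 1L, seed = 1L,
                              out_dir = tempfile("petconn_run_"),
                              run_classification = TRUE,
                              run_robustness = TRUE) {
  structure(list(cohort = cohort, alpha = alpha, target = as.integer(target),
                 lambda = lambda, kappa = kappa,
                 n_holdout = as.integer(n_holdout), plan = plan, gcn = gcn,
                 blur_ratios = blur_ratios,
                 k_neighbors = as.integer(k_neighbors),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 out_dir = out_dir,
                 run_classification = run_classification,
                 run_robustness = run_robustness),
            class = "experiment_config")
}

# order-stable FNV-1a hash of the JSON-serialized config (no digest
# dependency); used to stamp artifacts
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a full experiment
#'
#' Orchestrates phantom generation (or manifest loading), per-subject
#' connectome construction, residual-network scoring with the three-group
#' design (patients / fitting controls / held-out "other controls"),
#' GCN cross-validation with accuracy-weighted saliency, the logistic
#' baseline, and the boundary-noise robustness analysis. All artifacts are
#' written under `config$out_dir` and a machine-readable `summary.json`
#' records the headline numbers, the config hash and the master seed.
#' Deterministic: identical config + seed give identical summaries.
#'
#' @param config An [experiment_config()].
#' @return The summary list, invisibly. Stage errors are isolated in
#'   `summary$errors`.
#' @export
run_experiment <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  schema <- roi_schema()
  summary <- list(config_hash = config_hash(config), seed = config$seed,
                  software = as.character(utils::packageVersion("petconn")),
                  errors = list(), notices = list())

  # --- cohort ----------------------------------------------------------
  if (inherits(config$cohort, "cohort_spec")) {
    spec <- config$cohort
    spec$seed <- as.integer(child_seed(config$seed, "phantom") %% 2147483647)
    cohort <- generate_cohort(spec, schema)
  } else {
    cohort <- read_cohort(config$cohort)
  }
  groups <- cohort$groups
  summary$n_controls <- sum(groups == "control")
  summary$n_patients <- sum(groups == "patient")

  subj_dir <- file.path(config$out_dir, "subjects")
  write_cohort(cohort$subjects, groups, subj_dir)

  # --- connectomes ------------------------------------------------------
  conn_dir <- file.path(config$out_dir, "connectomes")
  dir.create(conn_dir, showWarnings = FALSE)
  organ_conns <- vector("list", length(cohort$subjects))
  roi_conns <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    organ_conns[[i]] <- build_connectome(
      cohort$subjects[[i]], schema, alpha = config$alpha,
      target = config$target, lambda = config$lambda
    )
    roi_conns[[i]] <- reduce_to_roi(organ_conns[[i]], schema)
    write_connectome(roi_conns[[i]],
                     file.path(conn_dir, roi_conns[[i]]$subject_id),
                     seed = config$seed)
  }
  summary$node_variability <- as.list(node_variability(roi_conns))

  ctrl_idx <- which(groups == "control")
  pat_idx <- which(groups == "patient")

  # --- residuals (three-group design) ----------------------------------
  if (length(pat_idx) == 0L) {
    summary$notices$residuals <- "no patients: residual stage skipped"
    summary$notices$classification <- "no patients: classification skipped"
  } else if (length(ctrl_idx) > config$n_holdout + 4L) {
    res_dir <- file.path(config$out_dir, "residuals")
    dir.create(res_dir, showWarnings = FALSE)
    sp <- split_controls(ctrl_idx, n_holdout = config$n_holdout,
                         seed = child_seed(config$seed, "split"))
    model <- fit_control_model(roi_conns[sp$fit])
    res_block <- list()
    for (kp in config$kappa) {
      rn_fit <- control_residuals_loo(roi_conns[sp$fit], kappa = kp)
      rn_hold <- lapply(roi_conns[sp$holdout], residual_network,
                        model = model, kappa = kp)
      rn_pat <- lapply(roi_conns[pat_idx], residual_network, model = model,
                       kappa = kp)
      s_fit <- vapply(rn_fit, sum_abs_residuals, numeric(1))
      s_hold <- vapply(rn_hold, sum_abs_residuals, numeric(1))
      s_pat <- vapply(rn_pat, sum_abs_residuals, numeric(1))
      contrast <- group_residual_contrast(rn_pat, rn_fit)
      write_matrix_csv(contrast, file.path(
        res_dir, sprintf("contrast_kappa%.2f.csv", kp)))
      res_block[[sprintf("kappa_%.2f", kp)]] <- list(
        welch_patients_vs_other_controls =
          welch_compare(s_pat, s_hold)$p,
        welch_controls_vs_other_controls =
          welch_compare(s_fit, s_hold)$p,
        mean_sum_abs_residuals = list(patients = mean(s_pat),
                                      controls = mean(s_fit),
                                      other_controls = mean(s_hold)),
        contrast_argmax = edge_name_of_max(contrast)
      )
    }
    summary$residuals <- res_block
    summary$mi_effect_max_edge <- edge_name_of_max(
      mi_effect_map(organ_conns[pat_idx], organ_conns[ctrl_idx], schema))
  } else {
    summary$notices$residuals <-
      "too few controls for the three-group design: residual stage skipped"
  }

  # --- classification ---------------------------------------------------
  if (config$run_classification && length(pat_idx) > 0L) {
    cls <- tryCatch({
      y <- as.integer(groups == "patient")
      plan <- config$plan
      plan$seed <- as.integer(child_seed(config$seed, "cvplan") %% 2147483647)
      gcn_cfg <- config$gcn
      gcn_cfg$seed <- as.integer(child_seed(config$seed, "gcn") %% 2147483647)
      cv <- cross_validate(roi_conns, y, plan, gcn_cfg)
      sal <- aggregate_saliency(cv$saliency, weights = cv$accuracy)
      write_matrix_csv(sal$importance,
                       file.path(config$out_dir, "saliency.csv"))
      log_res <- logistic_baseline(roi_conns, y, plan, mode = "ridge",
                                   seed = child_seed(config$seed, "logistic"))
      list(gcn_accuracy_mean = cv$mean_accuracy,
           gcn_accuracy_sd = cv$sd_accuracy,
           saliency_top_edge = edge_name_of_max(sal$importance),
           logistic_balanced_accuracy = log_res$balanced_accuracy)
    }, error = function(e) e)
    if (inherits(cls, "error")) {
      summary$errors$classification <- conditionMessage(cls)
    } else {
      summary$classification <- cls
    }
  }

  # --- robustness -------------------------------------------------------
  if (config$run_robustness && length(config$blur_ratios)) {
    rob <- tryCatch({
      block <- list()
      for (B in config$blur_ratios) {
        rhos <- c()
        for (r in seq_len(config$replicates)) {
          pc <- perturbation_config(
            k_neighbors = config$k_neighbors, blur_ratio = B,
            seed = as.integer(child_seed(config$seed, "blur",
                                         r * 1000 + round(B * 100)) %%
                                2147483647))
          rr <- rerun_pipeline(cohort$subjects, pc, schema,
                               alpha = config$alpha, target = config$target,
                               lambda = config$lambda)
          ok <- !vapply(rr$connectomes, is.null, logical(1))
          rhos <- c(rhos, mapply(subject_stability, roi_conns[ok],
                                 rr$connectomes[ok]))
        }
        block[[sprintf("B_%.2f", B)]] <- list(mean_spearman = mean(rhos),
                                              sd_spearman = sd(rhos))
      }
      block
    }, error = function(e) e)
    if (inherits(rob, "error")) {
      summary$errors$robustness <- conditionMessage(rob)
    } else {
      summary$robustness <- rob
    }
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(summary)
}

edge_name_of_max <- function(M) {
  ut <- which(upper.tri(M), arr.ind = TRUE)
  best <- ut[which.max(M[ut]), ]
  nodes <- rownames(M) %||% as.character(seq_len(nrow(M)))
  paste(nodes[best[1]], nodes[best[2]], sep = "|")
}
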