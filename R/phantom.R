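#' Organ specification for the synthetic phantom
#'
#' Axis-aligned box of lattice voxels with a per-organ SUV distribution.
#' Boxes live on a common regular voxel lattice so that touching organs
#' share an exact face (needed for boundary-noise experiments).
#'
#' @param label Fine organ label (TotalSegmentator-style name).
#' @param center Numeric length-3 box centre (mm).
#' @param extent Numeric length-3 box edge lengths (mm), each a positive
#'   multiple of `voxel_pitch`.
#' @param voxel_pitch Lattice pitch (mm), default 4.
#' @param suv_family One of `"lognormal"`, `"gamma"`, `"gaussian-mixture"`.
#' @param suv_params Family parameters: lognormal `list(meanlog, sdlog)`;
#'   gamma `list(shape, rate)`; gaussian-mixture
#'   `list(weights, means, sds)`.
#' @param spatial_gradient Linear multiplicative SUV drift along the
#'   cranio-caudal axis: voxel SUV is scaled by
#'   `1 + spatial_gradient * (t - 0.5)` with `t` the normalized z position
#'   in the organ. Default 0 (no drift).
#' @return An object of class `organ_spec`.
#' @export
organ_spec <- function(label, center, extent, voxel_pitch = 4,
                       suv_family = c("lognormal", "gamma", "gaussian-mixture"),
                       suv_params = list(meanlog = 0, sdlog = 0.3),
                       spatial_gradient = 0) {
  suv_family <- match.arg(suv_family)
  center <- as.double(center); extent <- as.double(extent)
  stopifnot(length(center) == 3L, length(extent) == 3L)
  if (any(extent <= 0)) stop("organ '", label, "': extent must be > 0")
  n_vox <- prod(round(extent / voxel_pitch))
  if (n_vox < 50) {
    stop("organ '", label, "': voxel count must be >= 50 (got ", n_vox, ")")
  }
  structure(list(label = as.character(label), center = center,
                 extent = extent, voxel_pitch = voxel_pitch,
                 suv_family = suv_family, suv_params = suv_params,
                 spatial_gradient = spatial_gradient),
            class = "organ_spec")
}

# Box spec from inclusive voxel index ranges on the common lattice.
box_organ <- function(label, xi, yi, zi, pitch = 4, ...) {
  rng <- function(i) c((i[1] + i[2] + 1) / 2 * pitch, (i[2] - i[1] + 1) * pitch)
  x <- rng(xi); y <- rng(yi); z <- rng(zi)
  organ_spec(label, center = c(x[1], y[1], z[1]),
             extent = c(x[2], y[2], z[2]), voxel_pitch = pitch, ...)
}

#' Default phantom body plan
#'
#' A crude whole-body plan of 17 fine organs on a 4 mm lattice covering all
#' 13 ROIs, with lognormal per-organ SUV distributions. The left- and
#' right-heart boxes share the interventricular face so that boundary noise
#' can leak uptake between them. Parameter values are generator defaults,
#' not claims about any clinical dataset.
#'
#' @param pitch Lattice pitch in mm (default 4).
#' @return List of [organ_spec()] objects.
#' @export
default_organ_specs <- function(pitch = 4) {
  ln <- function(m, s) list(meanlog = log(m), sdlog = s)
  list(
    box_organ("brain",                 c(3, 12), c(0, 9),   c(50, 59), pitch,
              suv_params = ln(6.0, 0.30)),
    box_organ("lung_upper_lobe_left",  c(0, 5),  c(0, 9),   c(30, 41), pitch,
              suv_params = ln(0.60, 0.35)),
    box_organ("lung_lower_lobe_right", c(10, 15), c(0, 9),  c(30, 41), pitch,
              suv_params = ln(0.60, 0.35)),
    box_organ("heart_atrium_left",     c(6, 8),  c(0, 4),   c(36, 41), pitch,
              suv_params = ln(2.2, 0.35)),
    box_organ("heart_ventricle_left",  c(6, 8),  c(0, 4),   c(30, 35), pitch,
              suv_params = ln(3.2, 0.40)),
    box_organ("heart_atrium_right",    c(6, 8),  c(5, 9),   c(36, 41), pitch,
              suv_params = ln(1.0, 0.30)),
    box_organ("heart_ventricle_right", c(6, 8),  c(5, 9),   c(30, 35), pitch,
              suv_params = ln(1.1, 0.30)),
    box_organ("ribs",                  c(0, 15), c(10, 11), c(30, 41), pitch,
              suv_params = ln(0.85, 0.30)),
    box_organ("liver",                 c(8, 15), c(0, 9),   c(20, 29), pitch,
              suv_params = ln(2.4, 0.25)),
    box_organ("spleen",                c(0, 4),  c(0, 6),   c(22, 27), pitch,
              suv_params = ln(1.9, 0.25)),
    box_organ("pancreas",              c(0, 6),  c(7, 9),   c(24, 27), pitch,
              suv_params = ln(1.6, 0.25)),
    box_organ("torso_fat",             c(0, 15), c(10, 12), c(20, 29), pitch,
              suv_params = ln(0.45, 0.30)),
    box_organ("subcutaneous_fat",      c(0, 15), c(13, 14), c(20, 29), pitch,
              suv_params = ln(0.35, 0.30)),
    box_organ("kidney_left",           c(1, 4),  c(2, 7),   c(14, 19), pitch,
              suv_params = ln(2.8, 0.30)),
    box_organ("kidney_right",          c(10, 13), c(2, 7),  c(14, 19), pitch,
              suv_params = ln(2.8, 0.30)),
    box_organ("skeletal_muscle",       c(0, 15), c(0, 9),   c(8, 13), pitch,
              suv_params = ln(0.90, 0.25)),
    box_organ("femur_left",            c(3, 6),  c(2, 7),   c(0, 7), pitch,
              suv_params = ln(0.70, 0.30))
  )
}

#' Disease effect specification
#'
#' Distributional shift applied to the designated organs of patient
#' subjects, plus optional latent coupling between organ pairs (induces
#' within-subject mutual information without changing marginals much).
#'
#' @param target_labels Fine organ labels and/or ROI names (expanded via the
#'   schema) whose SUV distributions are shifted.
#' @param mean_shift Multiplicative factor (> 0) on the location parameter.
#' @param variance_inflation Multiplicative factor (> 0) on the scale
#'   parameter.
#' @param coupling Optional list of length-2 character vectors of organ
#'   labels whose SUV fields share a latent smooth axial factor.
#' @param coupling_strength Standard deviation of the shared latent
#'   log-SUV field.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(target_labels = character(0), mean_shift = 1,
                        variance_inflation = 1, coupling = NULL,
                        coupling_strength = 0.4) {
  if (mean_shift <= 0 || variance_inflation <= 0) {
    stop("mean_shift and variance_inflation must be > 0")
  }
  structure(list(target_labels = as.character(target_labels),
                 mean_shift = mean_shift,
                 variance_inflation = variance_inflation,
                 coupling = coupling,
                 coupling_strength = coupling_strength),
            class = "effect_spec")
}

#' Cohort specification
#'
#' @param n_controls,n_patients Non-negative cohort sizes.
#' @param subject_variability Named vector `c(location=, scale=)`: standard
#'   deviations of the per-subject multiplicative lognormal jitter on each
#'   organ's location and scale parameters.
#' @param effect An [effect_spec()] applied to patients only.
#' @param seed Master seed for the cohort.
#' @param organ_specs List of [organ_spec()]; identical layout for all
#'   subjects.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls, n_patients,
                        subject_variability = c(location = 0.15, scale = 0.10),
                        effect = effect_spec("Heart Right", mean_shift = 1.5,
                                             variance_inflation = 1.5),
                        seed = 1L,
                        organ_specs = default_organ_specs()) {
  stopifnot(n_controls >= 0, n_patients >= 0)
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 subject_variability = subject_variability,
                 effect = effect, seed = as.integer(seed),
                 organ_specs = organ_specs),
            class = "cohort_spec")
}

# strict box overlap on all three axes (touching faces allowed)
check_no_overlap <- function(specs) {
  eps <- 1e-9
  n <- length(specs)
  if (n < 2) return(invisible(TRUE))
  lo <- t(vapply(specs, function(s) s$center - s$extent / 2, numeric(3)))
  hi <- t(vapply(specs, function(s) s$center + s$extent / 2, numeric(3)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (all(lo[i, ] < hi[j, ] - eps & lo[j, ] < hi[i, ] - eps)) {
      stop("organ boxes overlap: '", specs[[i]]$label, "' and '",
           specs[[j]]$label, "' (labels must partition space)")
    }
  }
  invisible(TRUE)
}

organ_voxel_centers <- function(spec) {
  ax <- lapply(1:3, function(d) {
    lo <- spec$center[d] - spec$extent[d] / 2
    n <- round(spec$extent[d] / spec$voxel_pitch)
    lo + (seq_len(n) - 0.5) * spec$voxel_pitch
  })
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

# draw n SUVs for one organ given jittered/shifted parameters; `lat` is an
# optional latent log-scale field (length n) from coupling.
draw_suv <- function(spec, n, t_axis, jit_loc, jit_scale,
                     mean_shift, var_inflation, lat) {
  p <- spec$suv_params
  suv <- switch(
    spec$suv_family,
    lognormal = {
      ml <- p$meanlog + log(mean_shift) + jit_loc
      sl <- p$sdlog * var_inflation * exp(jit_scale)
      exp(ml + sl * rnorm(n))
    },
    gamma = {
      shape <- p$shape / var_inflation^2
      rate <- p$rate / (mean_shift * exp(jit_loc) * var_inflation^2)
      rgamma(n, shape = shape, rate = rate)
    },
    `gaussian-mixture` = {
      comp <- sample.int(length(p$weights), n, replace = TRUE, prob = p$weights)
      mu <- p$means[comp] * mean_shift * exp(jit_loc)
      s <- p$sds[comp] * var_inflation * exp(jit_scale)
      pmax(rnorm(n, mu, s), 0)
    }
  )
  if (!is.null(lat)) suv <- suv * exp(lat)
  if (spec$spatial_gradient != 0) {
    suv <- suv * pmax(1 + spec$spatial_gradient * (t_axis - 0.5), 0)
  }
  suv
}

# shared smooth latent field over normalized axial position: K random
# Fourier modes with total variance strength^2
latent_field_coefs <- function(strength, K = 4L) {
  matrix(rnorm(2 * K, sd = strength / sqrt(K)), nrow = 2)
}

eval_latent_field <- function(coefs, t) {
  K <- ncol(coefs)
  out <- numeric(length(t))
  for (h in seq_len(K)) {
    out <- out + coefs[1, h] * cos(2 * pi * h * t) +
      coefs[2, h] * sin(2 * pi * h * t)
  }
  out
}

#' Generate one synthetic subject
#'
#' Pure function of `(specs, jitter, effect, seed)`: organ boxes are
#' rasterized on the lattice and each voxel receives an SUV drawn from the
#' organ's (jittered, possibly disease-shifted) distribution.
#'
#' @param specs List of [organ_spec()] (non-overlapping boxes).
#' @param jitter Named vector `c(location=, scale=)` of per-subject jitter
#'   standard deviations (multiplicative lognormal on the organ parameters).
#' @param seed Integer seed.
#' @param effect Optional [effect_spec()]; `NULL` for control subjects.
#' @param subject_id Subject identifier.
#' @param schema [roi_schema()] used to expand ROI names in
#'   `effect$target_labels`.
#' @return A [labeled_point_cloud()].
#' @export
generate_subject <- function(specs, jitter = c(location = 0.15, scale = 0.10),
                             seed = 1L, effect = NULL,
                             subject_id = "subject", schema = roi_schema()) {
  check_no_overlap(specs)
  targets <- if (!is.null(effect) && length(effect$target_labels)) {
    expand_labels(effect$target_labels, schema)
  } else character(0)
  labels_all <- vapply(specs, `[[`, character(1), "label")
  with_seed(seed, {
    # latent coupling fields drawn first so organ draws stay aligned
    coupled <- list()
    if (!is.null(effect) && length(effect$coupling)) {
      for (pair in effect$coupling) {
        coefs <- latent_field_coefs(effect$coupling_strength)
        for (lb in pair) coupled[[lb]] <- coefs
      }
    }
    pos_list <- vector("list", length(specs))
    suv_list <- vector("list", length(specs))
    lab_list <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      pos <- organ_voxel_centers(sp)
      n <- nrow(pos)
      zr <- range(pos[, 3])
      t_axis <- if (zr[2] > zr[1]) (pos[, 3] - zr[1]) / (zr[2] - zr[1]) else
        rep(0.5, n)
      jl <- rnorm(1, 0, jitter[["location"]])
      js <- rnorm(1, 0, jitter[["scale"]])
      ms <- if (sp$label %in% targets) effect$mean_shift else 1
      vi <- if (sp$label %in% targets) effect$variance_inflation else 1
      lat <- if (!is.null(coupled[[sp$label]])) {
        eval_latent_field(coupled[[sp$label]], t_axis)
      } else NULL
      suv_list[[i]] <- draw_suv(sp, n, t_axis, jl, js, ms, vi, lat)
      pos_list[[i]] <- pos
      lab_list[[i]] <- rep(sp$label, n)
    }
    labeled_point_cloud(do.call(rbind, pos_list), unlist(suv_list),
                        unlist(lab_list), subject_id)
  })
}

#' Generate a synthetic cohort
#'
#' Controls and patients share the organ layout and jitter model; patients
#' additionally receive the cohort's [effect_spec()]. Subject seeds are
#' derived deterministically from the cohort seed.
#'
#' @param spec A [cohort_spec()].
#' @param schema [roi_schema()] for effect-target expansion.
#' @return `list(subjects=, groups=)` where `groups` is a character vector
#'   with values `"control"` / `"patient"`.
#' @export
generate_cohort <- function(spec, schema = roi_schema()) {
  n <- spec$n_controls + spec$n_patients
  subjects <- vector("list", n)
  groups <- c(rep("control", spec$n_controls), rep("patient", spec$n_patients))
  for (i in seq_len(n)) {
    id <- sprintf("%s_%02d", ifelse(groups[i] == "control", "ctrl", "pat"), i)
    subjects[[i]] <- generate_subject(
      spec$organ_specs, jitter = spec$subject_variability,
      seed = child_seed(spec$seed, "subject", i),
      effect = if (groups[i] == "patient") spec$effect else NULL,
      subject_id = id, schema = schema
    )
  }
  list(subjects = subjects, groups = groups)
}
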