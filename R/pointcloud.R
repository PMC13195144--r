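#' Labeled voxel point cloud
#'
#' One subject's PET voxels: world-space positions (mm), voxel-wise SUV
#' values and fine anatomical labels.
#'
#' @param positions Numeric N x 3 matrix of voxel centre coordinates (mm).
#' @param suv Numeric vector of length N, finite and non-negative.
#' @param labels Character vector of length N of fine organ labels.
#' @param subject_id Subject identifier string.
#' @return An object of class `labeled_point_cloud`.
#' @export
labeled_point_cloud <- function(positions, suv, labels, subject_id = "subject") {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  suv <- as.double(suv)
  labels <- as.character(labels)
  n <- nrow(positions)
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  if (length(suv) != n || length(labels) != n) {
    stop("positions, suv and labels must have matching length")
  }
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (!all(is.finite(suv)) || any(suv < 0)) {
    stop("SUV values must be finite and >= 0")
  }
  if (anyNA(labels)) stop("labels must not contain NA (labels partition the voxels)")
  structure(
    list(positions = positions, suv = suv, labels = labels,
         subject_id = as.character(subject_id)),
    class = "labeled_point_cloud"
  )
}

#' @export
print.labeled_point_cloud <- function(x, ...) {
  cat("<labeled_point_cloud> subject:", x$subject_id,
      "| voxels:", length(x$suv),
      "| organs:", length(unique(x$labels)), "\n")
  invisible(x)
}

#' Subset a point cloud to a single organ
#' @param cloud A [labeled_point_cloud()].
#' @param organ Fine organ label to keep.
#' @return A `labeled_point_cloud` containing only that organ's voxels.
#' @export
organ_cloud <- function(cloud, organ) {
  keep <- cloud$labels == organ
  if (!any(keep)) stop("organ '", organ, "' not present in cloud")
  labeled_point_cloud(cloud$positions[keep, , drop = FALSE],
                      cloud$suv[keep], cloud$labels[keep], cloud$subject_id)
}

#' Write / read a point cloud as CSV
#'
#' Tabular dialect: columns `x,y,z,suv,label`; a `# units:` comment line
#' records that coordinates are world-space millimetres.
#'
#' @param cloud A [labeled_point_cloud()].
#' @param path Output file path.
#' @return `write_point_cloud()` returns `path` invisibly;
#'   `read_point_cloud()` returns a `labeled_point_cloud`.
#' @export
write_point_cloud <- function(cloud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: mm (x,y,z), SUV (suv); subject: %s",
                     cloud$subject_id), con)
  df <- data.frame(x = cloud$positions[, 1], y = cloud$positions[, 2],
                   z = cloud$positions[, 3], suv = cloud$suv,
                   label = cloud$labels)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_point_cloud
#' @param subject_id Subject id for the read cloud; defaults to the id in
#'   the units header when present.
#' @export
read_point_cloud <- function(path, subject_id = NULL) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    if (is.null(subject_id) && grepl("subject: ", first)) {
      subject_id <- sub(".*subject: ", "", first)
    }
  }
  df <- read.csv(path, skip = skip, stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "suv", "label")
  if (!all(need %in% names(df))) {
    stop("point-cloud file must have columns x,y,z,suv,label")
  }
  labeled_point_cloud(as.matrix(df[, c("x", "y", "z")]), df$suv, df$label,
                      subject_id %||% "subject")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort of point clouds with a JSON manifest
#'
#' One CSV file per subject plus `manifest.json` mapping subject id to file
#' and group label.
#'
#' @param subjects List of [labeled_point_cloud()].
#' @param groups Character/factor vector of group labels, one per subject.
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns `list(subjects=, groups=)`.
#' @export
write_cohort <- function(subjects, groups, dir) {
  stopifnot(length(subjects) == length(groups))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- list()
  for (i in seq_along(subjects)) {
    id <- subjects[[i]]$subject_id
    f <- file.path(dir, paste0(id, ".csv"))
    write_point_cloud(subjects[[i]], f)
    entries[[id]] <- list(file = basename(f), group = as.character(groups[i]))
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' @rdname write_cohort
#' @param manifest Path to a cohort `manifest.json`.
#' @export
read_cohort <- function(manifest) {
  entries <- jsonlite::read_json(manifest)
  dir <- dirname(manifest)
  subjects <- vector("list", length(entries))
  groups <- character(length(entries))
  for (i in seq_along(entries)) {
    id <- names(entries)[i]
    subjects[[i]] <- read_point_cloud(file.path(dir, entries[[i]]$file),
                                      subject_id = id)
    groups[i] <- entries[[i]]$group
  }
  list(subjects = subjects, groups = groups)
}
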