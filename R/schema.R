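#' Canonical 13-ROI schema for whole-body PET connectomics
#'
#' The pipeline reduces fine-grained segmentation labels (TotalSegmentator
#' style) to 13 meta-organ regions of interest (ROIs). `roi_schema()` returns
#' the canonical schema: the ordered ROI names and a total map from fine
#' organ label to ROI.
#'
#' @param organ_to_roi Optional named character vector mapping fine organ
#'   labels to ROI names; defaults to the canonical whole-body map. Every
#'   value must be one of the 13 canonical ROI names.
#' @return An object of class `roi_schema`: a list with `roi_names` (ordered
#'   character vector of length 13) and `organ_to_roi` (named character).
#' @examples
#' sch <- roi_schema()
#' sch$roi_names
#' sch$organ_to_roi[["heart_ventricle_right"]]
#' @export
roi_schema <- function(organ_to_roi = NULL) {
  roi_names <- c(
    "Axial Skeleton", "Appendicular Skeleton", "Skeletal Muscles", "Lung",
    "VAT Fat", "SAT Fat", "Liver", "Spleen", "Kidney", "Heart Left",
    "Heart Right", "Brain", "Pancreas"
  )
  if (is.null(organ_to_roi)) organ_to_roi <- default_organ_map()
  stopifnot(is.character(organ_to_roi), !is.null(names(organ_to_roi)))
  if (anyDuplicated(names(organ_to_roi))) {
    stop("each fine organ label must map to exactly one ROI")
  }
  bad <- setdiff(unique(organ_to_roi), roi_names)
  if (length(bad)) {
    stop("unknown ROI name(s) in mapping: ", paste(bad, collapse = ", "))
  }
  structure(list(roi_names = roi_names, organ_to_roi = organ_to_roi),
            class = "roi_schema")
}

# Fine organ label -> meta-organ, full whole-body vocabulary.
default_organ_map <- function() {
  c(
    costal_cartilages = "Axial Skeleton", ribs = "Axial Skeleton",
    sacrum = "Axial Skeleton", skull = "Axial Skeleton",
    sternum = "Axial Skeleton", vertebrae_c = "Axial Skeleton",
    vertebrae_ls = "Axial Skeleton", vertebrae_t = "Axial Skeleton",
    femur_left = "Appendicular Skeleton", femur_right = "Appendicular Skeleton",
    hip_left = "Appendicular Skeleton", hip_right = "Appendicular Skeleton",
    humerus_left = "Appendicular Skeleton",
    humerus_right = "Appendicular Skeleton",
    shoulder_girdle = "Appendicular Skeleton",
    autochthon_left = "Skeletal Muscles", autochthon_right = "Skeletal Muscles",
    gluteus_left = "Skeletal Muscles", gluteus_right = "Skeletal Muscles",
    iliopsoas_left = "Skeletal Muscles", iliopsoas_right = "Skeletal Muscles",
    skeletal_muscle = "Skeletal Muscles",
    lung_lower_lobe_left = "Lung", lung_lower_lobe_right = "Lung",
    lung_middle_lobe_right = "Lung", lung_upper_lobe_left = "Lung",
    lung_upper_lobe_right = "Lung",
    torso_fat = "VAT Fat",
    subcutaneous_fat = "SAT Fat",
    liver = "Liver",
    spleen = "Spleen",
    kidney_left = "Kidney", kidney_right = "Kidney",
    heart_atrium_left = "Heart Left", heart_ventricle_left = "Heart Left",
    heart_myocardium = "Heart Left",
    heart_atrium_right = "Heart Right", heart_ventricle_right = "Heart Right",
    brain = "Brain",
    pancreas = "Pancreas"
  )
}

#' Expand organ or ROI names to fine organ labels
#'
#' Convenience used by effect specifications: entries that name an ROI are
#' expanded to all fine labels of that ROI, entries that name a fine label
#' pass through.
#'
#' @param labels Character vector of fine labels and/or ROI names.
#' @param schema An [roi_schema()].
#' @return Character vector of fine organ labels.
#' @export
expand_labels <- function(labels, schema = roi_schema()) {
  out <- character(0)
  for (lb in labels) {
    if (lb %in% names(schema$organ_to_roi)) {
      out <- c(out, lb)
    } else if (lb %in% schema$roi_names) {
      out <- c(out, names(schema$organ_to_roi)[schema$organ_to_roi == lb])
    } else {
      stop("label '", lb, "' is neither a fine organ label nor a ROI name")
    }
  }
  unique(out)
}
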