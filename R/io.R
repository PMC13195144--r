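#' Write / read a connectome as JSON metadata plus CSV matrices
#'
#' Produces `<stem>.json` (subject, alpha, node order, level, software
#' version, optional seed) and `<stem>.C.csv`, `<stem>.D.csv`,
#' `<stem>.MI.csv` with rows/columns in the stored node order.
#'
#' @param conn A [connectome()].
#' @param stem Output path stem (no extension).
#' @param seed Optional seed to record.
#' @return The JSON path, invisibly.
#' @export
write_connectome <- function(conn, stem, seed = NULL) {
  meta <- list(subject_id = conn$subject_id, alpha = conn$alpha,
               level = conn$level, nodes = conn$nodes,
               seed = seed,
               software = paste0("petconn ",
                                 as.character(utils::packageVersion("petconn"))))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  for (nm in c("C", "D", "MI")) {
    write.csv(as.data.frame(conn[[nm]]), paste0(stem, ".", nm, ".csv"))
  }
  invisible(paste0(stem, ".json"))
}

#' @rdname write_connectome
#' @export
read_connectome <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  get_mat <- function(nm) {
    df <- read.csv(paste0(stem, ".", nm, ".csv"), row.names = 1,
                   check.names = FALSE)
    as.matrix(df)
  }
  nodes <- unlist(meta$nodes)
  C <- get_mat("C"); D <- get_mat("D"); MI <- get_mat("MI")
  dimnames(C) <- dimnames(D) <- dimnames(MI) <- list(nodes, nodes)
  # symmetrize away CSV round-trip noise
  D <- (D + t(D)) / 2
  MI <- (MI + t(MI)) / 2
  connectome(nodes, D, MI, meta$alpha, meta$level, meta$subject_id, C = C)
}

#' Write a symmetric matrix as CSV
#' @param M Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(M, path) {
  write.csv(as.data.frame(M), path)
  invisible(path)
}
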