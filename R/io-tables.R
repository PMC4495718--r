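## Fiber coordinate tables (TSV), connector graphs (JSON) and analysis
## reports (JSON + TSV summaries). All lengths in nm; schema violations
## raise errors naming the offending column/row and never yield partially
## loaded objects.

FIBER_TABLE_COLUMNS <- c("mt_id", "mid_x_nm", "mid_y_nm",
                         "bot_x_nm", "bot_y_nm", "bot_z_nm",
                         "top_x_nm", "top_y_nm", "top_z_nm")

SLAB_PLAUSIBLE_NM <- c(28.8, 66.4)  # observed tomogram slab range

#' Write a fiber model as a TSV coordinate table
#'
#' Columns: mt_id, midpoint x/y, bottom xyz, top xyz (all nm). Fiber-level
#' metadata (fiber_id, slab thickness, condition) is carried in `#`-prefixed
#' header comments.
#'
#' @param fiber A `fiber_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fiber_table <- function(fiber, path) {
  stopifnot(inherits(fiber, "fiber_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fiber_id=%s", fiber$fiber_id), con)
  writeLines(sprintf("# slab_thickness_nm=%.9g", fiber$slab_thickness_nm), con)
  writeLines(sprintf("# condition=%s", fiber$condition_label), con)
  if (!is.null(fiber$voxel_nm)) {
    writeLines(sprintf("# voxel_nm=%.9g", fiber$voxel_nm), con)
  }
  tab <- as.data.frame(fiber$mts[, FIBER_TABLE_COLUMNS])
  for (j in 2:ncol(tab)) tab[[j]] <- sprintf("%.9f", tab[[j]])
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fiber coordinate table
#'
#' Validates the schema (all nine columns present, numeric coordinates,
#' unique MT ids, top above bottom) and warns when the slab thickness lies
#' outside the plausible tomogram range (28.8-66.4 nm).
#'
#' @param path TSV path written by [write_fiber_table()] (or hand-built to
#'   the same schema).
#' @return A `fiber_model`.
#' @export
read_fiber_table <- function(path) {
  if (!file.exists(path)) stop_kf("no such file: %s", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  tab <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                           sep = "\t", stringsAsFactors = FALSE)
  missing_cols <- setdiff(FIBER_TABLE_COLUMNS, names(tab))
  if (length(missing_cols) > 0) {
    stop_kf("fiber table %s missing column(s): %s", path,
            paste(missing_cols, collapse = ", "))
  }
  for (cl in setdiff(FIBER_TABLE_COLUMNS, "mt_id")) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    bad <- which(is.na(v) & !is.na(tab[[cl]]))
    if (length(bad) > 0 || anyNA(v)) {
      row <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stop_kf("non-numeric value in column %s, row %d of %s", cl, row, path)
    }
    tab[[cl]] <- v
  }
  if (anyDuplicated(tab$mt_id)) {
    stop_kf("duplicate mt_id %s in %s",
            tab$mt_id[duplicated(tab$mt_id)][1], path)
  }
  if (any(tab$top_z_nm - tab$bot_z_nm <= 0)) {
    stop_kf("top_z_nm must exceed bot_z_nm for every MT in %s", path)
  }
  slab <- as.numeric(meta[["slab_thickness_nm"]] %||%
                       stats::median(tab$top_z_nm - tab$bot_z_nm))
  if (slab < SLAB_PLAUSIBLE_NM[1] || slab > SLAB_PLAUSIBLE_NM[2]) {
    warning(sprintf("slab thickness %.1f nm outside plausible tomogram range [%.1f, %.1f]",
                    slab, SLAB_PLAUSIBLE_NM[1], SLAB_PLAUSIBLE_NM[2]))
  }
  structure(list(
    fiber_id = meta[["fiber_id"]] %||% basename(path),
    mts = tibble::as_tibble(tab[, FIBER_TABLE_COLUMNS]),
    slab_thickness_nm = slab,
    condition_label = meta[["condition"]] %||% "unknown",
    mt_diameter_nm = 25,
    voxel_nm = if (!is.null(meta[["voxel_nm"]])) as.numeric(meta[["voxel_nm"]]) else NULL
  ), class = "fiber_model")
}

#' Write a connector graph as JSON
#'
#' @param graph A [connector_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connector_graph <- function(graph, path) {
  stopifnot(inherits(graph, "connector_graph"))
  obj <- list(
    fiber_id = graph$fiber_id,
    nodes = graph$nodes,
    hyperedges = lapply(seq_len(nrow(graph$edges)), function(i) {
      e <- list(connector_id = graph$edges$connector_id[i],
                mt_ids = graph$edges$members[[i]])
      if (!is.na(graph$edges$volume_nm3[i])) {
        e$volume_nm3 <- graph$edges$volume_nm3[i]
      }
      e
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Read a connector graph from JSON
#'
#' @param path JSON path written by [write_connector_graph()].
#' @return A [connector_graph()].
#' @export
read_connector_graph <- function(path) {
  if (!file.exists(path)) stop_kf("no such file: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  members <- lapply(obj$hyperedges, function(e) unlist(e$mt_ids))
  vols <- vapply(obj$hyperedges, function(e) {
    if (is.null(e$volume_nm3)) NA_real_ else as.numeric(e$volume_nm3)
  }, numeric(1))
  connector_graph(fiber_id = obj$fiber_id,
                  nodes = unlist(obj$nodes),
                  members = members,
                  volume_nm3 = vols)
}
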