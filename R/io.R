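#' Gaze, trace, AoI and MDrow interchange formats
#'
#' Plain-text readers/writers for the pipeline's external interfaces:
#' eye-tracker-style TSV (`t, x, y, validity`), vehicle-trace CSV
#' (`t, x, y, heading`), AoI definitions as JSON polygon lists
#' (`{name, priority, vertices: [[x, y], ...]}`), and the per-epoch MDrow
#' CSV (`t, gfp_alpha, mdrow, artifact_flag`).
#'
#' @param gaze,trace,aois,mdrow the objects to write.
#' @param path file path.
#' @return The path (writers, invisibly) or the parsed object (readers).
#' @name fatiscope-io
NULL

#' @rdname fatiscope-io
#' @export
write_gaze_tsv <- function(gaze, path) {
  utils::write.table(gaze[, c("t", "x", "y", "validity")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname fatiscope-io
#' @export
read_gaze_tsv <- function(path) {
  d <- utils::read.delim(path)
  tibble::tibble(t = d$t, x = d$x, y = d$y, validity = as.logical(d$validity))
}

#' @rdname fatiscope-io
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(trace[, c("t", "x", "y", "heading")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname fatiscope-io
#' @export
read_trace_csv <- function(path) {
  tibble::as_tibble(read.csv(path))
}

#' @rdname fatiscope-io
#' @export
write_aoi_json <- function(aois, path) {
  lst <- lapply(seq_len(nrow(aois)), function(i) {
    list(name = aois$name[i], priority = aois$priority[i],
         vertices = unname(apply(aois$vertices[[i]], 1, as.list,
                                 simplify = FALSE)))
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fatiscope-io
#' @export
read_aoi_json <- function(path) {
  lst <- jsonlite::read_json(path)
  aoi_set(tibble::tibble(
    name = vapply(lst, `[[`, character(1), "name"),
    priority = vapply(lst, function(x) as.integer(x$priority), integer(1)),
    vertices = lapply(lst, function(x) {
      do.call(rbind, lapply(x$vertices, function(v) unlist(v)))
    })
  ))
}

#' @rdname fatiscope-io
#' @export
write_mdrow_csv <- function(mdrow, path) {
  out <- data.frame(t = mdrow$t, gfp_alpha = mdrow$gfp_alpha,
                    mdrow = mdrow$mdrow, mdrow_smooth = mdrow$mdrow_smooth,
                    artifact_flag = as.integer(mdrow$artifact))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
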