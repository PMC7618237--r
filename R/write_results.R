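#' Write tidy result tables with a run manifest
#'
#' Writes one CSV per result family (probabilities, changes,
#' classifications, contributions, ...) plus a JSON run manifest
#' recording the configuration, seed and package version, so a run can
#' be reproduced from its output directory alone. Empty tables produce
#' header-only files.
#'
#' @param tables a named list of data.frames; each becomes
#'   `<name>.csv` in `out_dir`.
#' @param out_dir output directory (created if absent).
#' @param config optional list recorded verbatim in the manifest.
#' @param seed optional seed recorded in the manifest.
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables),
            all(nzchar(names(tables))))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    stopifnot(is.data.frame(tables[[nm]]))
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    written = as.list(stats::setNames(vapply(tables, nrow, integer(1)),
                                      names(tables))),
    seed = seed,
    config = config,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ncdbench")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(c(paths, mp))
}
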