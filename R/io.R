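#' Read and write force-clamp traces and coverage curves
#'
#' Traces are TSV/CSV files with header `t_s,F_pN,y_um`; coverage curves are
#' TSV with header `t_s,L_um,phi,Lfree_um` plus a JSON sidecar
#' (`<file>.json`) carrying `L_initial` and the model parameters used.
#'
#' @param path File path. `read_trace()` sniffs the delimiter from the
#'   extension (`.csv` vs anything else = tab).
#' @return `read_trace()`: a tibble `t_s`, `F_pN`, `y_um`.
#' @export
read_trace <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  tr <- reader(path, show_col_types = FALSE)
  check_trace(tr)
  tr
}

#' @rdname read_trace
#' @param trace A trace tibble (`t_s`, `F_pN`, `y_um`).
#' @export
write_trace <- function(trace, path) {
  check_trace(trace)
  readr::write_tsv(trace, path)
  invisible(path)
}

#' @rdname read_trace
#' @param curve A `coverage_curve`.
#' @export
write_coverage_curve <- function(curve, path) {
  readr::write_tsv(tibble::as_tibble(curve)[, c("t_s", "L_um", "phi", "Lfree_um")],
                   path)
  side <- list(L_initial = attr(curve, "L_initial"))
  geom <- attr(curve, "geom")
  wlc <- attr(curve, "wlc")
  if (!is.null(geom)) side$geometry <- unclass(geom)
  if (!is.null(wlc)) side$wlc <- unclass(wlc)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname read_trace
#' @export
read_coverage_curve <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    geom <- filament_geometry(side$L_initial)
    new_coverage_curve(df, geom = geom)
  } else {
    tibble::as_tibble(df)
  }
}
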