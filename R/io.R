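#' Read trajectories from the standard CSV dialect
#'
#' The dialect has header `track_id,t_s,x_um,y_um`, one row per sample,
#' coordinates in um with the cell centre at (0, 0); captured tracks simply
#' end inside the chromatin radius. Rows may appear in any order: tracks are
#' grouped by id and sorted by time. Duplicated `(track_id, t_s)` pairs and
#' non-numeric cells are rejected with the offending row named.
#'
#' @param path CSV file path.
#' @param r_cell,r_chr Geometry (um) attached to the result.
#' @return An `aster_tracks` tibble.
#' @export
read_trajectories <- function(path, r_cell = 40, r_chr = 10) {
  # malformed cells surface through readr::problems(), checked below
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    track_id = readr::col_character(),
    t_s = readr::col_double(),
    x_um = readr::col_double(),
    y_um = readr::col_double()), progress = FALSE))
  need <- c("track_id", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("missing trajectory columns: ", paste(miss, collapse = ", ")),
          class = "asterdrift_parse_error")
  }
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    abort(sprintf("non-numeric or malformed cell at row %d", probs$row[1]),
          class = "asterdrift_parse_error")
  }
  bad <- which(is.na(raw$t_s) | is.na(raw$x_um) | is.na(raw$y_um))
  if (length(bad)) {
    abort(sprintf("missing value in data row %d", bad[1]),
          class = "asterdrift_parse_error")
  }
  dup <- duplicated(raw[, c("track_id", "t_s")])
  if (any(dup)) {
    abort(sprintf("duplicated (track_id, t_s) at data row %d", which(dup)[1]),
          class = "asterdrift_parse_error")
  }
  out <- dplyr::arrange(raw, .data$track_id, .data$t_s)
  # track ids back to integer when they are numeric labels
  if (!any(is.na(suppressWarnings(as.numeric(out$track_id))))) {
    out$track_id <- as.numeric(out$track_id)
    if (all(out$track_id == round(out$track_id))) {
      out$track_id <- as.integer(out$track_id)
    }
    out <- dplyr::arrange(out, .data$track_id, .data$t_s)
  }
  as_aster_tracks(out, r_cell, r_chr)
}

#' Write trajectories to the standard CSV dialect
#'
#' Rows are ordered by `track_id` then `t_s` and numeric values are written
#' with 6 significant digits, so repeated writes of the same data are
#' byte-identical.
#'
#' @param tracks A trajectory tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(tracks, path) {
  check_tracks(tracks)
  out <- tracks |>
    dplyr::arrange(.data$track_id, .data$t_s) |>
    dplyr::mutate(dplyr::across(c("t_s", "x_um", "y_um"), ~ signif(.x, 6)))
  readr::write_csv(out[, c("track_id", "t_s", "x_um", "y_um")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write / read an optimizer reference structure as JSON
#'
#' @param reference A reference list (`chi`, `t_c`, `meta`) as produced by
#'   [generate_pseudo_experiment()].
#' @param path JSON file path.
#' @return `path` (write) or the reference list (read).
#' @export
write_reference <- function(reference, path) {
  jsonlite::write_json(reference, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  ref <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref$chi <- tibble::as_tibble(ref$chi)
  ref$t_c <- tibble::as_tibble(ref$t_c)
  ref
}
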