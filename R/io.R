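FCMAP_SCHEMA_VERSION <- "1.0"

signif6 <- function(x) signif(x, 6)  # all floating-point file outputs use 6 s.f.

#' Write a movie as a 16-bit multi-page TIFF with a JSON sidecar
#'
#' Intensities are scaled into the 16-bit range; the scale factor, timebase
#' and metadata go into `<path>.json` (with a schema version) so the movie
#' round-trips through [read_movie_tiff()].
#'
#' @param movie an [imaging_movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "imaging_movie"))
  mx <- max(movie$frames)
  scale <- if (mx > 0) mx else 1
  nt <- dim(movie$frames)[1]
  pages <- lapply(seq_len(nt), function(t) movie$frames[t, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  sidecar <- list(schema_version = FCMAP_SCHEMA_VERSION,
                  frame_interval = movie$frame_interval,
                  start_time = movie$start_time,
                  intensity_scale = scale,
                  metadata = movie$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path (expects `<path>.json` alongside).
#' @return An [imaging_movie()].
#' @export
read_movie_tiff <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path))
    stop_data("movie TIFF or its JSON sidecar not found at ", path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0, dim = c(length(pages), h, w))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]] * sc$intensity_scale
  imaging_movie(frames, sc$frame_interval, sc$start_time,
                as.list(sc$metadata))
}

#' Write / read a stimulus protocol as JSON
#'
#' @param protocol a [gen_stimulus_protocol()] object.
#' @param path JSON path.
#' @return `path` (write) or a `stim_protocol` (read).
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  jsonlite::write_json(c(list(schema_version = FCMAP_SCHEMA_VERSION),
                         unclass(protocol)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  if (!file.exists(path)) stop_data("protocol JSON not found at ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen_stimulus_protocol(intensities = p$intensities,
                        pulse_duration = p$durations[1],
                        inter_pulse = p$inter_pulse,
                        modulation_hz = p$modulation_hz,
                        duty = p$duty)
}

#' Write dF/F traces as long-format CSV
#'
#' Columns `time_s`, `roi_id`, `dff` (6 significant digits), one row per
#' frame per ROI; extra id columns may be prepended via `ids`.
#'
#' @param traces named list of [dff_trace()] objects (names are ROI ids).
#' @param path CSV path.
#' @param ids optional named list of constant id columns (e.g. fly, pre).
#' @return `path`, invisibly.
#' @export
write_dff_csv <- function(traces, path, ids = list()) {
  rows <- lapply(names(traces), function(id) {
    tr <- traces[[id]]
    df <- data.frame(time_s = signif6(tr$times), roi_id = id,
                     dff = signif6(tr$values))
    for (nm in rev(names(ids))) df <- cbind(stats::setNames(data.frame(ids[[nm]]), nm), df)
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write ROI masks as JSON
#'
#' Each ROI is stored as its label plus explicit (row, col) pixel list.
#'
#' @param rois list of [roi_mask()] objects.
#' @param path JSON path.
#' @return `path` (write) or a list of `roi_mask` (read).
#' @export
write_rois_json <- function(rois, path) {
  out <- list(schema_version = FCMAP_SCHEMA_VERSION,
              rois = lapply(rois, function(r) {
                list(label = r$label, pixels = unname(apply(r$pixels, 1, as.list)))
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  if (!file.exists(path)) stop_data("ROI JSON not found at ", path)
  doc <- jsonlite::read_json(path)
  lapply(doc$rois, function(r) {
    if (!is.null(r$pixels)) {
      px <- do.call(rbind, lapply(r$pixels, function(p) c(p[[1]], p[[2]])))
      roi_mask(r$label, px)
    } else {
      roi_disk(r$label, c(r$center[[1]], r$center[[2]]), r$radius)
    }
  })
}

#' Write a connectivity matrix as CSV
#'
#' Long format: `pre_label`, `post_label`, `mean_f_peak`, `n_flies`;
#' untested cells appear with empty `mean_f_peak`.
#'
#' @param mat a `connectivity_matrix`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(mat, path) {
  stopifnot(inherits(mat, "connectivity_matrix"))
  df <- expand.grid(pre_label = rownames(mat$values),
                    post_label = colnames(mat$values),
                    stringsAsFactors = FALSE)
  df$mean_f_peak <- signif6(mat$values[cbind(df$pre_label, df$post_label)])
  df$n_flies <- mat$n_flies[cbind(df$pre_label, df$post_label)]
  df$intensity <- mat$intensity_used
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an angle trace as CSV (`time_s`, `angle_deg`)
#'
#' @param angle an [angle_trace()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_angle_csv <- function(angle, path) {
  stopifnot(inherits(angle, "angle_trace"))
  utils::write.csv(data.frame(time_s = signif6(angle$times),
                              angle_deg = signif6(angle$angles)),
                   path, row.names = FALSE)
  invisible(path)
}
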