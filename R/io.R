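#' Construct an image stack
#'
#' The raw counting substrate: a photoelectron-calibrated movie.  Pixels are
#' stored as a `frames x rows x cols`-indexed list-free 3-D array
#' `[row, col, frame]` of non-negative integer counts.  Coordinates are
#' 0-based `(row, col)` with sub-pixel centroids as floats; frames are
#' 0-based.
#'
#' @param pixels 3-D array `[row, col, frame]` of non-negative counts, or a
#'   list of matrices.
#' @param pixel_size nm/pixel.
#' @param frame_interval,exposure s.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(pixels, pixel_size = 53, frame_interval = 0.010,
                        exposure = 0.010) {
  if (is.list(pixels))
    pixels <- array(unlist(pixels),
                    dim = c(nrow(pixels[[1L]]), ncol(pixels[[1L]]),
                            length(pixels)))
  stopifnot(length(dim(pixels)) == 3L)
  if (any(pixels < 0)) stop("pixel counts must be >= 0")
  check_pos(pixel_size, "pixel_size")
  check_pos(frame_interval, "frame_interval")
  check_pos(exposure, "exposure")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_interval = frame_interval, exposure = exposure),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d frames of %d x %d px, %g nm/px, %g ms/frame\n",
              d[3L], d[1L], d[2L], x$pixel_size, 1000 * x$frame_interval))
  invisible(x)
}

n_frames <- function(stack) dim(stack$pixels)[3L]
get_frame <- function(stack, i) stack$pixels[, , i + 1L]  # 0-based frame

#' Write an image stack as a multipage 16-bit grayscale TIFF
#'
#' Metadata (`pixel_size`, `frame_interval`, `exposure`) is stored as a JSON
#' object in the ImageDescription tag and restored by [read_stack()].
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  meta <- jsonlite::toJSON(list(pixel_size = stack$pixel_size,
                                frame_interval = stack$frame_interval,
                                exposure = stack$exposure),
                           auto_unbox = TRUE, digits = NA)
  frames <- lapply(seq_len(n_frames(stack)), function(i) stack$pixels[, , i])
  write_tiff(path, frames, bits = 16L, description = as.character(meta))
  invisible(path)
}

#' Read a multipage grayscale TIFF as an image stack
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval,exposure overrides; required when the
#'   file carries no embedded metadata.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       exposure = NULL) {
  tif <- read_tiff(path)
  meta <- list()
  if (!is.null(tif$description))
    meta <- tryCatch(jsonlite::fromJSON(tif$description), error = function(e) list())
  pick <- function(override, key) {
    if (!is.null(override)) return(override)
    if (!is.null(meta[[key]])) return(meta[[key]])
    stop("stack metadata key '", key, "' missing from ", path,
         " and no override supplied")
  }
  image_stack(tif$frames,
              pixel_size = pick(pixel_size, "pixel_size"),
              frame_interval = pick(frame_interval, "frame_interval"),
              exposure = pick(exposure, "exposure"))
}

#' Read a single-page label TIFF as an ROI mask
#'
#' @param path TIFF path (0 = outside any ROI, k > 0 = ROI label k).
#' @param stack optional [image_stack()]; when supplied the mask shape must
#'   match the stack frames (error otherwise).
#' @return integer label matrix.
#' @export
read_mask <- function(path, stack = NULL) {
  tif <- read_tiff(path)
  if (length(tif$frames) != 1L) stop("ROI mask must be a single-page TIFF")
  mask <- tif$frames[[1L]]
  if (!is.null(stack)) check_mask(mask, stack)
  mask
}

#' Write an ROI label mask as a single-page TIFF
#' @param mask integer label matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  bits <- if (max(mask) < 256) 8L else 16L
  write_tiff(path, list(mask), bits = bits)
  invisible(path)
}

check_mask <- function(mask, stack) {
  d <- dim(stack$pixels)
  if (nrow(mask) != d[1L] || ncol(mask) != d[2L])
    stop(sprintf("mask shape (%d x %d) does not match stack frames (%d x %d)",
                 nrow(mask), ncol(mask), d[1L], d[2L]))
  invisible(mask)
}

TRACK_SCHEMA <- c("track_id", "frame", "row", "col", "summed_intensity",
                  "background_mean", "background_sd", "roi_label", "extended")
TRACK_HEADER <- "# slimcount track table v1; 0-based (row, col) pixel coordinates, 0-based frames"

validate_tracks <- function(tracks) {
  missing <- setdiff(setdiff(TRACK_SCHEMA, "extended"), names(tracks))
  if (length(missing))
    stop("track table missing column(s): ", paste(missing, collapse = ", "))
  if (!"extended" %in% names(tracks)) tracks$extended <- FALSE
  key <- paste(tracks$track_id, tracks$frame)
  if (anyDuplicated(key))
    stop("track table has duplicated (track_id, frame) rows")
  ord <- order(tracks$track_id, tracks$frame)
  tracks <- tracks[ord, , drop = FALSE]
  bad <- unlist(lapply(split(tracks$frame, tracks$track_id),
                       function(f) any(diff(f) <= 0)))
  if (any(bad))
    stop("frames within a track must be strictly increasing")
  rownames(tracks) <- NULL
  tracks
}

#' Write a track table as CSV
#'
#' The schema is versioned in a leading comment line.
#' @param tracks track table `data.frame`.
#' @param path output CSV.
#' @export
write_tracks <- function(tracks, path) {
  tracks <- validate_tracks(tracks)
  con <- file(path, "w")
  writeLines(TRACK_HEADER, con)
  utils::write.csv(tracks[, TRACK_SCHEMA], con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a track table CSV
#' @param path CSV written by [write_tracks()].
#' @return validated track table `data.frame`.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("track table not found: ", path)
  tracks <- utils::read.csv(path, comment.char = "#")
  validate_tracks(tracks)
}

#' Write / read stoichiometry sample tables
#'
#' Columns: `track_id`, `acquisition_id`, `initial_intensity`
#' (photoelectrons), `stoichiometry` (molecules, fractional).
#' @param samples stoichiometry sample `data.frame`.
#' @param path CSV path.
#' @export
write_stoichiometries <- function(samples, path) {
  need <- c("track_id", "acquisition_id", "initial_intensity", "stoichiometry")
  missing <- setdiff(need, names(samples))
  if (length(missing))
    stop("stoichiometry table missing column(s): ", paste(missing, collapse = ", "))
  con <- file(path, "w")
  writeLines("# slimcount stoichiometry table v1", con)
  utils::write.csv(samples[, need], con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_stoichiometries
#' @export
read_stoichiometries <- function(path) {
  if (!file.exists(path)) stop("stoichiometry table not found: ", path)
  utils::read.csv(path, comment.char = "#")
}
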