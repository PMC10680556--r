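#' Tracking parameters
#'
#' Spot quantification follows the published recipe: the summed intensity is
#' every pixel within `inner_radius` (default 5 px) of the centroid minus
#' the local background averaged over the annulus between 5 and 8 px, and
#' candidates with a summed intensity below `candidate_factor` (default 0.4)
#' times the standard deviation of the background region are discarded.
#' Detection internals (smoothing sigma, threshold) are not published and
#' are exposed as parameters with the defaults below.
#'
#' @param inner_radius disc radius in px; "within r pixels" is read as
#'   Euclidean distance from the sub-pixel centroid to the pixel centre
#'   <= r.
#' @param annulus background annulus `(inner, outer]` in px.
#' @param candidate_factor threshold multiplier on the annulus SD; a spot is
#'   kept iff `summed_intensity >= candidate_factor * background_sd`
#'   (the published rule discards on strict `<`).
#' @param smooth_sigma Gaussian smoothing sigma (px) before maxima
#'   detection.
#' @param threshold_sd detection threshold: smoothed-pixel median plus this
#'   many robust SDs (MAD), computed over the masked region (robust so the
#'   spots themselves do not inflate the threshold).
#' @param max_link_displacement frame-to-frame linking gate, px.
#' @param min_track_length tracks shorter than this are dropped.
#' @param extend_frames after a track's last detection, keep measuring the
#'   summed intensity at the final centroid for up to this many frames so
#'   the photobleached tail (terminal steps) is recorded; 0 disables.
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(inner_radius = 5, annulus = c(5, 8),
                            candidate_factor = 0.4, smooth_sigma = 1.0,
                            threshold_sd = 3.0, max_link_displacement = 5,
                            min_track_length = 6, extend_frames = 120) {
  if (!(inner_radius <= annulus[1L] && annulus[1L] < annulus[2L]))
    stop("require inner_radius <= annulus inner < annulus outer")
  structure(list(inner_radius = inner_radius, annulus = annulus,
                 candidate_factor = candidate_factor,
                 smooth_sigma = smooth_sigma, threshold_sd = threshold_sd,
                 max_link_displacement = max_link_displacement,
                 min_track_length = min_track_length,
                 extend_frames = extend_frames),
            class = "tracking_params")
}

# Separable Gaussian smoothing with truncated, renormalized kernels at the
# image edge (no padding artefacts).
.smooth_cache <- new.env(parent = emptyenv())

smooth_operator <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  if (!is.null(.smooth_cache[[key]])) return(.smooth_cache[[key]])
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - half):(j + half)
    keep <- idx >= 1L & idx <= n
    K[idx[keep], j] <- kern[keep] / sum(kern[keep])
  }
  .smooth_cache[[key]] <- K
  K
}

gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  t(smooth_operator(nrow(img), sigma)) %*% img %*%
    smooth_operator(ncol(img), sigma)
}

local_maxima <- function(img) {
  m <- local_maxima_cpp(img)
  colnames(m) <- c("row", "col")
  m
}

disc_pixels <- function(centroid, radius, nr, nc) {
  # 0-based pixel centres within Euclidean distance <= radius of centroid
  r0 <- max(0L, floor(centroid[1L] - radius))
  r1 <- min(nr - 1L, ceiling(centroid[1L] + radius))
  c0 <- max(0L, floor(centroid[2L] - radius))
  c1 <- min(nc - 1L, ceiling(centroid[2L] + radius))
  if (r0 > r1 || c0 > c1)
    return(list(rows = integer(0), cols = integer(0), dist = numeric(0)))
  rows <- rep(r0:r1, times = c1 - c0 + 1L)
  cols <- rep(c0:c1, each = r1 - r0 + 1L)
  dist <- sqrt((rows - centroid[1L])^2 + (cols - centroid[2L])^2)
  keep <- dist <= radius
  list(rows = rows[keep], cols = cols[keep], dist = dist[keep])
}

#' Detect candidate spots in one frame
#'
#' Centroids are local maxima of the Gaussian-smoothed image above
#' mean + `threshold_sd` * SD of the (masked) smoothed pixels, merged so no
#' two maxima lie closer than `inner_radius` (the brighter wins), then
#' refined to sub-pixel precision by the intensity centroid of the raw image
#' over the inner disc.
#'
#' @param frame_image matrix of photoelectron counts.
#' @param mask optional ROI label matrix (0 = outside); an empty mask gives
#'   an empty result, not an error.
#' @param params a [tracking_params()].
#' @return `data.frame(row, col, peak_value, roi_label)`, 0-based
#'   sub-pixel coordinates.
#' @export
detect_spots <- function(frame_image, mask = NULL, params = tracking_params()) {
  nr <- nrow(frame_image); nc <- ncol(frame_image)
  if (is.null(mask)) mask <- matrix(1L, nr, nc)
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      peak_value = numeric(0), roi_label = integer(0))
  inside <- mask > 0
  if (!any(inside)) return(empty)
  sm <- gaussian_smooth(frame_image, params$smooth_sigma)
  vals <- sm[inside]
  # robust statistics: the masked region contains the spots themselves, so
  # mean/SD would track the signal, not the background
  thr <- stats::median(vals) + params$threshold_sd * stats::mad(vals)
  if (!is.finite(thr)) thr <- stats::median(vals)
  mx <- local_maxima(sm)
  if (!nrow(mx)) return(empty)
  keep <- inside[mx] & sm[mx] > thr
  mx <- mx[keep, , drop = FALSE]
  if (!nrow(mx)) return(empty)
  ord <- order(sm[mx], decreasing = TRUE)
  mx <- mx[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(nrow(mx))) {
    p <- mx[i, ]
    if (!nrow(kept) ||
        all((kept[, 1L] - p[1L])^2 + (kept[, 2L] - p[2L])^2 >=
            params$inner_radius^2))
      kept <- rbind(kept, p)
  }
  n_kept <- nrow(kept)
  rowv <- colv <- peakv <- numeric(n_kept)
  labv <- integer(n_kept)
  for (i in seq_len(n_kept)) {
    p0 <- kept[i, ] - 1  # to 0-based
    disc <- disc_pixels(p0, params$inner_radius, nr, nc)
    w <- pmax(frame_image[cbind(disc$rows + 1L, disc$cols + 1L)], 0)
    cen <- if (sum(w) > 0)
      c(sum(w * disc$rows), sum(w * disc$cols)) / sum(w) else p0
    rowv[i] <- cen[1L]; colv[i] <- cen[2L]
    peakv[i] <- sm[kept[i, 1L], kept[i, 2L]]
    labv[i] <- mask[kept[i, 1L], kept[i, 2L]]
  }
  data.frame(row = rowv, col = colv, peak_value = peakv, roi_label = labv)
}

#' Measure a spot's background-corrected summed intensity
#'
#' Summed intensity = sum of all pixel values within `inner_radius` of the
#' centroid, minus (number of disc pixels) x (background mean).  Background
#' mean and SD are computed over the annulus `(annulus[1], annulus[2]]`.
#' Disc and annulus are truncated at the image boundary; an empty annulus
#' flags the measurement invalid.
#'
#' @param frame_image matrix of photoelectron counts.
#' @param centroid 0-based `(row, col)`, sub-pixel.
#' @param params a [tracking_params()].
#' @param exclude optional matrix of other spots' 0-based `(row, col)`
#'   centroids; annulus pixels within `inner_radius` of any of them are
#'   excluded from the background so a neighbouring spot does not inflate
#'   it (ignored if the exclusion would empty the annulus).
#' @return list with `summed_intensity`, `background_mean`, `background_sd`,
#'   `n_disc`, `n_annulus`, `valid`, `truncated`.
#' @export
measure_spot <- function(frame_image, centroid, params = tracking_params(),
                         exclude = NULL) {
  ex <- if (is.null(exclude) || !length(exclude))
    matrix(numeric(0), 0L, 2L) else matrix(exclude, ncol = 2L)
  v <- measure_spot_cpp(frame_image, centroid[1L], centroid[2L],
                        params$inner_radius, params$annulus[1L],
                        params$annulus[2L], ex)
  list(summed_intensity = v[1L], background_mean = v[2L],
       background_sd = v[3L], n_disc = as.integer(v[4L]),
       n_annulus = as.integer(v[5L]), valid = v[6L] == 1,
       truncated = v[7L] == 1)
}

#' Apply the candidate intensity filter
#'
#' A spot is kept iff `summed_intensity >= candidate_factor * background_sd`
#' (the published rule discards candidates strictly below the threshold).
#' Raising `candidate_factor` never increases the retained count.
#'
#' @param spots `data.frame` with `summed_intensity` and `background_sd`.
#' @param params a [tracking_params()].
#' @return the retained subset of `spots`.
#' @export
filter_candidates <- function(spots, params = tracking_params()) {
  if (!nrow(spots)) return(spots)
  keep <- spots$summed_intensity >=
    params$candidate_factor * spots$background_sd
  keep[is.na(keep)] <- FALSE
  spots[keep, , drop = FALSE]
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: for each consecutive
#' frame pair, the globally closest (head, detection) pairs are linked in
#' order of distance while the distance is within `max_link_displacement`;
#' unmatched detections start new tracks; there is no gap closing (a
#' vanished spot ends its track's linkable run).  Tracks shorter than
#' `min_track_length` are dropped.
#'
#' @param spots `data.frame` with at least `frame`, `row`, `col` (plus any
#'   measurement columns, carried through).
#' @param params a [tracking_params()].
#' @return track table: `spots` columns plus `track_id`, sorted by
#'   (track_id, frame).
#' @export
link_tracks <- function(spots, params = tracking_params()) {
  if (!nrow(spots)) {
    spots$track_id <- integer(0)
    return(spots)
  }
  spots <- spots[order(spots$frame), , drop = FALSE]
  spots$track_id <- NA_integer_
  frames <- sort(unique(spots$frame))
  next_id <- 0L
  prev_idx <- integer(0)  # row indices of the previous frame's spots
  prev_frame <- NULL
  for (f in frames) {
    cur_idx <- which(spots$frame == f)
    assigned <- rep(FALSE, length(cur_idx))
    if (length(prev_idx) && !is.null(prev_frame) && f == prev_frame + 1L) {
      d <- sqrt(outer(spots$row[prev_idx], spots$row[cur_idx], "-")^2 +
                outer(spots$col[prev_idx], spots$col[cur_idx], "-")^2)
      used_prev <- rep(FALSE, length(prev_idx))
      repeat {
        d[used_prev, ] <- Inf; d[, assigned] <- Inf
        if (!length(d) || min(d) > params$max_link_displacement) break
        ij <- which(d == min(d), arr.ind = TRUE)[1L, ]
        spots$track_id[cur_idx[ij[2L]]] <- spots$track_id[prev_idx[ij[1L]]]
        used_prev[ij[1L]] <- TRUE; assigned[ij[2L]] <- TRUE
        if (all(used_prev) || all(assigned)) break
      }
    }
    for (j in which(!assigned)) {
      spots$track_id[cur_idx[j]] <- next_id
      next_id <- next_id + 1L
    }
    prev_idx <- cur_idx
    prev_frame <- f
  }
  len <- table(spots$track_id)
  keep_ids <- as.integer(names(len)[len >= params$min_track_length])
  spots <- spots[spots$track_id %in% keep_ids, , drop = FALSE]
  spots <- spots[order(spots$track_id, spots$frame), , drop = FALSE]
  rownames(spots) <- NULL
  spots
}

#' Detect, measure, filter, link and tail-extend one acquisition
#'
#' Runs the full per-stack tracking stage.  After linking, each track whose
#' last detection precedes the end of the stack is extended: the summed
#' intensity is measured at the final centroid for up to
#' `params$extend_frames` further frames (flagged `extended = TRUE`), so the
#' terminal photobleaching steps used for brightness calibration are present
#' in the intensity trace.
#'
#' @param stack an [image_stack()].
#' @param mask optional ROI label matrix; must match the stack shape.
#' @param params a [tracking_params()].
#' @param verbose emit a per-frame log line with spot counts.
#' @return track table `data.frame` (see [write_tracks()] for the schema).
#' @export
track_stack <- function(stack, mask = NULL, params = tracking_params(),
                        verbose = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.null(mask)) check_mask(mask, stack)
  nf <- n_frames(stack)
  per_frame <- vector("list", nf)
  for (f in seq_len(nf) - 1L) {
    img <- get_frame(stack, f)
    det <- detect_spots(img, mask, params)
    if (nrow(det)) {
      nd <- nrow(det)
      cents <- cbind(det$row, det$col)
      si <- bm <- bs <- numeric(nd); ok <- logical(nd)
      for (i in seq_len(nd)) {
        m <- measure_spot(img, c(det$row[i], det$col[i]), params,
                          exclude = if (nd > 1L) cents[-i, , drop = FALSE])
        si[i] <- m$summed_intensity; bm[i] <- m$background_mean
        bs[i] <- m$background_sd; ok[i] <- m$valid
      }
      det$summed_intensity <- si
      det$background_mean <- bm
      det$background_sd <- bs
      det$frame <- f
      det <- det[ok, , drop = FALSE]
      det <- filter_candidates(det, params)
    } else {
      det$summed_intensity <- det$background_mean <- det$background_sd <-
        numeric(0)
      det$frame <- integer(0)
    }
    if (verbose)
      message(sprintf("frame %d: %d spots", f, nrow(det)))
    per_frame[[f + 1L]] <- det
  }
  spots <- do.call(rbind, per_frame)
  tracks <- link_tracks(spots, params)
  if (!nrow(tracks)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      row = numeric(0), col = numeric(0),
                      summed_intensity = numeric(0),
                      background_mean = numeric(0), background_sd = numeric(0),
                      roi_label = integer(0), extended = logical(0)))
  }
  tracks$extended <- FALSE
  if (params$extend_frames > 0) {
    ext <- list()
    for (id in unique(tracks$track_id)) {
      tr <- tracks[tracks$track_id == id, ]
      last <- tr[which.max(tr$frame), ]
      upto <- min(nf - 1L, last$frame + params$extend_frames)
      if (upto <= last$frame) next
      fr <- (last$frame + 1L):upto
      si <- bm <- bs <- numeric(length(fr)); ok <- logical(length(fr))
      for (k in seq_along(fr)) {
        pf <- per_frame[[fr[k] + 1L]]
        m <- measure_spot(get_frame(stack, fr[k]), c(last$row, last$col),
                          params,
                          exclude = if (nrow(pf)) cbind(pf$row, pf$col))
        si[k] <- m$summed_intensity; bm[k] <- m$background_mean
        bs[k] <- m$background_sd; ok[k] <- m$valid
      }
      if (!any(ok)) next
      ext[[length(ext) + 1L]] <- data.frame(
        track_id = id, frame = fr[ok], row = last$row, col = last$col,
        summed_intensity = si[ok], background_mean = bm[ok],
        background_sd = bs[ok], roi_label = last$roi_label, extended = TRUE)
    }
    if (length(ext))
      tracks <- rbind(tracks[, TRACK_SCHEMA], do.call(rbind, ext))
  }
  tracks <- tracks[, TRACK_SCHEMA]
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  # a detection of another spot may collide with an extension row; keep the
  # detection (extended = FALSE) for uniqueness
  tracks <- tracks[!duplicated(tracks[, c("track_id", "frame")]), ,
                   drop = FALSE]
  rownames(tracks) <- NULL
  tracks
}
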