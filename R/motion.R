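#' Construct a single-camera frame
#'
#' A frame is an 8-bit grayscale pixel matrix (rows = image rows, top row
#' first) with a timestamp and a camera identifier.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @param t timestamp in seconds.
#' @param camera_id `"C1"` or `"C2"`.
#' @return an object of class `frame`.
#' @export
new_frame <- function(pixels, t, camera_id = c("C1", "C2")) {
  camera_id <- match.arg(camera_id)
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("intensities must lie in [0, 255]")
  }
  structure(list(pixels = pixels, t = t, camera_id = camera_id),
            class = "frame")
}

# 8-connected labeling: EBImage::bwlabel labels 4-connected components;
# components that touch only diagonally are merged afterwards.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  p1 <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))   # \ diagonal
  p2 <- cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))   # / diagonal
  pairs <- rbind(p1, p2)
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

frame_pixels <- function(x) if (inherits(x, "frame")) x$pixels else x

#' Detect moving objects between two consecutive frames
#'
#' Two-frame motion detector: absolute frame difference, binary threshold,
#' 8-connected components, and an area filter. Each retained component
#' becomes a blob with a tight bounding box and an intensity-weighted
#' centroid. With the default `mask_current = FALSE` the blobs describe the
#' difference image, so a target that moved further than its own extent
#' yields two blobs (its old and new positions). With
#' `mask_current = TRUE` each component is restricted to pixels that are
#' bright (`>= threshold`) in the *current* frame: the ghost blob at the old
#' position is dropped and the bounding box describes the current
#' silhouette, which is what the end-to-end pipeline uses.
#'
#' @param prev,curr two consecutive frames from the same camera: `frame`
#'   objects (validated for camera, shape and increasing time) or bare
#'   matrices.
#' @param threshold intensity threshold on the absolute difference
#'   (default 20).
#' @param min_area minimum component area in px^2 (default 16).
#' @param mask_current see Description.
#' @return a data.frame of blobs: `camera_id`, centroid `xc`, `yc` (px,
#'   column/row), bounding box `pW`, `pH` (px), `area` (px^2), and bbox
#'   corners `row_min`, `row_max`, `col_min`, `col_max`. Zero rows when
#'   nothing moved.
#' @examples
#' a <- matrix(0, 32, 32); b <- a; b[10:12, 10:14] <- 255
#' detect_moving(a, b, min_area = 4)
#' @export
detect_moving <- function(prev, curr, threshold = 20, min_area = 16,
                          mask_current = FALSE) {
  camera_id <- NA_character_
  if (inherits(prev, "frame") && inherits(curr, "frame")) {
    if (prev$camera_id != curr$camera_id) {
      stop("frames must come from the same camera")
    }
    if (curr$t <= prev$t) stop("frame timestamps must be strictly increasing")
    camera_id <- curr$camera_id
  }
  p <- frame_pixels(prev); c2 <- frame_pixels(curr)
  if (!all(dim(p) == dim(c2))) stop("frame shape mismatch")
  mask <- abs(c2 - p) >= threshold
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0) return(empty_blobs(camera_id))
  # label only the bounding region of the foreground (it is usually sparse)
  r0 <- min(fg[, 1]) - 1L; c0 <- min(fg[, 2]) - 1L
  lab <- label8(mask[(r0 + 1L):max(fg[, 1]), (c0 + 1L):max(fg[, 2]),
                     drop = FALSE] * 1)
  idx <- which(lab > 0, arr.ind = TRUE)
  lbl <- lab[idx]
  idx[, 1] <- idx[, 1] + r0
  idx[, 2] <- idx[, 2] + c0
  areas <- tabulate(lbl)
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(empty_blobs(camera_id))
  weight_img <- if (mask_current) c2 else abs(c2 - p)
  out <- lapply(keep, function(k) {
    sel <- idx[lbl == k, , drop = FALSE]
    w <- weight_img[sel]
    if (mask_current) {
      bright <- c2[sel] >= threshold
      if (!any(bright)) return(NULL)   # ghost of the previous position
      sel <- sel[bright, , drop = FALSE]
      w <- w[bright]
    }
    if (all(w == 0)) w <- rep(1, length(w))
    data.frame(
      camera_id = camera_id,
      xc = sum(sel[, 2] * w) / sum(w),
      yc = sum(sel[, 1] * w) / sum(w),
      pW = diff(range(sel[, 2])) + 1L,
      pH = diff(range(sel[, 1])) + 1L,
      area = areas[k],
      row_min = min(sel[, 1]), row_max = max(sel[, 1]),
      col_min = min(sel[, 2]), col_max = max(sel[, 2]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_blobs(camera_id) else out
}

empty_blobs <- function(camera_id = NA_character_) {
  data.frame(camera_id = character(0), xc = numeric(0), yc = numeric(0),
             pW = integer(0), pH = integer(0), area = integer(0),
             row_min = integer(0), row_max = integer(0),
             col_min = integer(0), col_max = integer(0))
}

#' Pair blobs across the two cameras into pixel observations
#'
#' Greedy one-to-one matching of C1 and C2 blobs at the same timestamp,
#' minimizing the horizontal centroid offset `|xc1 - xc2|` subject to
#' `|xc1 - xc2| <= max_x_offset` and to a triangulable disparity
#' `y1 - y2 >= 1` after converting image rows to signed center-origin
#' pixels (`y = y0/2 - row`). The geometric coordinates `y1`, `y2` are taken
#' from the bounding-box centers (the symmetric estimator of the rendered
#' silhouette center); centroid and bounding-box size are carried over from
#' the C1 blob. Unmatched blobs are dropped and counted in the
#' `n_unmatched` attribute.
#'
#' @param blobs1,blobs2 blob data.frames from [detect_moving()] for C1 and
#'   C2.
#' @param intr a [camera_intrinsics()].
#' @param max_x_offset maximum horizontal centroid offset in px
#'   (default 10).
#' @param t timestamp in seconds attached to the observations (default
#'   `NA`).
#' @return a data.frame of observations with columns `t`, `y1`, `y2`, `xc`,
#'   `yc`, `pW`, `pH`, and attribute `n_unmatched`.
#' @export
pair_stereo <- function(blobs1, blobs2, intr, max_x_offset = 10, t = NA_real_) {
  obs <- empty_observations()
  n1 <- nrow(blobs1); n2 <- nrow(blobs2)
  if (n1 > 0 && n2 > 0) {
    y1 <- intr$y0 / 2 - (blobs1$row_min + blobs1$row_max) / 2
    y2 <- intr$y0 / 2 - (blobs2$row_min + blobs2$row_max) / 2
    cost <- abs(outer(blobs1$xc, blobs2$xc, `-`))
    ok <- cost <= max_x_offset & outer(y1, y2, `-`) >= 1
    cost[!ok] <- Inf
    rows <- list()
    while (any(is.finite(cost))) {
      best <- arrayInd(which.min(cost), dim(cost))
      i <- best[1, 1]; j <- best[1, 2]
      rows[[length(rows) + 1]] <- data.frame(
        t = t, y1 = y1[i], y2 = y2[j],
        xc = blobs1$xc[i], yc = blobs1$yc[i],
        pW = blobs1$pW[i], pH = blobs1$pH[i])
      cost[i, ] <- Inf
      cost[, j] <- Inf
    }
    if (length(rows) > 0) obs <- do.call(rbind, rows)
  }
  attr(obs, "n_unmatched") <- (n1 - nrow(obs)) + (n2 - nrow(obs))
  obs
}

empty_observations <- function() {
  data.frame(t = numeric(0), y1 = numeric(0), y2 = numeric(0),
             xc = numeric(0), yc = numeric(0),
             pW = integer(0), pH = integer(0))
}

read_png_gray <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- apply(px[, , 1:3, drop = FALSE], c(1, 2), mean)
  px * 255
}

#' Detect and pair observations from PNG frame sequences
#'
#' Runs [detect_moving()] on consecutive frames of the per-camera PNG
#' sequences `cam1/frame_%06d.png` and `cam2/frame_%06d.png` under
#' `frames_dir` and pairs the blobs with [pair_stereo()]. Frame timestamps
#' come from a CSV with columns `frame`, `t` (e.g. the `truth.csv` written
#' by [simulate_to_dir()]) or, failing that, from the frame rate.
#'
#' @param frames_dir directory containing `cam1/` and `cam2/`.
#' @param intr a [camera_intrinsics()].
#' @param threshold,min_area,mask_current see [detect_moving()].
#' @param max_x_offset see [pair_stereo()].
#' @param times_csv optional CSV with columns `frame`, `t`.
#' @param fps frame rate used when `times_csv` is absent (default 15).
#' @return an observations data.frame (see [pair_stereo()]).
#' @export
detect_sequence <- function(frames_dir, intr, threshold = 20, min_area = 16,
                            mask_current = FALSE, max_x_offset = 10,
                            times_csv = NULL, fps = 15) {
  f1 <- sort(list.files(file.path(frames_dir, "cam1"), "^frame_.*\\.png$",
                        full.names = TRUE))
  f2 <- sort(list.files(file.path(frames_dir, "cam2"), "^frame_.*\\.png$",
                        full.names = TRUE))
  if (length(f1) != length(f2) || length(f1) < 2) {
    stop("need matching cam1/cam2 sequences with at least two frames")
  }
  t <- if (!is.null(times_csv)) {
    tt <- utils::read.csv(times_csv)
    tt$t[order(tt$frame)]
  } else {
    (seq_along(f1) - 1) / fps
  }
  prev1 <- read_png_gray(f1[1]); prev2 <- read_png_gray(f2[1])
  obs <- vector("list", length(f1))
  for (i in 2:length(f1)) {
    cur1 <- read_png_gray(f1[i]); cur2 <- read_png_gray(f2[i])
    b1 <- detect_moving(prev1, cur1, threshold, min_area, mask_current)
    b2 <- detect_moving(prev2, cur2, threshold, min_area, mask_current)
    obs[[i]] <- pair_stereo(b1, b2, intr, max_x_offset, t = t[i])
    prev1 <- cur1; prev2 <- cur2
  }
  out <- do.call(rbind, obs[!vapply(obs, is.null, logical(1))])
  if (is.null(out)) empty_observations() else out
}

#' Read and write observation tables
#'
#' Plain CSV with header `t,y1,y2,xc,yc,pW,pH`; `y1` and `y2` are signed
#' center-origin pixels.
#'
#' @param path file path.
#' @param obs an observation data.frame (e.g. from [pair_stereo()]),
#'   optionally carrying extra classification columns.
#' @return `read_observations()` returns the data.frame;
#'   `write_observations()` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path)
  need <- c("t", "y1", "y2", "xc", "yc", "pW", "pH")
  missing <- setdiff(need, names(obs))
  if (length(missing) > 0) {
    stop("observations file is missing columns: ",
         paste(missing, collapse = ", "))
  }
  obs
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}
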