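#' Describe a turntable camera rig
#'
#' The imaged world is a cube of side `world_extent` mm with the plant base
#' at its bottom center: x and y span `[-E/2, E/2]`, z spans `[0, E]`. Side
#' views sit on the turntable at the given azimuths looking horizontally at
#' the plant; the optional top view looks straight down. Pixel size is chosen
#' so the full cube (including its corners, a factor `sqrt(2)` wider than the
#' faces) projects inside every image.
#'
#' @param side_azimuths turntable azimuths in degrees, distinct, in
#'   `[0, 360)`. Default: the five equidistant views 0, 72, 144, 216, 288.
#' @param has_top_view include a top-down view.
#' @param image_size pixels, `c(H, W)` (scalar is square).
#' @param projection `"orthographic"` (turntable-at-infinity) or `"pinhole"`.
#' @param camera_distance mm from the cube center to a pinhole camera.
#' @param world_extent mm side of the imaged cube.
#' @return an object of class `camera_rig`.
#' @export
camera_rig <- function(side_azimuths = c(0, 72, 144, 216, 288),
                       has_top_view = TRUE,
                       image_size = c(384, 384),
                       projection = c("orthographic", "pinhole"),
                       camera_distance = NULL,
                       world_extent = 768) {
  projection <- match.arg(projection)
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  if (anyDuplicated(side_azimuths)) stop("side azimuths must be distinct")
  if (any(side_azimuths < 0 | side_azimuths >= 360))
    stop("azimuths must lie in [0, 360)")
  if (is.null(camera_distance)) camera_distance <- 3 * world_extent
  if (projection == "pinhole" && camera_distance <= world_extent)
    stop("pinhole camera_distance must exceed world_extent")
  structure(list(side_azimuths = as.numeric(side_azimuths),
                 has_top_view = isTRUE(has_top_view),
                 image_size = as.integer(image_size),
                 projection = projection,
                 camera_distance = camera_distance,
                 world_extent = world_extent),
            class = "camera_rig")
}

#' Camera rig matched to a carving grid
#'
#' Picks an image width of `2 + floor(1.3 * resolution)` so that the pixel
#' size is slightly larger (about 9 percent) than the voxel size of a grid of
#' the given resolution spanning the same cube. With pixels no finer than
#' voxels, every interior mask pixel receives at least one voxel-center
#' reprojection, which keeps round-trip Dice scores meaningful.
#'
#' @param resolution voxels per axis of the companion grid.
#' @param world_extent mm side of the imaged cube.
#' @param ... forwarded to [camera_rig()].
#' @export
rig_for_grid <- function(resolution, world_extent = 768, ...) {
  w <- 2L + as.integer(floor(1.3 * resolution))
  camera_rig(image_size = c(w, w), world_extent = world_extent, ...)
}

#' @export
print.camera_rig <- function(x, ...) {
  cat("<camera_rig>", length(x$side_azimuths), "side views",
      if (x$has_top_view) "+ top view" else "", "|", x$projection, "|",
      paste(x$image_size, collapse = "x"), "px |", x$world_extent, "mm cube\n")
  invisible(x)
}

#' Calibrated projection operators for a rig
#'
#' Expands a [camera_rig()] into per-view projection matrices. Each view
#' carries a 3x4 matrix `P` mapping world mm `(x, y, z, 1)` to continuous
#' 0-based pixel coordinates `(row, col)`; pinhole views divide by the third
#' row. Rows increase downward (decreasing z in side views).
#'
#' @param rig a [camera_rig()].
#' @return list of `calibrated_view` objects with elements `label`, `P`,
#'   `projective`, `dims`, `px` (nominal mm per pixel), and for pinhole views
#'   the camera `center` and orientation.
#' @export
calibrated_views <- function(rig) {
  H <- rig$image_size[1]; W <- rig$image_size[2]
  E <- rig$world_extent
  px <- sqrt(2) * E / (min(H, W) - 2)
  zc <- E / 2
  views <- list()
  mk <- function(label, P, projective, extra = list()) {
    structure(c(list(label = label, P = P, projective = projective,
                     dims = c(H, W), px = px), extra),
              class = "calibrated_view")
  }
  for (a in rig$side_azimuths) {
    th <- a * pi / 180
    u <- c(-sin(th), cos(th), 0) # image column direction
    if (rig$projection == "orthographic") {
      P <- rbind(c(0, 0, -1 / px, (H - 1) / 2 + zc / px),
                 c(u / px, (W - 1) / 2),
                 c(0, 0, 0, 1))
      views[[length(views) + 1]] <- mk(sprintf("side_%03d", round(a)), P, FALSE,
                                       list(azimuth = a))
    } else {
      center <- c(cos(th), sin(th), 0) * rig$camera_distance + c(0, 0, zc)
      fwd <- c(-cos(th), -sin(th), 0)
      dwn <- c(0, 0, -1)
      D <- rig$camera_distance
      f_px <- (min(H, W) - 2) / 2 * (D - E / sqrt(2)) / (E / sqrt(2))
      R <- rbind(dwn, u, fwd)
      P <- cbind(diag(c(f_px, f_px, 1)) %*% R,
                 -(diag(c(f_px, f_px, 1)) %*% R) %*% center)
      P[1, ] <- P[1, ] + (H - 1) / 2 * P[3, ]
      P[2, ] <- P[2, ] + (W - 1) / 2 * P[3, ]
      views[[length(views) + 1]] <- mk(sprintf("side_%03d", round(a)), P, TRUE,
                                       list(azimuth = a, center = center,
                                            f_px = f_px, Rmat = R))
    }
  }
  if (rig$has_top_view) {
    if (rig$projection == "orthographic") {
      P <- rbind(c(0, 1 / px, 0, (H - 1) / 2),
                 c(1 / px, 0, 0, (W - 1) / 2),
                 c(0, 0, 0, 1))
      views[[length(views) + 1]] <- mk("top", P, FALSE)
    } else {
      center <- c(0, 0, zc + rig$camera_distance)
      fwd <- c(0, 0, -1); dwn <- c(0, 1, 0); u <- c(1, 0, 0)
      D <- rig$camera_distance
      E2 <- E / sqrt(2)
      f_px <- (min(H, W) - 2) / 2 * (D - E / 2) / E2
      R <- rbind(dwn, u, fwd)
      P <- cbind(diag(c(f_px, f_px, 1)) %*% R,
                 -(diag(c(f_px, f_px, 1)) %*% R) %*% center)
      P[1, ] <- P[1, ] + (H - 1) / 2 * P[3, ]
      P[2, ] <- P[2, ] + (W - 1) / 2 * P[3, ]
      views[[length(views) + 1]] <- mk("top", P, TRUE,
                                       list(center = center, f_px = f_px,
                                            Rmat = R))
    }
  }
  views
}

#' @export
print.calibrated_view <- function(x, ...) {
  cat("<calibrated_view>", x$label,
      if (x$projective) "(pinhole)" else "(orthographic)",
      paste(x$dims, collapse = "x"), "px\n")
  invisible(x)
}

#' Project world points through a calibrated view
#'
#' @param view a `calibrated_view` from [calibrated_views()].
#' @param pts n x 3 matrix of world mm coordinates.
#' @return n x 2 matrix of continuous 0-based `(row, col)` pixel coordinates.
#' @export
project_points <- function(view, pts) {
  pts <- rbind(t(matrix(pts, ncol = 3)), 1)
  p <- view$P %*% pts
  if (view$projective) {
    cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
  } else {
    cbind(p[1, ], p[2, ])
  }
}
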