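#' Render binary silhouettes of a plant model
#'
#' Projects the capsule geometry of a [make_plant()] model through every view
#' of a [camera_rig()]. Under orthographic projection the silhouette of a
#' capsule is exactly the projected axis segment dilated by its radius, so a
#' pixel is foreground iff its center lies within the capsule radius of a
#' projected segment. Pinhole views use the distance between the pixel's
#' viewing ray and the capsule axis. Rendering is deterministic.
#'
#' @param model a `plant_model` (or any object with a `segments` matrix
#'   x1,y1,z1,x2,y2,z2,r in mm).
#' @param rig a [camera_rig()].
#' @return an object of class `silhouette_set`: list with `masks` (logical
#'   H x W matrices), `views` (from [calibrated_views()]), `rig`.
#' @export
render_silhouettes <- function(model, rig) {
  segs <- model$segments
  E <- rig$world_extent
  lo <- c(-E / 2, -E / 2, 0); hi <- c(E / 2, E / 2, E)
  pts <- rbind(segs[, 1:3, drop = FALSE], segs[, 4:6, drop = FALSE])
  r2 <- rep(segs[, 7], 2)
  if (any(sweep(pts, 2, lo, `-`) < -1e-9 - r2) ||
      any(sweep(pts, 2, hi, `-`) > 1e-9 + r2))
    stop("model extends outside the rig's world extent")
  views <- calibrated_views(rig)
  masks <- lapply(views, function(v) render_view(segs, v))
  structure(list(masks = masks, views = views, rig = rig),
            class = "silhouette_set")
}

render_view <- function(segs, view) {
  H <- view$dims[1]; W <- view$dims[2]
  mask <- matrix(FALSE, H, W)
  a2 <- project_points(view, segs[, 1:3, drop = FALSE])
  b2 <- project_points(view, segs[, 4:6, drop = FALSE])
  for (s in seq_len(nrow(segs))) {
    r_mm <- segs[s, 7]
    if (!view$projective) {
      rpx <- r_mm / view$px
      p <- a2[s, ]; q <- b2[s, ]
    } else {
      da <- sum((segs[s, 1:3] - view$center) * view$Rmat[3, ])
      db <- sum((segs[s, 4:6] - view$center) * view$Rmat[3, ])
      rpx <- r_mm * view$f_px / max(min(da, db) - r_mm, 1)
      p <- a2[s, ]; q <- b2[s, ]
    }
    r0 <- max(0L, floor(min(p[1], q[1]) - rpx - 1))
    r1 <- min(H - 1L, ceiling(max(p[1], q[1]) + rpx + 1))
    c0 <- max(0L, floor(min(p[2], q[2]) - rpx - 1))
    c1 <- min(W - 1L, ceiling(max(p[2], q[2]) + rpx + 1))
    if (min(p[1], q[1]) - rpx < -0.5 || max(p[1], q[1]) + rpx > H - 0.5 ||
        min(p[2], q[2]) - rpx < -0.5 || max(p[2], q[2]) + rpx > W - 0.5)
      stop(sprintf("model projects outside the image in view '%s'", view$label))
    if (r1 < r0 || c1 < c0) next
    rr <- seq.int(r0, r1); cc <- seq.int(c0, c1)
    pr <- rep(rr, times = length(cc))
    pc <- rep(cc, each = length(rr))
    if (!view$projective) {
      d2 <- dist2_point_seg2(pr, pc, p, q)
      hit <- d2 <= (r_mm / view$px)^2
    } else {
      d <- dist_ray_seg(view, pr, pc, segs[s, 1:3], segs[s, 4:6])
      hit <- d <= r_mm
    }
    if (any(hit))
      mask[cbind(pr[hit] + 1L, pc[hit] + 1L)] <- TRUE
  }
  mask
}

# squared distance from pixel centers (pr, pc) to the 2D segment p--q
dist2_point_seg2 <- function(pr, pc, p, q) {
  v <- q - p
  L2 <- sum(v^2)
  if (L2 < 1e-12) {
    return((pr - p[1])^2 + (pc - p[2])^2)
  }
  t <- ((pr - p[1]) * v[1] + (pc - p[2]) * v[2]) / L2
  t <- pmin(1, pmax(0, t))
  (pr - (p[1] + t * v[1]))^2 + (pc - (p[2] + t * v[2]))^2
}

# distance from the viewing rays of pixels (pr, pc) to the 3D segment a--b
dist_ray_seg <- function(view, pr, pc, a, b) {
  f <- view$f_px
  Rm <- view$Rmat
  H <- view$dims[1]; W <- view$dims[2]
  xc <- (pr - (H - 1) / 2) / f
  yc <- (pc - (W - 1) / 2) / f
  D <- cbind(xc, yc, 1) %*% Rm # world-frame ray directions
  D <- D / sqrt(rowSums(D^2))
  o <- view$center
  v <- b - a
  w0 <- o - a
  Du_v <- as.vector(D %*% v)
  Du_w <- as.vector(D %*% w0)
  # components of v and w0 orthogonal to each ray direction
  Mv2 <- sum(v^2) - Du_v^2
  Mvw <- sum(v * w0) - Du_v * Du_w
  Mw2 <- sum(w0^2) - Du_w^2
  s <- ifelse(Mv2 < 1e-12, 0, Mvw / pmax(Mv2, 1e-12))
  s <- pmin(1, pmax(0, s))
  d2 <- s^2 * sum(v^2) - 2 * s * sum(v * w0) + sum(w0^2) -
    (s * Du_v - Du_w)^2
  sqrt(pmax(d2, 0))
}

#' @export
print.silhouette_set <- function(x, ...) {
  areas <- vapply(x$masks, sum, numeric(1))
  cat("<silhouette_set>", length(x$masks), "views;",
      "foreground px:", paste(areas, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.silhouette_set <- function(x, view = 1, ...) {
  m <- x$masks[[view]]
  graphics::image(t(m[nrow(m):1, ]), col = c("white", "black"), axes = FALSE,
                  main = x$views[[view]]$label, ...)
  invisible(x)
}
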