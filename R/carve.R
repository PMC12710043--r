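#' Specify a cubic voxel grid
#'
#' The grid spans the same world cube as the camera rig: x and y in
#' `[-E/2, E/2]`, z in `[0, E]`, divided into `resolution^3` voxels of side
#' `world_extent / resolution` mm. The default 3 mm voxel size at resolution
#' 512 corresponds to "about 6 cm" for 20 voxels along a leaf base.
#'
#' @param resolution voxels per axis (>= 8).
#' @param world_extent mm side of the cube.
#' @return a list of class `grid_spec` with `resolution`, `voxel_size`,
#'   `origin`.
#' @export
grid_spec <- function(resolution = 512, world_extent = 768) {
  if (resolution < 8) stop("resolution must be >= 8")
  vs <- world_extent / resolution
  structure(list(resolution = as.integer(resolution), voxel_size = vs,
                 origin = c(-world_extent / 2, -world_extent / 2, 0),
                 world_extent = world_extent),
            class = "grid_spec")
}

new_voxel_grid <- function(occupancy, spec) {
  structure(list(occupancy = occupancy, resolution = spec$resolution,
                 voxel_size = spec$voxel_size, origin = spec$origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid>", paste(dim(x$occupancy), collapse = "x"), "voxels of",
      round(x$voxel_size, 3), "mm;", sum(x$occupancy), "occupied\n")
  invisible(x)
}

#' Voxel centers in world coordinates
#'
#' @param grid a `voxel_grid`.
#' @param which optional n x 3 matrix of 1-based (i, j, k) voxel indices;
#'   default all occupied voxels.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_centers <- function(grid, which = NULL) {
  if (is.null(which)) {
    idx <- base::which(grid$occupancy, arr.ind = TRUE)
  } else idx <- which
  sweep((idx - 0.5) * grid$voxel_size, 2, grid$origin, `+`)
}

#' Carve a visual hull from calibrated silhouettes
#'
#' A voxel is occupied iff its center projects inside the foreground mask in
#' every view (visual-hull intersection, center-point membership). An empty
#' intersection produces an empty grid with a warning, not an error.
#'
#' @param silhouettes a `silhouette_set` from [render_silhouettes()], or a
#'   list of logical masks when `views` is supplied.
#' @param gspec a [grid_spec()].
#' @param views optional list of `calibrated_view` objects matching the
#'   masks; taken from `silhouettes` when absent.
#' @return a `voxel_grid`.
#' @export
carve <- function(silhouettes, gspec, views = NULL) {
  if (inherits(silhouettes, "silhouette_set")) {
    masks <- silhouettes$masks
    if (is.null(views)) views <- silhouettes$views
  } else masks <- silhouettes
  if (length(masks) < 2) stop("carving needs at least two views")
  if (length(masks) != length(views))
    stop("number of masks must equal number of views")
  for (i in seq_along(masks)) {
    if (!all(dim(masks[[i]]) == views[[i]]$dims))
      stop("mask dimensions must match view image size")
    if (!is.logical(masks[[i]]))
      stop("masks must be strictly binary (logical)")
  }
  vlist <- lapply(seq_along(masks), function(i)
    list(P = views[[i]]$P, projective = views[[i]]$projective,
         mask = masks[[i]]))
  res <- gspec$resolution
  occ <- carve_cpp(rep(res, 3L), gspec$origin, gspec$voxel_size, vlist)
  dim(occ) <- rep(res, 3L)
  if (!any(occ)) warning("carved hull is empty")
  new_voxel_grid(occ, gspec)
}

#' Voxelize a capsule model directly
#'
#' Marks voxels whose centers lie within a capsule of the model, optionally
#' shrunk by `margin` mm. Used as the geometric reference when checking the
#' visual hull's superset property.
#'
#' @param model a `plant_model` or any object with a `segments` matrix.
#' @param gspec a [grid_spec()].
#' @param margin mm subtracted from each capsule radius.
#' @return a `voxel_grid`.
#' @export
voxelize_model <- function(model, gspec, margin = 0) {
  res <- gspec$resolution
  vs <- gspec$voxel_size
  occ <- array(FALSE, rep(res, 3L))
  segs <- model$segments
  ax <- gspec$origin[1] + (seq_len(res) - 0.5) * vs
  ay <- gspec$origin[2] + (seq_len(res) - 0.5) * vs
  az <- gspec$origin[3] + (seq_len(res) - 0.5) * vs
  for (s in seq_len(nrow(segs))) {
    r <- segs[s, 7] - margin
    if (r <= 0) next
    a <- segs[s, 1:3]; b <- segs[s, 4:6]
    lo <- pmin(a, b) - r; hi <- pmax(a, b) + r
    ii <- which(ax >= lo[1] & ax <= hi[1])
    jj <- which(ay >= lo[2] & ay <= hi[2])
    kk <- which(az >= lo[3] & az <= hi[3])
    if (!length(ii) || !length(jj) || !length(kk)) next
    g <- expand.grid(i = ii, j = jj, k = kk)
    p <- cbind(ax[g$i], ay[g$j], az[g$k])
    v <- b - a
    L2 <- sum(v^2)
    t <- if (L2 < 1e-12) rep(0, nrow(p)) else
      pmin(1, pmax(0, (sweep(p, 2, a) %*% v) / L2))
    cl <- sweep(t %*% t(v), 2, -a)
    d2 <- rowSums((p - cl)^2)
    hit <- d2 <= r^2
    if (any(hit))
      occ[cbind(g$i[hit], g$j[hit], g$k[hit])] <- TRUE
  }
  new_voxel_grid(occ, gspec)
}

#' Reproject a voxel grid into a view
#'
#' A pixel is foreground iff at least one occupied voxel center projects into
#' it. By construction `reproject(carve(S), v)` is a subset of the input mask
#' `S_v` for every view.
#'
#' @param grid a `voxel_grid`.
#' @param view a `calibrated_view`.
#' @return logical H x W mask.
#' @export
reproject <- function(grid, view) {
  if (!any(grid$occupancy)) stop("cannot reproject an empty grid")
  ctr <- voxel_centers(grid)
  rc <- round(project_points(view, ctr))
  H <- view$dims[1]; W <- view$dims[2]
  keep <- rc[, 1] >= 0 & rc[, 1] < H & rc[, 2] >= 0 & rc[, 2] < W
  mask <- matrix(FALSE, H, W)
  if (any(keep))
    mask[rc[keep, , drop = FALSE] + 1L] <- TRUE
  mask
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical matrices of equal shape.
#' @return fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must have identical shapes")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Score a reconstruction by silhouette reprojection
#'
#' Reprojects the hull into every view and compares with the input masks via
#' the Dice coefficient. The aggregate is the unweighted mean over views
#' (including the top view) by default; `aggregate = "pooled"` instead pools
#' pixels across views before computing a single Dice value.
#'
#' @param silhouettes the input `silhouette_set`.
#' @param grid the carved `voxel_grid`.
#' @param threshold acceptance threshold on the aggregate (default 0.70).
#' @param aggregate `"mean"` or `"pooled"`.
#' @return object of class `reconstruction_score` with `per_view`,
#'   `aggregate`, `accepted`.
#' @export
reconstruction_score <- function(silhouettes, grid, threshold = 0.70,
                                 aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  views <- silhouettes$views
  reproj <- lapply(views, function(v) reproject(grid, v))
  per_view <- mapply(dice, silhouettes$masks, reproj)
  names(per_view) <- vapply(views, `[[`, "", "label")
  agg <- if (aggregate == "mean") mean(per_view) else {
    inter <- sum(mapply(function(a, b) sum(a & b), silhouettes$masks, reproj))
    tot <- sum(vapply(silhouettes$masks, sum, numeric(1))) +
      sum(vapply(reproj, sum, numeric(1)))
    if (tot == 0) 1 else 2 * inter / tot
  }
  structure(list(per_view = per_view, aggregate = agg,
                 threshold = threshold,
                 accepted = agg >= threshold),
            class = "reconstruction_score")
}

#' @export
print.reconstruction_score <- function(x, ...) {
  cat("<reconstruction_score> aggregate Dice =", round(x$aggregate, 4),
      if (x$accepted) "(accepted)" else "(rejected)", "\n")
  print(round(x$per_view, 4))
  invisible(x)
}

#' Accept or reject a reconstruction
#'
#' A reconstruction is kept iff its aggregate Dice accuracy is at least the
#' threshold (0.70 by default; the boundary value itself survives, since only
#' scores strictly below the threshold are removed) and its skeleton has a
#' valid tree topology.
#'
#' @param score a `reconstruction_score`.
#' @param topology_ok logical: does the skeleton form a tree?
#' @param threshold Dice acceptance threshold.
#' @return logical flag.
#' @export
accept_reconstruction <- function(score, topology_ok, threshold = 0.70) {
  agg <- if (inherits(score, "reconstruction_score")) score$aggregate else score
  isTRUE(agg >= threshold) && isTRUE(topology_ok)
}
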