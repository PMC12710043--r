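#' PCA coordinate frame of the stem
#'
#' Principal-component frame of the stem node coordinates with fixed sign
#' conventions: `e1` is the first principal axis oriented upward
#' (`e1 . z > 0`), `e2` the second principal axis oriented so `e2 . x >= 0`
#' (ties broken by `e2 . y >= 0`), and `e3 = e1 x e2` completing a
#' right-handed frame. For a collinear stem the second axis is chosen
#' deterministically in the plane orthogonal to `e1` (the projection of the
#' world x axis, or y if degenerate).
#'
#' @param stem_xyz n x 3 matrix of stem node coordinates (mm), or a
#'   `segmented_plant`.
#' @return object of class `stem_frame` with `origin` (centroid), `e1`,
#'   `e2`, `e3`.
#' @export
stem_frame <- function(stem_xyz) {
  if (inherits(stem_xyz, "segmented_plant"))
    stem_xyz <- as.matrix(
      stem_xyz$skeleton$nodes[stem_xyz$stem, c("x", "y", "z")])
  stem_xyz <- as.matrix(stem_xyz)
  if (nrow(stem_xyz) < 2) stop("stem frame needs at least two nodes")
  ctr <- colMeans(stem_xyz)
  X <- sweep(stem_xyz, 2, ctr)
  sv <- svd(X, nu = 0, nv = 3)
  e1 <- sv$v[, 1]
  if (sum(e1 * c(0, 0, 1)) < 0) e1 <- -e1
  collinear <- length(sv$d) < 2 || sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  if (collinear) {
    cand <- c(1, 0, 0)
    e2 <- cand - sum(cand * e1) * e1
    if (sqrt(sum(e2^2)) < 1e-8) {
      cand <- c(0, 1, 0)
      e2 <- cand - sum(cand * e1) * e1
    }
    e2 <- e2 / sqrt(sum(e2^2))
  } else {
    e2 <- sv$v[, 2]
    e2 <- e2 - sum(e2 * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
  }
  if (e2[1] < 0 || (e2[1] == 0 && e2[2] < 0)) e2 <- -e2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  structure(list(origin = ctr, e1 = e1, e2 = e2, e3 = e3),
            class = "stem_frame")
}

#' @export
print.stem_frame <- function(x, ...) {
  tilt <- acos(min(1, max(-1, x$e1[3]))) * 180 / pi
  cat("<stem_frame> e1 tilt from vertical:", round(tilt, 2), "deg\n")
  invisible(x)
}

#' Principal axis of a leaf base
#'
#' First principal axis of the first `n_vox` nodes of the leaf path starting
#' at the junction (about 6 cm at the default 20 nodes and 3 mm voxels),
#' oriented away from the junction: the axis has positive projection onto
#' the direction from the first to the last of those nodes. Shorter leaves
#' use all their nodes.
#'
#' @param leaf_xyz m x 3 matrix of leaf path coordinates ordered from the
#'   junction outward (m >= 2).
#' @param n_vox number of leading nodes to use (default 20).
#' @return unit 3-vector.
#' @export
leaf_axis <- function(leaf_xyz, n_vox = 20) {
  leaf_xyz <- as.matrix(leaf_xyz)
  if (nrow(leaf_xyz) < 2) stop("leaf axis needs at least two nodes")
  m <- min(n_vox, nrow(leaf_xyz))
  pts <- leaf_xyz[seq_len(m), , drop = FALSE]
  X <- sweep(pts, 2, colMeans(pts))
  a <- svd(X, nu = 0, nv = 1)$v[, 1]
  ref <- pts[m, ] - pts[1, ]
  if (sum(a * ref) < 0) a <- -a
  a
}

#' Leaf inclination and azimuth in the stem frame
#'
#' Inclination `theta = arccos(axis . e1)` in degrees (0 along the stem
#' axis), azimuth `phi = atan2(axis . e3, axis . e2)` mapped to `[0, 360)`.
#'
#' @param frame a [stem_frame()].
#' @param axis unit leaf axis from [leaf_axis()].
#' @return object of class `leaf_angle`: list with `theta`, `phi` (degrees).
#' @export
leaf_angles <- function(frame, axis) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("leaf axis has zero length")
  axis <- axis / nrm
  ct <- min(1, max(-1, sum(axis * frame$e1)))
  theta <- acos(ct) * 180 / pi
  if (theta >= 180) theta <- 0
  phi <- (atan2(sum(axis * frame$e3), sum(axis * frame$e2)) * 180 / pi) %% 360
  structure(list(theta = theta, phi = phi), class = "leaf_angle")
}

#' Phyllotaxic angle series from ordered leaf azimuths
#'
#' Differences between sequential leaves' azimuths,
#' `phi_i = (azimuth[i+1] - azimuth[i]) mod 360`, with the range filter
#' flags of [filter_angles()] attached. Plants with fewer than two measured
#' leaves carry no phyllotaxy information and are rejected.
#'
#' @param phis leaf azimuths in degrees, ordered bottom-up by rank.
#' @return object of class `phyllotaxy_series`: `phi_values` (input),
#'   `phyllo` (the series), `Phi` (deviations `|phyllo - 180|`), `kept`
#'   (range-filter flags).
#' @export
phyllo_series <- function(phis) {
  if (length(phis) < 2)
    stop("phyllotaxy requires at least two leaf azimuths")
  phyllo <- diff(phis) %% 360
  structure(list(phi_values = phis, phyllo = phyllo,
                 Phi = abs(phyllo - 180),
                 kept = phyllo >= 90 & phyllo <= 270),
            class = "phyllotaxy_series")
}

#' @export
print.phyllotaxy_series <- function(x, ...) {
  cat("<phyllotaxy_series>", length(x$phyllo), "angles;",
      sum(x$kept), "kept by the 90-270 filter\n")
  print(data.frame(phyllo = round(x$phyllo, 2), Phi = round(x$Phi, 2),
                   kept = x$kept))
  invisible(x)
}

#' Deviation from perfectly alternating phyllotaxy
#'
#' `Phi_i = |phi_i - 180|`: the departure of each phyllotaxic angle from the
#' 180-degree alternating ideal.
#'
#' @param series a `phyllotaxy_series` or numeric vector of angles.
#' @return numeric vector of deviations in `[0, 180]`.
#' @export
deviation <- function(series) {
  phyllo <- if (inherits(series, "phyllotaxy_series")) series$phyllo else series
  abs(phyllo - 180)
}

#' Range filter on phyllotaxic angles
#'
#' An angle is kept iff `90 <= phi <= 270`; equivalently iff its deviation
#' `Phi = |phi - 180|` is at most 90. Both boundaries are inclusive: the
#' removal rules act strictly (below 90, above 270, deviation above 90).
#'
#' @param series a `phyllotaxy_series` or numeric vector of angles.
#' @return logical keep flags.
#' @export
filter_angles <- function(series) {
  phyllo <- if (inherits(series, "phyllotaxy_series")) series$phyllo else series
  phyllo >= 90 & phyllo <= 270
}

#' Conjugate phyllotaxic angle
#'
#' The same pair of leaves measured from the other side of the plant:
#' `360 - phi`, mapped back into `[0, 360)` (so 0 maps to 0). An involution:
#' `conjugate(conjugate(x)) == x`.
#'
#' @param phi angles in degrees, in `[0, 360)`.
#' @return conjugated angles.
#' @export
conjugate <- function(phi) {
  (360 - phi) %% 360
}

#' Align two measurement series over the plant-side ambiguity
#'
#' Which of the two conjugate angles a method reports depends only on the
#' arbitrary side of the plant where measurement starts. Given two series
#' for the same leaf pairs, the Pearson correlation over the shared kept
#' angles decides: non-negative means both series were measured from the
#' same side and `b` is returned unchanged; negative means opposite sides
#' and `b` is conjugated elementwise. With fewer than two shared angles or
#' zero variance the pair is flagged degenerate and left untransformed.
#'
#' @param a,b equal-length angle vectors (degrees); `NA` marks missing
#'   angles.
#' @param kept optional logical vector of angles passing the range filter in
#'   both series; default: both within `[90, 270]`.
#' @return list with `a`, `b` (possibly conjugated), `transformed`, `r`
#'   (the correlation used), `degenerate`.
#' @export
align_pair <- function(a, b, kept = NULL) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (is.null(kept)) kept <- filter_angles(a) & filter_angles(b)
  shared <- which(kept & !is.na(a) & !is.na(b))
  if (length(shared) < 2) {
    return(list(a = a, b = b, transformed = FALSE, r = NA_real_,
                degenerate = TRUE))
  }
  if (stats::sd(a[shared]) == 0 || stats::sd(b[shared]) == 0) {
    return(list(a = a, b = b, transformed = FALSE, r = NA_real_,
                degenerate = TRUE))
  }
  r <- stats::cor(a[shared], b[shared])
  if (r >= 0) {
    list(a = a, b = b, transformed = FALSE, r = r, degenerate = FALSE)
  } else {
    list(a = a, b = conjugate(b), transformed = TRUE, r = r,
         degenerate = FALSE)
  }
}

#' Pooled repeatability of phyllotaxy measurements
#'
#' Squared Pearson correlation over pairs of repeated measurements pooled
#' across plants, after per-plant range filtering and conjugate alignment
#' via [align_pair()]. Degenerate plants (too few shared angles) contribute
#' their angles unaligned, mirroring the no-transformation default.
#'
#' @param pairs list of plants, each a list with angle vectors `a` and `b`.
#' @return squared correlation, or `NA` if the pooled variance is degenerate
#'   or fewer than two pooled pairs remain.
#' @export
repeatability_r2 <- function(pairs) {
  pa <- numeric(0); pb <- numeric(0)
  for (p in pairs) {
    al <- align_pair(p$a, p$b)
    keep <- filter_angles(al$a) & filter_angles(al$b) &
      !is.na(al$a) & !is.na(al$b)
    pa <- c(pa, al$a[keep])
    pb <- c(pb, al$b[keep])
  }
  if (length(pa) < 2) return(NA_real_)
  if (stats::sd(pa) == 0 || stats::sd(pb) == 0) return(NA_real_)
  stats::cor(pa, pb)^2
}

#' Measure leaf angles of a segmented plant
#'
#' Computes the stem PCA frame, each leaf's base axis ([leaf_axis()]), and
#' the per-leaf inclination/azimuth ([leaf_angles()]), then derives the
#' phyllotaxic series over leaves ordered by attachment height.
#'
#' @param seg a `segmented_plant` from [segment_plant()].
#' @param n_vox leading leaf nodes used for the axis (default 20).
#' @return object of class `phyllotaxy_record`: `angles` data frame
#'   (`rank`, `theta_deg`, `phi_deg`, `attach_height_mm`), `series` (a
#'   [phyllo_series()], or `NULL` for fewer than two leaves), `frame`.
#' @export
measure_phyllotaxy <- function(seg, n_vox = 20) {
  frame <- stem_frame(seg)
  nd <- seg$skeleton$nodes
  rows <- lapply(seg$leaves, function(lf) {
    pts <- as.matrix(nd[c(lf$junction, lf$path), c("x", "y", "z")])
    ax <- leaf_axis(pts, n_vox = n_vox)
    ang <- leaf_angles(frame, ax)
    data.frame(rank = lf$rank, theta_deg = ang$theta, phi_deg = ang$phi,
               attach_height_mm = lf$attachment_height_mm)
  })
  angles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rank = integer(0), theta_deg = numeric(0),
               phi_deg = numeric(0), attach_height_mm = numeric(0))
  series <- if (nrow(angles) >= 2) phyllo_series(angles$phi_deg) else NULL
  structure(list(angles = angles, series = series, frame = frame),
            class = "phyllotaxy_record")
}

#' @export
print.phyllotaxy_record <- function(x, ...) {
  cat("<phyllotaxy_record>", nrow(x$angles), "leaves measured\n")
  if (nrow(x$angles))
    print(transform(x$angles, theta_deg = round(theta_deg, 1),
                    phi_deg = round(phi_deg, 1)))
  if (!is.null(x$series)) {
    cat("phyllotaxic angles (deg):",
        paste(round(x$series$phyllo, 1), collapse = ", "), "\n")
  }
  invisible(x)
}
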