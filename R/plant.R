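#' Specify a procedural sorghum-like plant
#'
#' A plant is a vertical stem with `n_leaves` leaves attached at the
#' cumulative internode heights. Leaf `i` emerges at a known azimuth (degrees,
#' counterclockwise from +x viewed from above) and inclination (degrees from
#' the vertical stem axis), then droops along a planar arc. These stored
#' azimuths are the ground truth against which reconstructed angles are
#' judged; the derived true phyllotaxic series is
#' `phi_i = (azimuth[i+1] - azimuth[i]) mod 360`.
#'
#' @param n_leaves number of leaves (>= 0).
#' @param internode_lengths mm of stem between successive leaf attachments;
#'   length `n_leaves` (leaf `i` attaches at `cumsum(internode_lengths)[i]`).
#' @param true_azimuths degrees in `[0, 360)`, one per leaf.
#' @param true_inclinations degrees in `[0, 90]`, one per leaf; the angle
#'   between the leaf base direction and the stem axis.
#' @param leaf_length mm along each leaf midrib.
#' @param leaf_droop dimensionless curvature: total direction change along a
#'   leaf is `leaf_droop * 180` degrees.
#' @param stem_radius,leaf_radius capsule radii in mm.
#' @param tiller optional secondary shoot: a list with elements
#'   `attach_height`, `azimuth`, `inclination`, `length` (mm/deg).
#' @param seed optional RNG seed recorded with the spec (generation itself is
#'   deterministic; the seed documents provenance of randomized specs).
#' @return an object of class `plant_spec`.
#' @seealso [make_plant()], [random_plant_spec()]
#' @export
plant_spec <- function(n_leaves,
                       internode_lengths,
                       true_azimuths,
                       true_inclinations,
                       leaf_length = 300,
                       leaf_droop = 0.35,
                       stem_radius = 8,
                       leaf_radius = 6,
                       tiller = NULL,
                       seed = NULL) {
  if (!is.numeric(n_leaves) || length(n_leaves) != 1 || n_leaves < 0 ||
      n_leaves != round(n_leaves))
    stop("n_leaves must be a single non-negative integer")
  n_leaves <- as.integer(n_leaves)
  if (n_leaves == 0) {
    internode_lengths <- if (missing(internode_lengths)) 300 else internode_lengths
    true_azimuths <- numeric(0)
    true_inclinations <- numeric(0)
  }
  if (n_leaves > 0 && length(internode_lengths) != n_leaves)
    stop("internode_lengths must have length n_leaves")
  if (any(internode_lengths <= 0)) stop("internode lengths must be > 0")
  if (length(true_azimuths) != n_leaves)
    stop("true_azimuths must have length n_leaves")
  if (n_leaves > 0 && (any(true_azimuths < 0) || any(true_azimuths >= 360)))
    stop("azimuths must lie in [0, 360)")
  if (length(true_inclinations) != n_leaves)
    stop("true_inclinations must have length n_leaves")
  if (n_leaves > 0 &&
      (any(true_inclinations < 0) || any(true_inclinations > 90)))
    stop("inclinations must lie in [0, 90]")
  for (len in c(leaf_length, stem_radius, leaf_radius))
    if (!is.numeric(len) || len <= 0) stop("lengths and radii must be > 0")
  if (leaf_droop < 0) stop("leaf_droop must be >= 0")
  structure(list(n_leaves = n_leaves,
                 internode_lengths = as.numeric(internode_lengths),
                 true_azimuths = as.numeric(true_azimuths),
                 true_inclinations = as.numeric(true_inclinations),
                 leaf_length = leaf_length,
                 leaf_droop = leaf_droop,
                 stem_radius = stem_radius,
                 leaf_radius = leaf_radius,
                 tiller = tiller,
                 seed = seed),
            class = "plant_spec")
}

#' True phyllotaxic angle series from leaf azimuths
#'
#' Successive differences of leaf azimuths normalized into `[0, 360)`:
#' `phi_i = (azimuth[i+1] - azimuth[i]) mod 360`. Invariant to adding a
#' constant rotation to all azimuths.
#'
#' @param azimuths leaf azimuths in degrees, ordered bottom-up.
#' @return numeric vector of length `length(azimuths) - 1` (empty for fewer
#'   than two leaves).
#' @export
true_phyllotaxy <- function(azimuths) {
  if (length(azimuths) < 2) return(numeric(0))
  diff(azimuths) %% 360
}

#' @export
print.plant_spec <- function(x, ...) {
  cat("<plant_spec>", x$n_leaves, "leaves, stem height",
      round(sum(x$internode_lengths), 1), "mm\n")
  if (x$n_leaves > 1)
    cat("  true phyllotaxy (deg):",
        paste(round(true_phyllotaxy(x$true_azimuths), 1), collapse = ", "),
        "\n")
  invisible(x)
}

leaf_polyline <- function(origin, azimuth_deg, inclination_deg, length_mm,
                          droop, step = 6) {
  a <- azimuth_deg * pi / 180
  n_step <- max(2L, ceiling(length_mm / step))
  s_mid <- (seq_len(n_step) - 0.5) / n_step # arclength fractions of midpoints
  bend <- droop * 180
  psi <- pmin(inclination_deg + bend * s_mid, 165) * pi / 180
  dirs <- cbind(sin(psi) * cos(a), sin(psi) * sin(a), cos(psi))
  steps <- dirs * (length_mm / n_step)
  pts <- rbind(origin, sweep(apply(steps, 2, cumsum), 2, origin, `+`))
  unname(pts)
}

polyline_segments <- function(pts, radius) {
  n <- nrow(pts) - 1
  cbind(pts[seq_len(n), , drop = FALSE],
        pts[seq_len(n) + 1, , drop = FALSE],
        rep(radius, n))
}

#' Build plant geometry from a spec
#'
#' Realizes a [plant_spec()] as capsule-swept geometry: the stem is a vertical
#' capsule from the ground to the topmost leaf junction, and each leaf is a
#' polyline of capsules following a rising-then-drooping arc in the vertical
#' plane of its azimuth. The ground-truth table (per-leaf attachment height,
#' azimuth, inclination) and the derived true phyllotaxic series travel with
#' the model.
#'
#' @param spec a [plant_spec()].
#' @return an object of class `plant_model` with elements `segments` (matrix
#'   with columns x1,y1,z1,x2,y2,z2,r in mm), `ground_truth` (data frame),
#'   `phi_true`, and `spec`.
#' @export
make_plant <- function(spec) {
  if (!inherits(spec, "plant_spec")) stop("spec must be a plant_spec")
  heights <- cumsum(spec$internode_lengths)
  stem_top <- if (spec$n_leaves > 0) heights[spec$n_leaves] else
    sum(spec$internode_lengths)
  segs <- matrix(c(0, 0, 0, 0, 0, stem_top, spec$stem_radius), nrow = 1)
  if (spec$n_leaves > 0) {
    for (i in seq_len(spec$n_leaves)) {
      pts <- leaf_polyline(c(0, 0, heights[i]), spec$true_azimuths[i],
                           spec$true_inclinations[i], spec$leaf_length,
                           spec$leaf_droop)
      segs <- rbind(segs, polyline_segments(pts, spec$leaf_radius))
    }
  }
  if (!is.null(spec$tiller)) {
    tl <- spec$tiller
    a <- tl$azimuth * pi / 180
    psi <- tl$inclination * pi / 180
    p0 <- c(0, 0, tl$attach_height)
    p1 <- p0 + tl$length * c(sin(psi) * cos(a), sin(psi) * sin(a), cos(psi))
    segs <- rbind(segs, c(p0, p1, spec$stem_radius * 0.8))
  }
  gt <- data.frame(leaf_rank = seq_len(spec$n_leaves),
                   attach_height_mm = if (spec$n_leaves) heights else numeric(0),
                   azimuth_deg = spec$true_azimuths,
                   inclination_deg = spec$true_inclinations)
  colnames(segs) <- c("x1", "y1", "z1", "x2", "y2", "z2", "r")
  structure(list(segments = segs,
                 ground_truth = gt,
                 phi_true = true_phyllotaxy(spec$true_azimuths),
                 spec = spec),
            class = "plant_model")
}

#' @export
print.plant_model <- function(x, ...) {
  cat("<plant_model>", nrow(x$ground_truth), "leaves,",
      nrow(x$segments), "capsule segments\n")
  invisible(x)
}

#' Draw a randomized plant spec
#'
#' Convenience generator for test populations: leaf count uniform on
#' `n_leaves`, internodes uniform on `internode_range`, inclinations uniform
#' on `inclination_range`, and phyllotaxic deviations from the 180-degree
#' alternating ideal uniform on `Phi_range` with random sign, accumulated
#' into azimuths from a uniform starting azimuth.
#'
#' @param seed RNG seed (all randomness in this function is governed by it).
#' @param n_leaves candidate leaf counts.
#' @param internode_range,mm range of internode lengths.
#' @param inclination_range degrees from the stem axis.
#' @param Phi_range range of `|phi - 180|` deviations, degrees.
#' @param ... forwarded to [plant_spec()].
#' @return a [plant_spec()].
#' @export
random_plant_spec <- function(seed, n_leaves = 5:8,
                              internode_range = c(40, 80),
                              inclination_range = c(20, 60),
                              Phi_range = c(0, 60), ...) {
  rng <- local({ set.seed(seed); list(
    k = sample(n_leaves, 1),
    u = runif(64)) })
  k <- rng$k
  u <- rng$u
  internodes <- internode_range[1] +
    (internode_range[2] - internode_range[1]) * u[seq_len(k)]
  incl <- inclination_range[1] +
    (inclination_range[2] - inclination_range[1]) * u[k + seq_len(k)]
  dev <- Phi_range[1] + (Phi_range[2] - Phi_range[1]) * u[2 * k + seq_len(k - 1)]
  sgn <- ifelse(u[3 * k + seq_len(k - 1)] < 0.5, -1, 1)
  az0 <- 360 * u[4 * k]
  az <- (az0 + cumsum(c(0, 180 + sgn * dev))) %% 360
  plant_spec(n_leaves = k, internode_lengths = internodes,
             true_azimuths = az, true_inclinations = incl, seed = seed, ...)
}
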