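#' Reconstruct and measure a plant from silhouettes
#'
#' The full measurement chain: carve the visual hull, thin it to a skeleton,
#' bridge gaps, prune spurious branches, check tree topology, segment stem
#' and leaves, and measure phyllotaxy in the stem PCA frame. Also scores the
#' reconstruction by silhouette reprojection and applies the acceptance
#' filter (aggregate Dice >= 0.70 and tree topology).
#'
#' @param silhouettes a `silhouette_set`.
#' @param resolution voxel grid resolution (default 256).
#' @param max_bridge mm for [join_gaps()].
#' @param classifier spurious-branch classifier for [prune_spurious()].
#' @param n_vox leaf-axis node count for [measure_phyllotaxy()].
#' @param dice_threshold acceptance threshold on the aggregate Dice.
#' @return object of class `plant_reconstruction` with the intermediate
#'   stages (`grid`, `skeleton`, `segmented`, `record`), the
#'   `score`, `topology_ok`, and `accepted`.
#' @export
reconstruct_plant <- function(silhouettes, resolution = 256,
                              max_bridge = 15,
                              classifier = rule_classifier(),
                              n_vox = 20,
                              dice_threshold = 0.70) {
  gspec <- grid_spec(resolution, silhouettes$rig$world_extent)
  grid <- carve(silhouettes, gspec)
  skel <- thin(grid)
  skel <- join_gaps(skel, max_bridge = max_bridge)
  skel <- keep_largest_component(skel)
  skel <- break_small_cycles(skel)
  skel <- prune_spurious(skel, classifier = classifier)
  topo <- is_tree(skel)
  score <- reconstruction_score(silhouettes, grid, threshold = dice_threshold)
  seg <- NULL; rec <- NULL
  if (topo) {
    seg <- segment_plant(skel)
    rec <- measure_phyllotaxy(seg, n_vox = n_vox)
  }
  structure(list(grid = grid, skeleton = skel, segmented = seg,
                 record = rec, score = score, topology_ok = topo,
                 accepted = accept_reconstruction(score, topo,
                                                  dice_threshold)),
            class = "plant_reconstruction")
}

# components beyond bridging reach are reconstruction debris; keep the
# largest (ties: the one containing the lowest node)
keep_largest_component <- function(skel) {
  g <- skeleton_igraph(skel)
  comp <- igraph::components(g)
  if (comp$no <= 1) return(skel)
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1) {
    zmin <- vapply(big, function(cid)
      min(skel$nodes$z[comp$membership == cid]), numeric(1))
    big <- big[which.min(zmin)]
  }
  drop_skeleton_nodes(skel, which(comp$membership != big[1]))
}

#' @export
print.plant_reconstruction <- function(x, ...) {
  cat("<plant_reconstruction> Dice =", round(x$score$aggregate, 3),
      "| tree topology:", x$topology_ok,
      "| accepted:", x$accepted, "\n")
  if (!is.null(x$record)) print(x$record)
  invisible(x)
}

#' Simulate, image and measure one plant
#'
#' Convenience wrapper: build the plant from its spec, render silhouettes on
#' a grid-matched rig, and run [reconstruct_plant()]. The returned object
#' carries the ground truth for comparison.
#'
#' @param spec a [plant_spec()].
#' @param resolution grid resolution.
#' @param rig optional [camera_rig()]; default [rig_for_grid()].
#' @param ... forwarded to [reconstruct_plant()].
#' @return a `plant_reconstruction` with an extra `truth` element (the
#'   model's ground-truth table and true phyllotaxic series).
#' @export
simulate_and_measure <- function(spec, resolution = 256, rig = NULL, ...) {
  model <- make_plant(spec)
  if (is.null(rig)) rig <- rig_for_grid(resolution)
  sil <- render_silhouettes(model, rig)
  out <- reconstruct_plant(sil, resolution = resolution, ...)
  out$truth <- list(ground_truth = model$ground_truth,
                    phi_true = model$phi_true)
  out
}

#' Mirror a segmented plant
#'
#' Reflects the skeleton through the x = 0 plane (the "other side of the
#' plant"). Re-measuring a mirrored plant yields the conjugate of every
#' phyllotaxic angle, which [align_pair()] undoes.
#'
#' @param seg a `segmented_plant`.
#' @return the mirrored `segmented_plant`.
#' @export
mirror_plant <- function(seg) {
  seg$skeleton$nodes$x <- -seg$skeleton$nodes$x
  seg
}
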