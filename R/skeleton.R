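#' Thin a voxel hull to a skeleton graph
#'
#' Topology-preserving curve thinning: simple points (whose deletion does not
#' change the number of object or background components in their
#' neighborhood, for 26/6 connectivity) are removed sequentially in six fixed
#' border-direction sub-iterations until no more can be removed; voxels with
#' at most one object neighbor are retained as curve endpoints. The result is
#' a 1-voxel-wide subset of the hull with the hull's connectivity, returned
#' as a graph over the surviving voxels with 26-adjacency edges.
#'
#' Diagonal 26-adjacency can create spurious triangles along a voxel curve;
#' edges that are chords of such triangles are removed (longest first,
#' deterministic tie-break) so that acyclic skeletons satisfy the tree
#' condition `|E| = |V| - 1`. Genuine cycles (e.g. a toroidal hull) have no
#' chords and are preserved.
#'
#' @param grid a nonempty `voxel_grid`.
#' @return an object of class `skeleton_graph`: `nodes` data frame (voxel
#'   indices `i, j, k`, world mm `x, y, z`, local `radius_mm` estimated as
#'   the distance to the nearest background voxel of the hull), `edges` data
#'   frame (`from`, `to`, `is_bridge`), plus grid metadata.
#' @export
thin <- function(grid) {
  if (!inherits(grid, "voxel_grid")) stop("grid must be a voxel_grid")
  if (!any(grid$occupancy)) stop("cannot thin an empty grid")
  dims <- dim(grid$occupancy)
  keep <- thin_cpp(as.logical(grid$occupancy), dims)
  idx <- arrayInd(keep, dims)
  rad <- local_radius_cpp(as.logical(grid$occupancy), dims, idx - 1L,
                          rmax = 15L)
  xyz <- sweep((idx - 0.5) * grid$voxel_size, 2, grid$origin, `+`)
  nodes <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      radius_mm = rad * grid$voxel_size)
  edges <- adjacency_edges(idx, dims)
  skel <- new_skeleton(nodes, edges, grid)
  reduce_triangles(skel)
}

new_skeleton <- function(nodes, edges, grid = NULL) {
  structure(list(nodes = nodes, edges = edges,
                 voxel_size = if (!is.null(grid)) grid$voxel_size else
                   attr(nodes, "voxel_size")),
            class = "skeleton_graph")
}

# 26-adjacency edges among voxels given as 1-based (i,j,k) rows
adjacency_edges <- function(idx, dims) {
  n <- nrow(idx)
  key <- function(m) (m[, 1] - 1) + dims[1] * ((m[, 2] - 1) +
                                                 dims[2] * (m[, 3] - 1))
  keys <- key(idx)
  lookup <- seq_len(n)
  names(lookup) <- as.character(keys)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
                 (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    m <- lookup[as.character(key(nb[ok, , drop = FALSE]))]
    hit <- !is.na(m)
    from <- c(from, which(ok)[hit])
    to <- c(to, unname(m[hit]))
  }
  data.frame(from = from, to = to, is_bridge = logical(length(from)))
}

# drop diagonal edges that are chords of adjacency triangles
reduce_triangles <- function(skel) {
  g <- skeleton_igraph(skel)
  nd <- skel$nodes
  e <- skel$edges
  len <- sqrt((nd$x[e$from] - nd$x[e$to])^2 + (nd$y[e$from] - nd$y[e$to])^2 +
                (nd$z[e$from] - nd$z[e$to])^2)
  ord <- order(-len, e$from, e$to)
  adj <- igraph::as_adj_list(g, mode = "all")
  alive <- rep(TRUE, nrow(e))
  eid <- igraph::get_edge_ids(g, t(cbind(e$from, e$to)))
  edge_alive <- function(a, b) {
    id <- igraph::get_edge_ids(g, c(a, b))
    id > 0 && alive_e[id]
  }
  alive_e <- rep(TRUE, igraph::ecount(g))
  for (r in ord) {
    a <- e$from[r]; b <- e$to[r]
    common <- intersect(as.integer(adj[[a]]), as.integer(adj[[b]]))
    chord <- FALSE
    for (cmn in common) {
      if (edge_alive(a, cmn) && edge_alive(cmn, b)) { chord <- TRUE; break }
    }
    if (chord) {
      alive[r] <- FALSE
      alive_e[eid[r]] <- FALSE
    }
  }
  skel$edges <- e[alive, , drop = FALSE]
  rownames(skel$edges) <- NULL
  skel
}

skeleton_igraph <- function(skel) {
  igraph::graph_from_data_frame(
    data.frame(from = skel$edges$from, to = skel$edges$to),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(skel$nodes))))
}

#' @export
print.skeleton_graph <- function(x, ...) {
  ncomp <- if (nrow(x$nodes)) igraph::count_components(skeleton_igraph(x)) else 0
  cat("<skeleton_graph>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      ncomp, "component(s),", sum(x$edges$is_bridge), "bridge edge(s)\n")
  invisible(x)
}

#' Is the skeleton a tree?
#'
#' True iff the graph is connected and `|E| = |V| - 1`. Reconstructions whose
#' final skeleton is not a tree are considered topologically incorrect.
#'
#' @param skel a `skeleton_graph`.
#' @return logical flag.
#' @export
is_tree <- function(skel) {
  n <- nrow(skel$nodes)
  if (n == 0) return(FALSE)
  if (n == 1) return(nrow(skel$edges) == 0)
  nrow(skel$edges) == n - 1 &&
    igraph::count_components(skeleton_igraph(skel)) == 1
}

#' Bridge gaps between skeleton components
#'
#' While two connected components have a closest node pair within
#' `max_bridge` mm, the globally closest such pair is connected by a flagged
#' bridge edge; the process repeats until no two components are within reach.
#' Already-connected skeletons are returned unchanged.
#'
#' @param skel a `skeleton_graph`.
#' @param max_bridge maximum bridging distance in mm (default 15, i.e. five
#'   voxels at the reference 3 mm voxel size).
#' @return a `skeleton_graph`.
#' @export
join_gaps <- function(skel, max_bridge = 15) {
  repeat {
    g <- skeleton_igraph(skel)
    comp <- igraph::components(g)$membership
    if (max(comp) <= 1) return(skel)
    xyz <- as.matrix(skel$nodes[, c("x", "y", "z")])
    best <- c(Inf, NA, NA)
    ids <- sort(unique(comp))
    for (ai in seq_along(ids)) {
      for (bi in seq_along(ids)) {
        if (bi <= ai) next
        ia <- which(comp == ids[ai]); ib <- which(comp == ids[bi])
        d <- outer_dist_min(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
        if (d$min < best[1]) best <- c(d$min, ia[d$i], ib[d$j])
      }
    }
    if (!is.finite(best[1]) || best[1] > max_bridge) return(skel)
    skel$edges <- rbind(skel$edges,
                        data.frame(from = best[2], to = best[3],
                                   is_bridge = TRUE))
  }
}

outer_dist_min <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  w <- arrayInd(which.min(d2), dim(d2))
  list(min = sqrt(max(d2[w], 0)), i = w[1], j = w[2])
}

#' Break small reconstruction cycles
#'
#' Visual hulls of crossing leaves can contain thin handles that survive
#' topology-preserving thinning as short cycles. For every chord edge
#' outside a minimum-length spanning tree, the fundamental cycle it closes
#' is measured; chords whose cycle is shorter than `max_cycle` mm are
#' removed (the leftover strand becomes a short terminal branch that
#' [prune_spurious()] deletes). Larger cycles are genuine topology errors
#' and are left in place so that [is_tree()] rejects the reconstruction.
#'
#' @param skel a `skeleton_graph`.
#' @param max_cycle mm; cycles at most this long are considered
#'   reconstruction noise (default 150, half the default leaf length: a
#'   genuine closed loop of plant material cannot be shorter than a leaf's
#'   reach).
#' @return a `skeleton_graph`.
#' @export
break_small_cycles <- function(skel, max_cycle = 150) {
  n <- nrow(skel$nodes)
  if (nrow(skel$edges) <= n - 1) return(skel)
  nd <- skel$nodes
  e <- skel$edges
  len <- sqrt((nd$x[e$from] - nd$x[e$to])^2 + (nd$y[e$from] - nd$y[e$to])^2 +
                (nd$z[e$from] - nd$z[e$to])^2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to, weight = len, eid = seq_len(nrow(e))),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  in_mst <- rep(FALSE, nrow(e))
  in_mst[igraph::E(mst)$eid] <- TRUE
  drop <- logical(nrow(e))
  for (r in which(!in_mst)) {
    d <- igraph::distances(mst, as.character(e$from[r]),
                           as.character(e$to[r]),
                           weights = igraph::E(mst)$weight)
    if (is.finite(d) && d + len[r] <= max_cycle) drop[r] <- TRUE
  }
  if (any(drop)) {
    skel$edges <- e[!drop, , drop = FALSE]
    rownames(skel$edges) <- NULL
  }
  skel
}

#' Terminal-branch features
#'
#' Describes every terminal branch (path from a degree-1 tip to the nearest
#' junction of degree >= 3): arc length (mm), mean local radius (mm),
#' straightness (chord length over arc length), and the attachment and tip
#' heights as fractions of the skeleton's z range. These are the inputs to
#' the spurious-branch classifier.
#'
#' @param skel a connected `skeleton_graph`.
#' @return data frame, one row per terminal branch, with the tip node id,
#'   junction node id and the node ids of the branch (junction excluded) in
#'   a list column.
#' @export
branch_features <- function(skel) {
  g <- skeleton_igraph(skel)
  deg <- igraph::degree(g)
  tips <- which(deg == 1)
  nd <- skel$nodes
  zr <- range(nd$z)
  zspan <- max(zr[2] - zr[1], 1e-9)
  rows <- list()
  for (t in tips) {
    path <- t
    prev <- -1L
    cur <- t
    repeat {
      nbrs <- as.integer(igraph::neighbors(g, cur))
      nbrs <- setdiff(nbrs, prev)
      if (deg[cur] >= 3 || length(nbrs) == 0) break
      prev <- cur
      cur <- nbrs[1]
      if (deg[cur] >= 3) break
      path <- c(path, cur)
    }
    junction <- if (deg[cur] >= 3) cur else NA_integer_
    pts <- as.matrix(nd[path, c("x", "y", "z"), drop = FALSE])
    anchor <- if (!is.na(junction))
      as.numeric(nd[junction, c("x", "y", "z")]) else pts[nrow(pts), ]
    seg <- rbind(pts, anchor)
    arc <- sum(sqrt(rowSums(diff(seg)^2)))
    chord <- sqrt(sum((seg[1, ] - seg[nrow(seg), ])^2))
    rows[[length(rows) + 1]] <- data.frame(
      tip = t, junction = junction,
      length_mm = max(arc, 1e-9),
      mean_radius_mm = mean(nd$radius_mm[path]),
      straightness = min(1, chord / max(arc, 1e-9)),
      attach_height_frac = (anchor[3] - zr[1]) / zspan,
      tip_height_frac = (nd$z[t] - zr[1]) / zspan)
    rows[[length(rows)]]$nodes <- I(list(path))
  }
  do.call(rbind, rows)
}

#' Rule-based spurious-branch classifier
#'
#' Returns a classifier function for [prune_spurious()]: a terminal branch is
#' spurious iff it is shorter than `min_length` mm or its mean local radius
#' is below `radius_floor` mm. With `min_length = 0` and `radius_floor = 0`
#' the classifier labels nothing and pruning is the identity.
#'
#' @param min_length mm; default 60 (twice the 20-voxel leaf-axis window
#'   at the reference 3 mm voxel size: a shorter branch cannot support an
#'   angle measurement).
#' @param radius_floor mm; default 4: visual-hull webbing thins to sheets
#'   about one reference voxel (3 mm) thick, while real organs are at
#'   least the leaf capsule radius (6 mm) across, so branches whose mean
#'   local radius sits below 4 mm trace webbing, not plant material.
#' @return function mapping a [branch_features()] data frame to a logical
#'   vector.
#' @export
rule_classifier <- function(min_length = 60, radius_floor = 4) {
  force(min_length); force(radius_floor)
  function(features) {
    features$length_mm < min_length | features$mean_radius_mm < radius_floor
  }
}

#' Train a margin classifier for spurious branches
#'
#' Builds a linear support-vector classifier over the five
#' [branch_features()] columns from synthetically labeled branches: true
#' branches sampled from clean plant statistics, spurious ones short and
#' thin. A functional stand-in for a classifier trained on hand-labeled real
#' skeletons.
#'
#' @param seed RNG seed.
#' @param n branches per class.
#' @return classifier function usable with [prune_spurious()].
#' @export
train_branch_classifier <- function(seed = 1, n = 200) {
  set.seed(seed)
  real <- data.frame(length_mm = runif(n, 80, 400),
                     mean_radius_mm = runif(n, 3, 12),
                     straightness = runif(n, 0.6, 1),
                     attach_height_frac = runif(n, 0, 1),
                     tip_height_frac = runif(n, 0, 1))
  spur <- data.frame(length_mm = runif(n, 1, 25),
                     mean_radius_mm = runif(n, 0.5, 6),
                     straightness = runif(n, 0.3, 1),
                     attach_height_frac = runif(n, 0, 1),
                     tip_height_frac = runif(n, 0, 1))
  dat <- rbind(real, spur)
  dat$spurious <- factor(rep(c("no", "yes"), each = n))
  fit <- e1071::svm(spurious ~ ., data = dat, kernel = "linear", scale = TRUE)
  cols <- names(real)
  function(features) {
    predict(fit, features[, cols, drop = FALSE]) == "yes"
  }
}

#' Prune spurious terminal branches
#'
#' Scores every terminal branch with the classifier and deletes those
#' labeled spurious, re-evaluating after each round because removals can
#' expose new terminal branches. The branch containing the root (the
#' degree-1 node of minimum height) is never pruned, so the stem path stays
#' connected to the ground. If the classifier labels every branch of a
#' branched skeleton spurious the input is considered degenerate and an
#' error is raised.
#'
#' @param skel a connected `skeleton_graph`.
#' @param classifier function from a [branch_features()] frame to a logical
#'   vector; default [rule_classifier()].
#' @return a `skeleton_graph`.
#' @export
prune_spurious <- function(skel, classifier = rule_classifier()) {
  repeat {
    g <- skeleton_igraph(skel)
    if (igraph::count_components(g) != 1)
      stop("prune_spurious requires a connected skeleton")
    deg <- igraph::degree(g)
    if (!any(deg >= 3)) return(skel) # bare path: nothing to prune
    feats <- branch_features(skel)
    if (is.null(feats) || nrow(feats) == 0) return(skel)
    root <- which(deg == 1)[which.min(skel$nodes$z[deg == 1])]
    spurious <- classifier(feats)
    protected <- feats$tip == root
    if (all(spurious))
      stop("pruning would delete all branches: degenerate input")
    drop_rows <- which(spurious & !protected)
    if (!length(drop_rows)) return(skel)
    drop_nodes <- unique(unlist(feats$nodes[drop_rows]))
    skel <- drop_skeleton_nodes(skel, drop_nodes)
  }
}

drop_skeleton_nodes <- function(skel, drop_nodes) {
  keep <- setdiff(seq_len(nrow(skel$nodes)), drop_nodes)
  remap <- integer(nrow(skel$nodes))
  remap[keep] <- seq_along(keep)
  e <- skel$edges
  ke <- e$from %in% keep & e$to %in% keep
  e <- e[ke, , drop = FALSE]
  e$from <- remap[e$from]; e$to <- remap[e$to]
  rownames(e) <- NULL
  nd <- skel$nodes[keep, , drop = FALSE]
  rownames(nd) <- NULL
  out <- skel
  out$nodes <- nd
  out$edges <- e
  out
}
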