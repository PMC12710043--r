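test_that("thinning a vertical cylinder leaves a near-axial path", {
  cyl <- cylinder_model(radius = 30, z0 = 60, z1 = 700)
  gspec <- grid_spec(64)
  grid <- voxelize_model(cyl, gspec)
  skel <- thin(grid)
  expect_true(is_tree(skel))
  g <- phyllo3d:::skeleton_igraph(skel)
  expect_true(all(igraph::degree(g) <= 2)) # a path
  # nodes stay within one voxel of the axis
  lateral <- sqrt(skel$nodes$x^2 + skel$nodes$y^2)
  expect_true(all(lateral <= sqrt(2) * gspec$voxel_size + 1e-9))
  # and the path spans most of the cylinder height
  expect_lt(min(skel$nodes$z), 150)
  expect_gt(max(skel$nodes$z), 600)
})

test_that("a single voxel thins to a single node without edges", {
  gspec <- grid_spec(16)
  occ <- array(FALSE, rep(16, 3)); occ[8, 8, 8] <- TRUE
  skel <- thin(phyllo3d:::new_voxel_grid(occ, gspec))
  expect_equal(nrow(skel$nodes), 1)
  expect_equal(nrow(skel$edges), 0)
  expect_true(is_tree(skel))
})

test_that("thinning preserves topology across a shape battery", {
  gspec <- grid_spec(48, world_extent = 480)
  # solid cylinder: contractible, skeleton chi = V - E = 1
  cyl <- voxelize_model(cylinder_model(radius = 40, z0 = 50, z1 = 400), gspec)
  s <- thin(cyl)
  expect_equal(nrow(s$nodes) - nrow(s$edges), 1L)
  expect_true(is_tree(s))
  # Y junction: still contractible
  yj <- list(segments = rbind(c(0, 0, 50, 0, 0, 250, 30),
                              c(0, 0, 250, 120, 0, 400, 25),
                              c(0, 0, 250, -120, 0, 400, 25)))
  s <- thin(voxelize_model(yj, gspec))
  expect_equal(nrow(s$nodes) - nrow(s$edges), 1L)
  expect_true(is_tree(s))
  # torus: one cycle survives, chi = 0 and the tree test fails
  ctr <- c(0, 0, 240); R <- 140; r <- 35
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  ring <- cbind(ctr[1] + R * cos(th), ctr[2] + R * sin(th), ctr[3])
  segs <- cbind(ring, ring[c(2:72, 1), ], r)
  s <- thin(voxelize_model(list(segments = segs), gspec))
  expect_equal(nrow(s$nodes) - nrow(s$edges), 0L)
  expect_false(is_tree(s))
})

test_that("is_tree distinguishes paths, cycles and forests", {
  nodes <- data.frame(i = 1:4, j = 1, k = 1:4,
                      x = 1:4, y = 0, z = 1:4, radius_mm = 1)
  path <- phyllo3d:::new_skeleton(nodes,
    data.frame(from = 1:3, to = 2:4, is_bridge = FALSE))
  expect_true(is_tree(path))
  cyc <- phyllo3d:::new_skeleton(nodes,
    data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1), is_bridge = FALSE))
  expect_false(is_tree(cyc))
  forest <- phyllo3d:::new_skeleton(nodes,
    data.frame(from = c(1, 3), to = c(2, 4), is_bridge = FALSE))
  expect_false(is_tree(forest))
})

test_that("join_gaps bridges nearby components and leaves far ones apart", {
  mk <- function(gap_mm) {
    nodes <- data.frame(i = 1, j = 1, k = 1,
                        x = c(0, 5, 10, 10 + gap_mm, 15 + gap_mm),
                        y = 0, z = 0, radius_mm = 1)
    nodes$i <- seq_len(nrow(nodes))
    phyllo3d:::new_skeleton(nodes,
      data.frame(from = c(1, 2, 4), to = c(2, 3, 5), is_bridge = FALSE))
  }
  near <- join_gaps(mk(5), max_bridge = 10)
  expect_equal(igraph::count_components(phyllo3d:::skeleton_igraph(near)), 1)
  expect_equal(sum(near$edges$is_bridge), 1)
  # the bridge joins the closest pair (nodes 3 and 4)
  br <- near$edges[near$edges$is_bridge, ]
  expect_setequal(c(br$from, br$to), c(3, 4))
  far <- join_gaps(mk(50), max_bridge = 10)
  expect_equal(igraph::count_components(phyllo3d:::skeleton_igraph(far)), 2)
  # connected input is returned unchanged
  sk <- near
  expect_identical(join_gaps(sk, max_bridge = 10), sk)
})

test_that("injected noise spurs are pruned while true leaves survive", {
  rec <- fixture_recon(2, 128)
  skel <- rec$skeleton
  k <- length(rec$segmented$leaves)
  # graft a 2-node spur onto a mid-stem node
  mid <- rec$segmented$stem[round(length(rec$segmented$stem) / 3)]
  nd <- skel$nodes
  base <- nd[mid, ]
  spur <- rbind(base, base)
  spur$x <- base$x + c(8, 16); spur$radius_mm <- 2
  noisy <- skel
  noisy$nodes <- rbind(nd, spur)
  rownames(noisy$nodes) <- NULL
  n0 <- nrow(nd)
  noisy$edges <- rbind(skel$edges,
                       data.frame(from = c(mid, n0 + 1), to = c(n0 + 1, n0 + 2),
                                  is_bridge = FALSE))
  expect_true(is_tree(noisy))
  pruned <- prune_spurious(noisy)
  expect_equal(nrow(pruned$nodes), n0)
  seg <- segment_plant(pruned)
  expect_equal(length(seg$leaves), k)
})

test_that("pruning a clean plant removes nothing", {
  rec <- fixture_recon(2, 128)
  skel <- rec$skeleton
  again <- prune_spurious(skel)
  expect_equal(nrow(again$nodes), nrow(skel$nodes))
})

test_that("the permissive rule classifier is the identity transform", {
  rec <- fixture_recon(2, 128)
  skel <- rec$skeleton
  out <- prune_spurious(skel, rule_classifier(min_length = 0))
  expect_identical(out$nodes, skel$nodes)
})

test_that("pruning never disconnects the stem from the root", {
  rec <- fixture_recon(4, 128)
  skel <- prune_spurious(rec$skeleton, rule_classifier(min_length = 120))
  g <- phyllo3d:::skeleton_igraph(skel)
  expect_equal(igraph::count_components(g), 1)
  expect_lt(min(skel$nodes$z), 100) # root region retained
})

test_that("an all-spurious labeling raises a degenerate-input error", {
  rec <- fixture_recon(2, 128)
  expect_error(prune_spurious(rec$skeleton, function(f) rep(TRUE, nrow(f))),
               "degenerate")
})

test_that("the trained margin classifier separates synthetic branch classes", {
  cls <- train_branch_classifier(seed = 7)
  feats <- data.frame(length_mm = c(200, 5), mean_radius_mm = c(6, 1.5),
                      straightness = c(0.9, 0.8),
                      attach_height_frac = c(0.4, 0.4),
                      tip_height_frac = c(0.6, 0.45))
  expect_equal(unname(cls(feats)), c(FALSE, TRUE))
})

test_that("thinning is deterministic", {
  sil <- fixture_silhouettes(64)
  grid <- carve(sil, grid_spec(64))
  s1 <- thin(grid); s2 <- thin(grid)
  expect_identical(s1$nodes, s2$nodes)
  expect_identical(s1$edges, s2$edges)
})
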