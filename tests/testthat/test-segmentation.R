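path_skeleton <- function(z = seq(0, 100, by = 5)) {
  n <- length(z)
  nodes <- data.frame(i = seq_len(n), j = 1, k = seq_len(n),
                      x = 0, y = 0, z = z, radius_mm = 1)
  phyllo3d:::new_skeleton(nodes,
    data.frame(from = seq_len(n - 1), to = seq_len(n - 1) + 1,
               is_bridge = FALSE))
}

test_that("a bare path is all stem with no leaves", {
  seg <- segment_plant(path_skeleton())
  expect_length(seg$leaves, 0)
  expect_length(seg$stem, 21)
  expect_equal(seg$skeleton$nodes$z[seg$stem[1]], 0) # ordered from the root
})

test_that("a 3-tip tree classifies the shared trunk as stem", {
  # trunk 1-5, two arms from node 5
  nodes <- data.frame(i = 1:9, j = 1, k = 1:9,
                      x = c(0, 0, 0, 0, 0, 10, 20, -10, -20),
                      y = 0,
                      z = c(0, 10, 20, 30, 40, 45, 50, 45, 50),
                      radius_mm = 1)
  skel <- phyllo3d:::new_skeleton(nodes,
    data.frame(from = c(1, 2, 3, 4, 5, 6, 5, 8),
               to = c(2, 3, 4, 5, 6, 7, 8, 9), is_bridge = FALSE))
  seg <- segment_plant(skel)
  expect_true(all(1:5 %in% seg$stem))
  expect_length(seg$leaves, 2)
  expect_true(seg$fallback) # two non-root tips -> >=2 fallback rule
})

test_that("non-tree input is rejected and a floating root is detected", {
  nodes <- data.frame(i = 1:3, j = 1, k = 1:3, x = c(0, 1, 0), y = 0,
                      z = c(0, 1, 2), radius_mm = 1)
  cyc <- phyllo3d:::new_skeleton(nodes,
    data.frame(from = c(1, 2, 3), to = c(2, 3, 1), is_bridge = FALSE))
  expect_error(segment_plant(cyc), "tree")
})

test_that("leaf ordering follows attachment height with stated tie-breaks", {
  h <- c(10, 50, 90)
  seg <- list(leaves = list(
    list(rank = NA, junction = 1, path = 2, attachment_height_mm = 90),
    list(rank = NA, junction = 1, path = 2, attachment_height_mm = 10),
    list(rank = NA, junction = 1, path = 2, attachment_height_mm = 50)),
    skeleton = list(nodes = data.frame(x = c(0, 1), y = c(0, 0),
                                       z = c(0, 1))))
  class(seg) <- "segmented_plant"
  out <- order_leaves(seg)
  expect_equal(vapply(out$leaves, `[[`, numeric(1), "attachment_height_mm"),
               sort(h))
  expect_equal(vapply(out$leaves, `[[`, integer(1), "rank"), 1:3)
})

test_that("equal heights break by azimuth, and ordering is permutation-invariant", {
  nodes <- data.frame(x = c(0, cos(10 * pi / 180), cos(200 * pi / 180)),
                      y = c(0, sin(10 * pi / 180), sin(200 * pi / 180)),
                      z = c(50, 50, 50))
  mk <- function(perm) {
    leaves <- list(
      list(rank = NA, junction = 1, path = 2, attachment_height_mm = 50),
      list(rank = NA, junction = 1, path = 3, attachment_height_mm = 50))
    seg <- list(leaves = leaves[perm], skeleton = list(nodes = nodes))
    class(seg) <- "segmented_plant"
    order_leaves(seg)
  }
  for (perm in list(1:2, 2:1)) {
    out <- mk(perm)
    expect_equal(out$leaves[[1]]$path, 2) # azimuth 10 ranks below azimuth 200
    expect_equal(out$leaves[[2]]$path, 3)
  }
})

test_that("path-count rule matches the subtree-tip-count oracle on random trees", {
  set.seed(11)
  for (trial in 1:40) {
    n <- sample(5:50, 1)
    g <- igraph::sample_tree(n, method = "prufer")
    deg <- igraph::degree(g)
    tips <- which(deg == 1)
    root <- tips[1]
    other <- setdiff(tips, root)
    counts <- phyllo3d:::subtree_tip_counts(g, root, other)
    # oracle: enumerate root-to-tip paths and count node memberships
    oracle <- integer(n)
    for (t in other) {
      p <- as.integer(igraph::shortest_paths(g, root, t)$vpath[[1]])
      oracle[p] <- oracle[p] + 1L
    }
    expect_equal(counts[-root], oracle[-root])
    expect_equal(which(counts > 2), which(oracle > 2))
  }
})

test_that("synthetic plants segment into the true number of leaves", {
  for (s in c(2, 4)) {
    rec <- fixture_recon(s, 128)
    k <- nrow(rec$truth$ground_truth)
    expect_equal(length(rec$segmented$leaves), k)
    # attachment heights track truth in rank order; the estimate is biased
    # upward because the first stretch of an inclined leaf base lies within
    # the stem's hull and is absorbed into the stem line
    h_meas <- vapply(rec$segmented$leaves, `[[`, numeric(1),
                     "attachment_height_mm")
    h_true <- rec$truth$ground_truth$attach_height_mm
    expect_false(is.unsorted(h_meas))
    expect_true(all(h_meas - h_true >= -2 * 6))      # never far below truth
    expect_true(all(abs(h_meas - h_true) <= 8 * 6))  # within 8 voxels
  }
})

test_that("segmentation is invariant to node-order permutation", {
  rec <- fixture_recon(2, 128)
  skel <- rec$skeleton
  set.seed(5)
  perm <- sample(nrow(skel$nodes))
  inv <- order(perm)
  pskel <- skel
  pskel$nodes <- skel$nodes[perm, , drop = FALSE]
  rownames(pskel$nodes) <- NULL
  pskel$edges <- data.frame(from = inv[skel$edges$from],
                            to = inv[skel$edges$to],
                            is_bridge = skel$edges$is_bridge)
  a <- segment_plant(skel)
  b <- segment_plant(pskel)
  key <- function(seg, ids) {
    nd <- seg$skeleton$nodes[ids, c("x", "y", "z")]
    nd <- nd[order(nd$x, nd$y, nd$z), ]
    rownames(nd) <- NULL
    nd
  }
  expect_equal(key(a, a$stem), key(b, b$stem))
  expect_equal(length(a$leaves), length(b$leaves))
  for (i in seq_along(a$leaves))
    expect_equal(key(a, a$leaves[[i]]$path), key(b, b$leaves[[i]]$path))
})
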