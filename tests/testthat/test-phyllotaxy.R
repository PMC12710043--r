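test_that("a vertical stem yields e1 = z exactly and deterministic frames", {
  z <- seq(0, 300, by = 10)
  stem <- cbind(0, 0, z)
  fr <- stem_frame(stem)
  expect_equal(fr$e1, c(0, 0, 1))
  expect_equal(sum(fr$e2 * fr$e1), 0, tolerance = 1e-12)
  # right-handed orthonormal
  expect_equal(sum(fr$e3^2), 1, tolerance = 1e-12)
  cr <- c(fr$e1[2] * fr$e2[3] - fr$e1[3] * fr$e2[2],
          fr$e1[3] * fr$e2[1] - fr$e1[1] * fr$e2[3],
          fr$e1[1] * fr$e2[2] - fr$e1[2] * fr$e2[1])
  expect_equal(fr$e3, cr)
  # shuffled node order gives the identical frame
  set.seed(3)
  fr2 <- stem_frame(stem[sample(nrow(stem)), ])
  expect_equal(fr2$e1, fr$e1)
  expect_equal(fr2$e2, fr$e2)
})

test_that("a tilted stem's tilt is recovered", {
  set.seed(8)
  z <- seq(0, 400, by = 5)
  tilt <- 10 * pi / 180
  stem <- cbind(z * sin(tilt) + rnorm(length(z), 0, 1.5),
                rnorm(length(z), 0, 1.5), z * cos(tilt))
  fr <- stem_frame(stem)
  ang <- acos(sum(fr$e1 * c(0, 0, 1))) * 180 / pi
  expect_equal(ang, 10, tolerance = 0.5)
})

test_that("leaf axes follow the base tangent, not the chord", {
  # straight horizontal leaf along +x
  pts <- cbind(seq(0, 100, by = 5), 0, 50)
  expect_equal(leaf_axis(pts), c(1, 0, 0))
  # 10 nodes with n_vox = 20: uses all without error
  expect_silent(a <- leaf_axis(pts[1:10, ], n_vox = 20))
  expect_equal(a, c(1, 0, 0))
  expect_error(leaf_axis(pts[1, , drop = FALSE]), "two nodes")
  # strongly drooping leaf: axis within 15 degrees of the junction tangent
  pl <- phyllo3d:::leaf_polyline(c(0, 0, 200), azimuth_deg = 0,
                                inclination_deg = 45, length_mm = 300,
                                droop = 0.6, step = 3)
  ax <- leaf_axis(pl, n_vox = 20)
  tangent <- c(sin(45 * pi / 180), 0, cos(45 * pi / 180))
  ang_t <- acos(sum(ax * tangent)) * 180 / pi
  expect_lt(ang_t, 15)
  chord <- pl[nrow(pl), ] - pl[1, ]
  chord <- chord / sqrt(sum(chord^2))
  expect_lt(ang_t, acos(sum(ax * chord)) * 180 / pi)
})

test_that("leaf angles respect the frame definition", {
  fr <- stem_frame(cbind(0, 0, seq(0, 100, 5)))
  expect_equal(leaf_angles(fr, fr$e1)$theta, 0)
  a2 <- leaf_angles(fr, fr$e2)
  expect_equal(a2$theta, 90)
  expect_equal(a2$phi, 0)
  expect_equal(leaf_angles(fr, -fr$e3)$phi, 270)
  expect_error(leaf_angles(fr, c(0, 0, 0)), "zero")
})

test_that("phyllotaxic series use modular differences", {
  expect_equal(phyllo_series(c(0, 180, 0))$phyllo, c(180, 180))
  expect_equal(phyllo_series(c(350, 10))$phyllo, 20)
  expect_equal(phyllo_series(c(10, 350))$phyllo, 340)
  expect_error(phyllo_series(123), "two")
})

test_that("deviations and boundaries match the filtering rules", {
  expect_equal(deviation(180), 0)
  expect_equal(deviation(178.95), 1.05)
  expect_equal(deviation(90), 90)
  expect_false(filter_angles(89.9))
  expect_true(filter_angles(270))   # strictly-greater removal keeps 270
  expect_true(filter_angles(90))
  expect_false(filter_angles(271))  # deviation 91 > 90 removed
})

test_that("phi-range filter and deviation filter select identical sets", {
  set.seed(21)
  phi <- runif(5000, 0, 360)
  expect_identical(filter_angles(phi), deviation(phi) <= 90)
})

test_that("conjugation is the side-of-plant involution", {
  expect_equal(conjugate(160), 200)
  expect_equal(conjugate(180), 180)
  expect_equal(conjugate(0), 0)
  set.seed(2)
  x <- runif(100, 0, 360)
  expect_equal(conjugate(conjugate(x)), x, tolerance = 1e-12)
})

test_that("align_pair detects and undoes opposite-side measurement", {
  a <- c(160, 200, 150, 210, 190)
  same <- align_pair(a, a)
  expect_false(same$transformed)
  expect_equal(same$r, 1)
  opp <- align_pair(a, conjugate(a))
  expect_true(opp$transformed)
  expect_identical(opp$b, conjugate(conjugate(a)))
  expect_equal(opp$b, a)
  # correlation magnitude is preserved under alignment
  set.seed(4)
  b <- a + rnorm(5, 0, 8)
  expect_equal(abs(stats::cor(a, b)),
               abs(stats::cor(align_pair(a, conjugate(b))$a,
                              align_pair(a, conjugate(b))$b)),
               tolerance = 1e-12)
  # degenerate cases
  expect_true(align_pair(c(100, NA, NA), c(110, NA, NA))$degenerate)
  expect_true(align_pair(c(150, 150, 150), c(150, 150, 150))$degenerate)
})

test_that("repeatability behaves under identity, noise and monotonicity", {
  plants <- lapply(1:10, function(i) {
    a <- runif(5, 100, 260)
    list(a = a, b = a)
  })
  expect_equal(repeatability_r2(plants), 1)
  # independent noise: near-zero R2 (long per-plant series keep the
  # conjugate-alignment selection bias negligible)
  set.seed(9)
  null <- lapply(1:5, function(i)
    list(a = runif(300, 90, 270), b = runif(300, 90, 270)))
  expect_lt(repeatability_r2(null), 0.01)
  # increasing noise decreases expected R2
  r2_at <- function(sd) {
    set.seed(31)
    mean(vapply(1:20, function(i) {
      plants <- lapply(1:20, function(j) {
        a <- runif(5, 110, 250)
        list(a = a, b = pmin(pmax(a + rnorm(5, 0, sd), 90), 270))
      })
      repeatability_r2(plants)
    }, numeric(1)))
  }
  expect_gt(r2_at(5), r2_at(20))
  expect_gt(r2_at(20), r2_at(60))
})

test_that("rotating the whole plant shifts every azimuth by a constant", {
  rec <- fixture_recon(2, 128)
  seg <- rec$segmented
  th <- 35 * pi / 180
  rot <- seg
  x <- seg$skeleton$nodes$x; y <- seg$skeleton$nodes$y
  rot$skeleton$nodes$x <- cos(th) * x - sin(th) * y
  rot$skeleton$nodes$y <- sin(th) * x + cos(th) * y
  m0 <- measure_phyllotaxy(seg)
  m1 <- measure_phyllotaxy(rot)
  dphi <- (m1$angles$phi_deg - m0$angles$phi_deg) %% 360
  expect_lt(max(circ_err(dphi, dphi[1])), 1)
  expect_lt(max(circ_err(m1$series$phyllo, m0$series$phyllo)), 1)
})

test_that("mirroring the plant conjugates the series exactly", {
  rec <- fixture_recon(4, 128)
  seg <- rec$segmented
  m0 <- measure_phyllotaxy(seg)
  m1 <- measure_phyllotaxy(mirror_plant(seg))
  expect_equal(m1$series$phyllo, conjugate(m0$series$phyllo),
               tolerance = 1e-6)
  al <- align_pair(m0$series$phyllo, m1$series$phyllo)
  expect_true(al$transformed)
  expect_identical(al$b, conjugate(m1$series$phyllo))
  expect_equal(al$b, m0$series$phyllo, tolerance = 1e-6)
})
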