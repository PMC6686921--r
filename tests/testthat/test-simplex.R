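make_frame2d <- function(ve, vf, va) {
  # direct 2-D frame for formula-level tests (bypasses the 3-D transform)
  V <- rbind(E = ve, F = vf, A = va)
  colnames(V) <- c("x", "y")
  detT <- (V["F", 1] - V["E", 1]) * (V["A", 2] - V["E", 2]) -
    (V["A", 1] - V["E", 1]) * (V["F", 2] - V["E", 2])
  per <- sum(sqrt(rowSums((V - V[c(2, 3, 1), ])^2)))
  structure(list(vertices2d = V, detT = detT, perimeter = per),
            class = "triadmix_frame")
}

test_that("triangle construction validates its vertices", {
  tri <- build_triangle(c(1, 2, 2), c(2, 1, 2), c(2, 2, 1))
  expect_s3_class(tri, "triadmix_triangle")
  expect_identical(rownames(tri), c("E", "F", "A"))
  expect_error(build_triangle(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)),
               "degenerate")
  expect_error(build_triangle(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "degenerate")
  expect_error(build_triangle(c(1, NA, 0), c(0, 1, 0), c(0, 0, 1)), "finite")
})

test_that("planarize leaves a z = 0 triangle in place and removes translation", {
  tri <- build_triangle(c(1, 2, 0), c(0, 0, 0), c(3, 0, 0))
  fr <- planarize(tri)
  expect_equal(fr$vertices2d,
               rbind(E = c(1, 2), F = c(0, 0), A = c(3, 0)),
               tolerance = 1e-12, ignore_attr = "dimnames")

  shifted <- build_triangle(c(1, 2, 1), c(0, 0, 1), c(3, 0, 1))
  fr2 <- planarize(shifted, points = rbind(c(0, 0, 1), c(1, 1, 2)))
  expect_equal(fr2$vertices2d, fr$vertices2d, tolerance = 1e-12)
  expect_equal(unname(fr2$points[1, ]), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(fr2$points[2, "z"]), 1, tolerance = 1e-12)
})

test_that("the planar frame satisfies its orientation convention", {
  withr::local_seed(21)
  for (rep in 1:50) {
    fr <- planarize(random_triangle())
    V <- fr$vertices2d
    expect_equal(unname(V["F", ]), c(0, 0))
    expect_equal(unname(V["A", "y"]), 0)
    expect_gt(V["A", "x"], V["F", "x"])
    expect_gt(V["E", "y"], 0)
  }
})

test_that("planarization is rigid: all distances preserved", {
  withr::local_seed(22)
  for (rep in 1:30) {
    tri <- random_triangle()
    pts <- matrix(stats::runif(15, -2, 2), ncol = 3)
    fr <- planarize(tri, points = pts)
    V2 <- cbind(fr$vertices2d, z = 0)
    for (i in 1:5) {
      for (vx in c("E", "F", "A")) {
        d3 <- sqrt(sum((pts[i, ] - tri[vx, ])^2))
        d2 <- sqrt(sum((fr$points[i, ] - V2[vx, ])^2))
        expect_equal(d2, d3, tolerance = 1e-12)
      }
    }
  }
})

test_that("barycentric coordinates are invariant under joint rigid motion", {
  withr::local_seed(23)
  for (rep in 1:20) {
    tri <- random_triangle()
    pt <- matrix(stats::runif(3, -1, 1), ncol = 3)
    rm_ <- random_rigid_motion()
    tri2 <- build_triangle(rm_$R %*% tri["E", ] + rm_$t,
                           rm_$R %*% tri["F", ] + rm_$t,
                           rm_$R %*% tri["A", ] + rm_$t)
    pt2 <- matrix(as.numeric(rm_$R %*% t(pt)) + rm_$t, ncol = 3)
    f1 <- planarize(tri, pt); f2 <- planarize(tri2, pt2)
    l1 <- barycentric(f1, f1$points[, 1:2, drop = FALSE])
    l2 <- barycentric(f2, f2$points[, 1:2, drop = FALSE])
    expect_equal(l1, l2, tolerance = 1e-9)
    # proportions inherit the invariance
    expect_equal(ancestry_proportions(l1), ancestry_proportions(l2),
                 tolerance = 1e-9)
    # out-of-plane magnitude is also rigid-motion invariant
    expect_equal(abs(f1$points[, 3]), abs(f2$points[, 3]), tolerance = 1e-9)
  }
})

test_that("determinant barycentric matches the frozen worked example", {
  fr <- make_frame2d(c(0, 0), c(2, 0), c(0, 2))
  lam <- barycentric(fr, c(0.5, 0.5))
  expect_equal(unname(lam[1, ]), c(0.5, 0.25, 0.25), tolerance = 1e-12)
})

test_that("vertices and centroid give unit and uniform coordinates", {
  withr::local_seed(24)
  fr <- planarize(random_triangle())
  V <- fr$vertices2d
  expect_equal(unname(barycentric(fr, V["E", ])[1, ]), c(1, 0, 0),
               tolerance = 1e-10)
  expect_equal(unname(barycentric(fr, V["A", ])[1, ]), c(0, 0, 1),
               tolerance = 1e-10)
  expect_equal(unname(barycentric(fr, colMeans(V))[1, ]), rep(1 / 3, 3),
               tolerance = 1e-10)
})

test_that("determinant method agrees with the linear-system oracle", {
  withr::local_seed(25)
  for (rep in 1:200) {
    fr <- planarize(random_triangle())
    q <- stats::runif(2, -3, 3)
    lam <- barycentric(fr, q)
    expect_equal(sum(lam), 1, tolerance = 1e-9)
    expect_equal(unname(lam[1, ]), bary_solve_oracle(fr, q), tolerance = 1e-9)
  }
})

test_that("proportions clamp outside-triangle coordinates", {
  expect_equal(unname(ancestry_proportions(c(1.2, -0.1, -0.1))[1, ]),
               c(1, 0, 0))
  expect_equal(unname(ancestry_proportions(c(1 / 3, 1 / 3, 1 / 3))[1, ]),
               rep(1 / 3, 3))
  expect_equal(unname(ancestry_proportions(c(0.5, 0.6, -0.1))[1, ]),
               c(0.5 / 1.1, 0.6 / 1.1, 0), tolerance = 1e-12)
  expect_error(ancestry_proportions(c(0.5, 0.2, 0.1)), "sum to 1")
  P <- ancestry_proportions(rbind(c(0.7, 0.6, -0.3), c(0.2, 0.3, 0.5)))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-12)
})

test_that("barycentric and its inverse compose to the identity", {
  withr::local_seed(26)
  for (rep in 1:20) {
    fr <- planarize(random_triangle())
    q <- stats::runif(2, -2, 2)
    lam <- barycentric(fr, q)
    expect_equal(unname(barycentric_to_cartesian(lam, fr)[1, ]), q,
                 tolerance = 1e-10)
  }
  fr <- planarize(random_triangle())
  expect_equal(unname(barycentric_to_cartesian(c(1, 0, 0), fr)[1, ]),
               unname(fr$vertices2d["E", ]), tolerance = 1e-12)
})

test_that("coordinates transfer between frames preserves barycentric values", {
  withr::local_seed(27)
  for (rep in 1:20) {
    f_sub <- planarize(random_triangle())   # subject-specific triangle
    f_ref <- planarize(random_triangle())   # differently-sized reference
    q <- stats::runif(2, -1, 2)
    lam <- barycentric(f_sub, q)
    q_ref <- barycentric_to_cartesian(lam, f_ref)
    expect_equal(barycentric(f_ref, q_ref[1, ]), lam, tolerance = 1e-9)
  }
})

test_that("near-degenerate frames are refused for the barycentric solve", {
  tri <- build_triangle(c(0, 1e-9, 0), c(0, 0, 0), c(3, 0, 0))
  fr <- planarize(tri)
  expect_error(barycentric(fr, c(1, 0)), "unstable")
})
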