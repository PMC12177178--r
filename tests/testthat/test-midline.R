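test_that("fit_plane recovers coordinate planes from three points", {
  fr <- fit_plane(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(fr$normal, c(1, 0, 0))
  expect_equal(fr$offset, 0)

  fr2 <- fit_plane(c(2, 0, 0), c(2, 5, 0), c(2, 0, 7))
  expect_equal(fr2$normal, c(1, 0, 0))
  expect_equal(fr2$offset, -2)

  # All three defining points lie on the plane to < 1e-6 um.
  for (p in list(c(2, 0, 0), c(2, 5, 0), c(2, 0, 7))) {
    expect_lt(abs(signed_distance(fr2, p)), 1e-6)
  }
})

test_that("fit_plane rejects collinear points", {
  expect_error(fit_plane(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), "collinear")
  expect_error(fit_plane(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "collinear")
})

test_that("fit_plane is invariant under permutation of its points", {
  set.seed(41)
  for (rep in 1:10) {
    pts <- matrix(runif(9, -1000, 1000), nrow = 3)
    ref <- fit_plane(pts[1, ], pts[2, ], pts[3, ])
    perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    for (pm in perms) {
      fr <- fit_plane(pts[pm[1], ], pts[pm[2], ], pts[pm[3], ])
      expect_equal(fr$normal, ref$normal, tolerance = 1e-9)
      expect_equal(fr$offset, ref$offset, tolerance = 1e-6)
    }
    expect_equal(sqrt(sum(ref$normal^2)), 1, tolerance = 1e-9)
  }
})

test_that("signed distance is linear, zero on the plane, odd under reflection", {
  fr <- make_frame(mid = 0)
  expect_equal(signed_distance(fr, c(3, 9, 9)), 3)
  expect_equal(signed_distance(fr, c(0, -4, 17)), 0)
  set.seed(7)
  pts <- matrix(runif(30, -500, 500), ncol = 3)
  refl <- pts
  refl[, 1] <- -refl[, 1]
  expect_equal(signed_distance(fr, refl), -signed_distance(fr, pts))
})

test_that("classify_side applies exclusion before hemisphere assignment", {
  fr <- make_frame(mid = 0, w = 150)
  expect_equal(classify_side(fr, c(40, 0, 0)), "excluded")
  expect_equal(classify_side(fr, c(-149.9, 0, 0)), "excluded")
  expect_equal(classify_side(fr, c(150, 0, 0)), "ipsi")  # band is open
  fr0 <- make_frame(mid = 0, w = 0)
  expect_equal(classify_side(fr0, c(40, 0, 0)), "ipsi")
  expect_equal(classify_side(fr0, c(-40, 0, 0)), "contra")
  expect_equal(classify_side(fr0, c(0, 5, -2)), "on_plane")
})

test_that("classify_side requires an injection side", {
  fr <- fit_plane(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(classify_side(fr, c(1, 0, 0)), "injection side")
})

test_that("the four labels partition any point cloud", {
  set.seed(11)
  fr <- make_frame(mid = 100, w = 60)
  pts <- matrix(runif(600, -400, 600), ncol = 3)
  # Force some exact on-plane and in-band points.
  pts[1:5, 1] <- 100
  pts[6:10, 1] <- 130
  cls <- classify_side(fr, pts)
  expect_true(all(cls %in% c("ipsi", "contra", "on_plane", "excluded")))
  expect_length(cls, nrow(pts))
  tab <- table(factor(cls, c("ipsi", "contra", "on_plane", "excluded")))
  expect_equal(sum(tab), nrow(pts))
  # Exclusion precedes the on-plane label: points on the plane inside a
  # nonzero band are excluded, like any other in-band point.
  expect_true(all(cls[1:10] == "excluded"))
})

test_that("reflection across the plane swaps ipsi and contra counts", {
  set.seed(13)
  for (w in c(0, 75)) {
    fr <- make_frame(mid = 250, w = w)
    pts <- matrix(runif(300, -500, 1000), ncol = 3)
    refl <- pts
    refl[, 1] <- 2 * 250 - refl[, 1]
    c1 <- table(factor(classify_side(fr, pts),
                       c("ipsi", "contra", "on_plane", "excluded")))
    c2 <- table(factor(classify_side(fr, refl),
                       c("ipsi", "contra", "on_plane", "excluded")))
    expect_equal(unname(c1[["ipsi"]]), unname(c2[["contra"]]))
    expect_equal(unname(c1[["contra"]]), unname(c2[["ipsi"]]))
    expect_equal(unname(c1[["on_plane"]]), unname(c2[["on_plane"]]))
    expect_equal(unname(c1[["excluded"]]), unname(c2[["excluded"]]))
  }
})
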