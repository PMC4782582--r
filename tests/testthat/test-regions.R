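test_that("disk structuring elements are centered, symmetric true-diameter disks", {
  for (d in c(1, 2, 3, 5, 13)) {
    off <- disk_element(d)$offsets
    expect_true(any(off[, 1] == 0 & off[, 2] == 0))
    # symmetric under negation
    key <- paste(off[, 1], off[, 2]); neg <- paste(-off[, 1], -off[, 2])
    expect_setequal(key, neg)
    expect_true(all(off[, 1]^2 + off[, 2]^2 <= (d / 2)^2))
  }
  expect_identical(nrow(disk_element(1)$offsets), 1L)   # origin only
  expect_identical(nrow(disk_element(3)$offsets), 9L)   # full 3x3
})

test_that("erosion of an empty cluster shrinks the full frame by the disk radius", {
  Sj <- matrix(FALSE, 11, 11)
  M <- erode_inverse(Sj, 3)
  expected <- matrix(FALSE, 11, 11); expected[2:10, 2:10] <- TRUE
  expect_identical(M, expected)

  # a single complement pixel cannot host a d=3 disk
  Sj2 <- matrix(TRUE, 11, 11); Sj2[5, 5] <- FALSE
  expect_true(all(!erode_inverse(Sj2, 3)))
})

test_that("erosion equals the brute-force offset definition on random masks", {
  set.seed(17)
  for (i in 1:12) {
    Sj <- random_mask(32, 32)
    for (d in c(3, 5, 13)) {
      expect_identical(erode_inverse(Sj, d), oracle_erode(!Sj, d))
    }
  }
})

test_that("erosion is anti-extensive, monotone in d, and identity at d = 1", {
  set.seed(23)
  for (i in 1:10) {
    Sj <- random_mask(24, 24, 0.5)
    M3 <- erode_inverse(Sj, 3); M5 <- erode_inverse(Sj, 5)
    M13 <- erode_inverse(Sj, 13)
    expect_true(all(!(M3 & Sj)))          # M subset of complement
    expect_true(all(M5 <= M3))            # monotone: larger d, smaller M
    expect_true(all(M13 <= M5))
    expect_identical(erode_inverse(Sj, 1), !Sj)
  }
})

test_that("oversized structuring elements yield an empty mask with a warning", {
  expect_warning(M <- erode_inverse(matrix(FALSE, 10, 10), 25),
                 class = "empty_erosion_warning")
  expect_true(all(!M))
})

test_that("two-pass labeling matches flood fill on random masks, both connectivities", {
  set.seed(41)
  for (i in 1:50) {
    m <- random_mask(32, 32, runif(1, 0.2, 0.7))
    for (conn in c(4L, 8L)) {
      lab <- label_components(m, conn)
      oracle <- oracle_flood_fill(m, conn)
      # identical components as pixel sets: label maps must agree up to
      # renaming; both use raster order of first pixel so they are equal
      expect_identical(lab$label_map, oracle)
      expect_identical(sum(lab$regions$area), sum(m))
    }
  }
})

test_that("labeling handles empty masks and reports areas/centroids", {
  lab <- label_components(matrix(FALSE, 8, 8))
  expect_identical(nrow(lab$regions), 0L)
  expect_error(pick_reference_region(lab), class = "empty_selection_error")

  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE; m[7:9, 7:9] <- TRUE
  lab2 <- label_components(m)
  expect_identical(lab2$regions$area, c(9L, 9L))
  expect_equal(lab2$regions$centroid_row[1], 2)  # 0-based centroid
})

test_that("reference region selection minimizes nearest-pixel distance to origin", {
  m <- matrix(FALSE, 12, 12)
  m[1:3, 1:3] <- TRUE      # top-left, area 9
  m[9:12, 8:12] <- TRUE    # bottom-right, area 20 (larger)
  lab <- label_components(m)
  expect_identical(pick_reference_region(lab, 2), 1L)

  # single region: that region
  m2 <- matrix(FALSE, 8, 8); m2[4:6, 4:6] <- TRUE
  expect_identical(pick_reference_region(label_components(m2)), 1L)

  # among three regions the smallest min-distance wins
  m3 <- matrix(FALSE, 60, 60)
  m3[40:42, 3:8] <- TRUE     # dist ~ 40
  m3[10:13, 8:12] <- TRUE    # dist ~ 12.2
  m3[50:54, 30:36] <- TRUE   # dist ~ 55+
  lab3 <- label_components(m3)
  ref <- pick_reference_region(lab3, 3)
  px <- which(lab3$label_map == ref, arr.ind = TRUE) - 1
  expect_equal(min(sqrt(px[, 1]^2 + px[, 2]^2)),
               min(sqrt((10:13 - 1)^2 %o% rep(1, 5) +
                        rep(1, 4) %o% (8:12 - 1)^2)))
})

test_that("boundary loops are closed chains of 8-neighbors on boundary pixels", {
  m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
  b <- trace_boundaries(m)$boundaries[[1]]
  expect_identical(nrow(b) - 1L, 16L)            # 5x5 square perimeter
  expect_identical(b[1, ], b[nrow(b), ])

  set.seed(53)
  for (i in 1:15) {
    mm <- random_mask(24, 24, 0.4)
    cs <- trace_boundaries(mm)
    for (b in cs$boundaries) {
      n <- nrow(b)
      expect_identical(b[1, ], b[n, ])           # closed
      if (isTRUE(attr(b, "degenerate"))) next
      steps <- abs(diff(b))
      expect_true(all(pmax(steps[, 1], steps[, 2]) == 1))  # 8-neighbors
      for (q in seq_len(n - 1)) {
        r <- b[q, 1] + 1; c <- b[q, 2] + 1
        expect_true(mm[r, c])
        on_edge <- r == 1 || r == 24 || c == 1 || c == 24
        bg4 <- (r > 1 && !mm[r - 1, c]) || (r < 24 && !mm[r + 1, c]) ||
               (c > 1 && !mm[r, c - 1]) || (c < 24 && !mm[r, c + 1])
        expect_true(on_edge || bg4)              # boundary predicate
      }
    }
  }
})

test_that("single pixels trace to a flagged degenerate loop", {
  m <- matrix(FALSE, 8, 8); m[4, 5] <- TRUE
  b <- trace_boundaries(m)$boundaries[[1]]
  expect_true(attr(b, "degenerate"))
  expect_identical(b[1, ], c(row = 3L, col = 4L))  # 0-based
})
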