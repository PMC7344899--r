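test_that("residue minimum distances honor the minimum-image convention", {
  fr <- labeled_frame(matrix(c(0, 0, 0.5), 1, 3), matrix(c(0, 0, 0), 1, 3),
                      c(10, 10, 10))
  expect_equal(residue_min_distances(fr), 0.5)
  fr2 <- labeled_frame(matrix(c(9.9, 0, 0), 1, 3), matrix(c(0.1, 0, 0), 1, 3),
                       c(10, 10, 10))
  expect_equal(residue_min_distances(fr2), 0.2, tolerance = 1e-12)
})

test_that("minimum distances equal the exhaustive double-loop scan", {
  set.seed(7)
  for (rep in 1:5) {
    fr <- random_frame(5, 50)
    expect_equal(residue_min_distances(fr), brute_min_distances(fr))
  }
})

test_that("labeled frames validate their invariants", {
  expect_error(labeled_frame(matrix(0, 1, 3), matrix(0, 0, 3), c(10, 10, 10)))
  expect_error(labeled_frame(matrix(0, 1, 3), matrix(0, 1, 3), c(10, -1, 10)))
})

test_that("contact matrix is binary with an inclusive 1 nm boundary", {
  near <- labeled_frame(matrix(c(0, 0, 0.5), 1, 3), matrix(0, 1, 3), c(10, 10, 10))
  far <- labeled_frame(matrix(c(0, 0, 1.5), 1, 3), matrix(0, 1, 3), c(10, 10, 10))
  exact <- labeled_frame(matrix(c(0, 0, 1.0), 1, 3), matrix(0, 1, 3), c(10, 10, 10))
  cm <- contact_matrix(list(near, far, exact))
  expect_equal(as.vector(cm$contacts), c(1L, 0L, 1L))
})

test_that("contact entries are non-decreasing in the threshold", {
  set.seed(8)
  frames <- replicate(20, random_frame(10, 30), simplify = FALSE)
  thresholds <- c(0.5, 1, 2, 4)
  cms <- lapply(thresholds, function(th) contact_matrix(frames, threshold = th)$contacts)
  for (i in seq_len(length(thresholds) - 1)) {
    expect_true(all(cms[[i + 1]] >= cms[[i]]))
  }
})

test_that("residue and global contact indices equal their brute-force means", {
  set.seed(9)
  M <- matrix(rbinom(30 * 1000, 1, 0.4), 30, 1000)
  cm <- new_contact_matrix(M, temperature = 310)
  idx <- residue_contact_index(cm)
  expect_equal(idx$index, rowMeans(M))
  expect_equal(idx$residue, 1:30)
  expect_equal(global_contact_index(idx), mean(rowMeans(M)))
  expect_equal(global_contact_index(idx, window = 1:15), mean(rowMeans(M)[1:15]))

  # worked window example: bound first half, unbound second half
  v <- c(rep(1, 15), rep(0, 15))
  expect_equal(global_contact_index(v, window = 1:15), 1)
  expect_equal(global_contact_index(v), 0.5)
  expect_error(global_contact_index(v, window = 10:40))
})

test_that("segment splitting follows the earlier-blocks-take-remainder rule", {
  M <- matrix(1L, 2, 10)
  seg <- convergence_segments(new_contact_matrix(M), n_segments = 3)
  expect_equal(seg$segments$n_frames, c(4L, 3L, 3L))
  expect_equal(seg$sd, 0)

  # 10 frames per segment carrying 2, 5 and 8 contacts -> gci 0.2 / 0.5 / 0.8
  M2 <- matrix(c(rep(1L, 2), rep(0L, 8),
                 rep(1L, 5), rep(0L, 5),
                 rep(1L, 8), rep(0L, 2)), nrow = 1)
  seg2 <- convergence_segments(new_contact_matrix(M2), n_segments = 3)
  expect_equal(seg2$segments$gci, c(0.2, 0.5, 0.8))
  expect_equal(seg2$sd, sqrt(mean((c(0.2, 0.5, 0.8) - 0.5)^2)))
  expect_equal(seg2$sd, 0.244949, tolerance = 1e-6)

  expect_error(convergence_segments(new_contact_matrix(matrix(1L, 1, 2)),
                                    n_segments = 3))
})

test_that("melting curves are sorted by temperature and flat curves have zero spread", {
  mk <- function(temp, p) new_contact_matrix(matrix(as.integer(p), 5, 30),
                                             temperature = temp)
  cms <- list(mk(400, 1), mk(310, 1), mk(350, 1))  # deliberately unsorted
  curve <- melting_curve(cms)
  expect_equal(curve$temperature, c(310, 350, 400))
  expect_equal(curve$gci, rep(1, 3))
  expect_equal(curve$segment_sd, rep(0, 3))
})

test_that("TAGCI averages the windowed index over the ladder", {
  temps <- seq(310, 450, by = 10)
  ones <- purrr::map(temps, function(tt) {
    new_contact_matrix(matrix(1L, 20, 12), temperature = tt)
  })
  expect_equal(tagci(ones, "all-bound")$tagci, 1)

  # per-temperature windowed values 1.00, 0.95, ... decreasing by 0.05
  dec <- purrr::map(seq_along(temps), function(i) {
    frac <- 1 - 0.05 * (i - 1)
    M <- matrix(0L, 15, 100)
    M[, seq_len(round(frac * 100))] <- 1L
    new_contact_matrix(M, temperature = temps[i])
  })
  expect_equal(tagci(dec, "decreasing")$tagci, 0.65, tolerance = 1e-12)
})

test_that("TAGCI window must fit inside the construct", {
  temps <- seq(310, 450, by = 10)
  del211 <- construct_fixtures()$sequence[7]
  n <- nchar(del211)
  expect_equal(n, 20)
  cms <- purrr::map(temps, function(tt) {
    new_contact_matrix(matrix(1L, n, 10), temperature = tt)
  })
  expect_equal(tagci(cms, "Del 2-11", window_len = 15)$tagci, 1)
  expect_error(tagci(cms, "Del 2-11", window_len = 21), "at least 21")
})
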