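test_that("quantize_to_level keeps the top j bits", {
  f <- matrix(c(200, 100, 0, 255), 2, 2)
  expect_equal(quantize_to_level(f, 8, 8), f)                    # identity
  expect_equal(quantize_to_level(f, 8, 1), matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(quantize_to_level(matrix(c(0, 5, 10, 15), 2, 2), 4, 2),
               matrix(c(0, 1, 2, 3), 2, 2))
  expect_error(quantize_to_level(f, 8, 0), "level j")
  expect_error(quantize_to_level(f, 8, 9), "level j")
  expect_error(quantize_to_level(matrix(16, 1, 1), 4, 2), "exceed")
})

test_that("shannon_entropy matches hand values and extremes", {
  expect_equal(shannon_entropy(spectral_histogram(matrix(5, 3, 3), 4, 4)), 0)
  # 2^j equally frequent symbols -> j bits
  f <- matrix(rep(c(0L, 4L, 8L, 12L), 4), 4, 4)
  expect_equal(shannon_entropy(spectral_histogram(f, 4, 2)), 2)
  # counts {3,1} over 4 pixels
  expect_equal(shannon_entropy(c(3, 1)),
               0.75 * log2(4 / 3) + 0.25 * log2(4))
  expect_error(shannon_entropy(numeric(0)), "empty")
})

test_that("count_spectral_boxes counts distinct quantized tuples", {
  expect_equal(count_spectral_boxes(matrix(9, 5, 5), 4, 2), 1)   # constant
  f <- matrix(0:7, 2, 4)
  expect_equal(count_spectral_boxes(f, 3, 2), 4)  # {0,0,1,1,2,2,3,3}
  # exhaustive-enumeration oracle on random 6x6 frames at S = 4
  set.seed(42)
  for (rep in 1:20) {
    g <- random_frame(4, 6, 6)
    for (j in 1:3)
      expect_equal(count_spectral_boxes(g, 4, j), oracle_sbm(g, 4, j))
  }
})

test_that("box counts are monotone in level and bounded", {
  set.seed(7)
  for (rep in 1:50) {
    g <- random_frame(5, 7, 7)
    sbm <- vapply(1:4, function(j) count_spectral_boxes(g, 5, j), numeric(1))
    expect_true(all(diff(sbm) >= 0))
    expect_true(all(sbm >= 1 & sbm <= pmin(2^(1:4), 49)))
  }
})

test_that("levels nest across analysis depths", {
  # depth-8 level j+4 uses the same grid as depth-4 level j
  set.seed(8)
  g <- random_frame(4, 6, 6)
  for (j in 1:3)
    expect_equal(count_spectral_boxes(g, 8, j + 4), count_spectral_boxes(g, 4, j))
})

test_that("possible_boxes follows both conventions", {
  expect_equal(possible_boxes(16, 1, mode = "esr"), 65536)
  expect_equal(possible_boxes(8, 1, 3, mode = "dsr"), 8)
  expect_equal(possible_boxes(4, 3, 2, mode = "dsr"), 64)
  expect_equal(possible_boxes(4, 2, mode = "esr"), 256)
  expect_error(possible_boxes(8, 1, mode = "dsr"), "dsr mode")
})

test_that("sfd_esr matches direct substitution", {
  expect_equal(sfd_esr(matrix(3, 4, 4), 4), 0)        # constant
  # S = 2, both level-1 boxes occupied: log(2)/log(4) = 0.5
  expect_equal(sfd_esr(matrix(c(0, 0, 3, 3), 2, 2), 2), 0.5)
  expect_error(sfd_esr(matrix(0, 2, 2), 1), "S must be >= 2")
})

test_that("sfd_dsr hits its range endpoints", {
  expect_equal(sfd_dsr(matrix(0:15, 4, 4), 4), 1)     # every box occupied
  expect_equal(sfd_dsr(matrix(9, 4, 4), 4), 0)        # constant
  set.seed(9)
  for (rep in 1:30) {
    g <- random_frame(4, 5, 5)
    v <- sfd_dsr(g, 4)
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("entropy_weight normalizes the level histogram entropy", {
  expect_equal(entropy_weight(matrix(6, 3, 3), 4, 2), 0)  # constant
  # uniform over all level-2 boxes -> 1
  f <- matrix(c(0L, 4L, 8L, 12L), 2, 2)
  expect_equal(entropy_weight(f, 4, 2), 1)
  # quantized counts {2,1,1} over 4 pixels: H = 1.5, f_2 = 0.75
  g <- matrix(c(0L, 1L, 4L, 8L), 2, 2)
  expect_equal(entropy_weight(g, 4, 2), 0.75)
  expect_error(entropy_weight(g, 4, 4), "1 <= j <= S - 1")
})

test_that("ew_sfd reduces to sfd_dsr on uniform histograms and never exceeds it", {
  # all level histograms uniform: values 0..15 once each
  f <- matrix(0:15, 4, 4)
  expect_identical(ew_sfd(f, 4), sfd_dsr(f, 4))
  expect_equal(ew_sfd(matrix(5, 4, 4), 4), 0)  # constant: all levels floored
  set.seed(10)
  for (rep in 1:100) {
    g <- random_frame(4, 5, 5)
    expect_lte(ew_sfd(g, 4), sfd_dsr(g, 4) + 1e-12)
    expect_gte(ew_sfd(g, 4), 0)
  }
})

test_that("metrics agree with the brute-force oracle on random frames", {
  set.seed(12)
  for (rep in 1:50) {
    g <- random_frame(4, 8, 8)
    ref <- oracle_metrics(g, 4)
    m <- frame_metrics(g, S = 4)
    expect_equal(m$sfd_esr, ref$sfd_esr, tolerance = 1e-12)
    expect_equal(m$sfd_dsr, ref$sfd_dsr, tolerance = 1e-12)
    expect_equal(m$ew_sfd, ref$ew_sfd, tolerance = 1e-12)
    expect_equal(m$entropy_bits, ref$entropy, tolerance = 1e-12)
  }
})

test_that("all metrics are invariant under pixel permutation", {
  set.seed(13)
  g <- random_frame(5, 6, 6)
  p <- matrix(sample(as.vector(g)), 6, 6)
  for (field in c("entropy_bits", "sfd_esr", "sfd_dsr", "ew_sfd"))
    expect_equal(frame_metrics(p, S = 5)[[field]],
                 frame_metrics(g, S = 5)[[field]])
})

test_that("multi-band frames obey joint bounds and full-occupancy identity", {
  # 2-band frame holding every (v1, v2) pair at S = 2: SFD_DSR = n = 2
  grid <- expand.grid(0:3, 0:3)
  f <- array(0L, c(4, 4, 2))
  f[, , 1] <- matrix(grid[[1]], 4, 4)
  f[, , 2] <- matrix(grid[[2]], 4, 4)
  m <- frame_metrics(f, S = 2)
  expect_equal(m$n, 2L)
  expect_equal(m$sfd_dsr, 2)
  expect_equal(m$entropy_bits, 4)  # S*n bits, uniform joint histogram
  expect_identical(m$ew_sfd, m$sfd_dsr)
  set.seed(14)
  g <- array(sample(0:7, 5 * 5 * 3, replace = TRUE), c(5, 5, 3))
  mg <- frame_metrics(g, S = 3)
  expect_true(mg$entropy_bits <= 3 * 3 + 1e-12)
  expect_true(mg$ew_sfd <= mg$sfd_dsr + 1e-12 && mg$sfd_dsr <= 3 + 1e-12)
})

test_that("box_count_profile reports consistent per-level records", {
  set.seed(15)
  g <- random_frame(4, 6, 6)
  prof <- box_count_profile(g, 4)
  expect_equal(prof$j, 1:3)
  expect_true(all(prof$sbm <= prof$sbt_dsr))
  expect_true(all(prof$sbt_esr == 16))
  expect_true(all(prof$f >= 0 & prof$f <= 1))
  expect_true(all(diff(prof$sbm) >= 0))
})

test_that("zero-pixel exclusion drops only all-zero pixels", {
  f <- matrix(c(0, 0, 3, 3), 2, 2)
  h <- spectral_histogram(f, 2, 2, exclude_zero = TRUE)
  expect_equal(h$total_pixels, 2L)
  expect_equal(shannon_entropy(h), 0)
  expect_error(spectral_histogram(matrix(0, 2, 2), 2, 1, exclude_zero = TRUE),
               "no pixels")
})
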