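# Background subtraction, frame averaging and motion rejection.

test_that("background subtraction is exact elementwise arithmetic", {
  m <- matrix(c(1, 0.2, 0.5, 0), 2, 2, byrow = TRUE)
  b <- matrix(c(0.5, 0, 0.5, 0), 2, 2, byrow = TRUE)
  expect_equal(subtract_background(m, b),
               matrix(c(0.5, 0.2, 0, 0), 2, 2, byrow = TRUE))
  expect_identical(subtract_background(m, matrix(0, 2, 2)), m)
  expect_true(all(subtract_background(m, m) == 0))
  expect_error(subtract_background(m, matrix(0, 3, 3)), "identical shapes")
})

test_that("frame averaging matches the arithmetic mean and reduces noise", {
  f1 <- matrix(1:6 / 6, 2, 3)
  expect_identical(average_frames(list(f1), 1), f1)
  expect_true(all(average_frames(list(f1, -f1)) == 0))
  expect_error(average_frames(list(f1), integer(0)), "empty")

  # variance of the mean of N i.i.d.-noise frames ~ sigma^2 / N
  set.seed(8)
  N <- 100; sigma <- 0.3
  frames <- lapply(seq_len(N), function(i) matrix(rnorm(400, 0, sigma), 20))
  v <- stats::var(as.vector(average_frames(frames)))
  expect_lt(abs(v - sigma^2 / N) / (sigma^2 / N), 0.2)
})

test_that("motion rejection recovers injected shifted frames", {
  set.seed(3)
  base <- matrix(0, 16, 64)
  for (r in 1:16) base[r, ] <- sin(seq(0, 6 * pi, length.out = 64) + r / 3)
  shift10 <- function(m) m[, c(55:64, 1:54)]
  frames <- lapply(1:10, function(i) base + matrix(rnorm(16 * 64, 0, 0.05), 16))
  bad <- c(3L, 7L)
  for (i in bad) frames[[i]] <- shift10(base) + matrix(rnorm(16 * 64, 0, 0.05), 16)

  rep <- motion_reject(frames)
  expect_equal(rep$rejected, bad)
  expect_setequal(rep$kept, setdiff(1:10, bad))
  # averaged equals the arithmetic mean over kept frames (oracle)
  expect_equal(rep$averaged, average_frames(frames, rep$kept))
  # correlation matrix contract
  expect_equal(rep$correlation_matrix, t(rep$correlation_matrix))
  expect_true(all(diag(rep$correlation_matrix) == 1))
  # kept frames are mutually more correlated than rejected ones
  off <- rep$correlation_matrix; diag(off) <- NA
  expect_gt(mean(off[rep$kept, rep$kept], na.rm = TRUE),
            mean(off[rep$rejected, ], na.rm = TRUE))
})

test_that("motion rejection handles degenerate stacks", {
  f <- matrix(runif(64), 8)
  rep <- motion_reject(rep(list(f), 6))
  expect_length(rep$rejected, 0)
  expect_equal(rep$averaged, f)

  expect_error(motion_reject(list(f)), "at least k")
  frames <- c(rep(list(f), 4), list(matrix(0.5, 8, 8)))
  expect_warning(rep2 <- motion_reject(frames), "constant frame")
  expect_true(5 %in% rep2$rejected)
})

test_that("motion reports serialize to JSON", {
  set.seed(4)
  frames <- lapply(1:5, function(i) matrix(rnorm(100), 10))
  rep <- motion_reject(frames)
  f <- tempfile(fileext = ".json")
  write_motion_report(rep, f)
  j <- jsonlite::read_json(f)
  expect_setequal(unlist(j$kept), rep$kept)
  unlink(f)
})
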