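test_that("rigid fit of a set onto itself is the identity with zero residual", {
  lm <- fixture_landmarks()
  fit <- estimate_rigid(lm, lm)
  expect_equal(fit$transform$matrix, diag(3), tolerance = 1e-12)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$rms_mm, 0, tolerance = 1e-12)
})

test_that("rigid fit recovers a constructed rotation and translation exactly", {
  lm <- fixture_landmarks()
  truth <- rigid_transform(rot_z(10 * pi / 180), c(1, 2, 3))
  fit <- estimate_rigid(lm, apply_transform(truth, lm))
  expect_equal(fit$transform$matrix, truth$matrix, tolerance = 1e-9)
  expect_equal(fit$transform$translation, truth$translation, tolerance = 1e-9)
  expect_lt(fit$rms_mm, 1e-9)
})

test_that("no rigid transform beats the closed-form fit on jittered landmarks", {
  lm <- fixture_landmarks()
  dst_xyz <- as.matrix(lm[, c("x", "y", "z")])
  dst_xyz[1, ] <- dst_xyz[1, ] + c(0.3, 0, 0) / sqrt(1)
  dst <- landmark_set(lm$name, dst_xyz)
  fit <- estimate_rigid(lm, dst)
  expect_gt(fit$rms_mm, 0)
  src_xyz <- as.matrix(lm[, c("x", "y", "z")])
  rms_of <- function(tr) {
    res <- apply_transform(tr, src_xyz) - dst_xyz
    sqrt(mean(rowSums(res^2)))
  }
  withr::with_seed(11L, {
    random_rms <- replicate(1000, rms_of(random_rigid(180, 5)))
  })
  expect_true(all(random_rms >= fit$rms_mm - 1e-12))
})

test_that("closed-form rigid fit matches brute-force search over a rotation grid", {
  lm <- fixture_landmarks()
  src <- as.matrix(lm[, c("x", "y", "z")])
  withr::with_seed(21L, {
    truth <- random_rigid(25, 3)
    dst <- apply_transform(truth, src) + matrix(rnorm(18, sd = 0.1), ncol = 3)
  })
  fit <- estimate_rigid(lm, landmark_set(lm$name, dst))
  # brute force: for each rotation on an Euler grid, the optimal translation
  # aligns the centroids; compare achieved RMS
  step <- 4 * pi / 180
  ang <- seq(-30, 30, by = 4) * pi / 180
  cs <- colMeans(src); cd <- colMeans(dst)
  best <- Inf
  rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  for (a1 in ang) for (a2 in ang) for (a3 in ang) {
    R <- rot_z(a3) %*% ry(a2) %*% rx(a1)
    res <- sweep(src, 2, cs) %*% t(R) - sweep(dst, 2, cd)
    best <- min(best, sqrt(mean(rowSums(res^2))))
  }
  expect_lte(fit$rms_mm, best + 1e-12)
  # grid best must come within the resolution-limited neighbourhood
  expect_lt(best - fit$rms_mm, max(abs(src)) * step)
})

test_that("rigid fit round trip composes to the identity and rms is motion-invariant", {
  lm <- fixture_landmarks()
  withr::with_seed(31L, {
    for (i in 1:5) {
      jit <- matrix(rnorm(18, sd = 0.2), ncol = 3)
      dst <- landmark_set(lm$name, as.matrix(lm[, c("x", "y", "z")]) + jit)
      ab <- estimate_rigid(lm, dst)$transform
      ba <- estimate_rigid(dst, lm)$transform
      expect_equal(as_matrix4(compose_transforms(ab, ba)), diag(4),
                   tolerance = 1e-6)
      # moving both sets by one common rigid motion leaves the residual alone
      mv <- random_rigid(40, 10)
      fit1 <- estimate_rigid(lm, dst)
      fit2 <- estimate_rigid(apply_transform(mv, lm), apply_transform(mv, dst))
      expect_equal(fit1$rms_mm, fit2$rms_mm, tolerance = 1e-9)
    }
  })
})

test_that("recovered-transform landmark error scales with the jitter level", {
  lm <- fixture_landmarks()
  src <- as.matrix(lm[, c("x", "y", "z")])
  err_at <- function(sigma, seed) {
    withr::with_seed(seed, {
      mean(replicate(30, {
        truth <- random_rigid(10, 1)
        dst <- apply_transform(truth, src) +
          matrix(rnorm(18, sd = sigma), ncol = 3)
        fit <- estimate_rigid(lm, landmark_set(lm$name, dst))
        rec <- apply_transform(fit$transform, src)
        tru <- apply_transform(truth, src)
        sqrt(mean(rowSums((rec - tru)^2)))
      }))
    })
  }
  e1 <- err_at(0.02, 41L); e2 <- err_at(0.2, 42L)
  expect_gt(e2 / e1, 5)     # ~linear in sigma (10x), allow sampling slack
})

test_that("degenerate and mismatched landmark inputs are rejected", {
  lm <- fixture_landmarks()
  line <- landmark_set(letters[1:4], cbind(1:4, 2 * (1:4), 3 * (1:4)))
  expect_error(estimate_rigid(line, line), "degenerate")
  other <- landmark_set(c(lm$name[-1], "nose"), as.matrix(lm[, c("x", "y", "z")]))
  expect_error(estimate_rigid(lm, other), "names differ")
})

test_that("affine fit recovers pure scaling exactly and rejects rank-deficient sets", {
  lm <- fixture_landmarks()
  scaled <- landmark_set(lm$name, 1.2 * as.matrix(lm[, c("x", "y", "z")]))
  fit <- estimate_affine(lm, scaled)
  expect_equal(fit$transform$matrix, 1.2 * diag(3), tolerance = 1e-9)
  expect_lt(fit$rms_mm, 1e-9)
  idf <- estimate_affine(lm, lm)
  expect_equal(as_matrix4(idf$transform), diag(4), tolerance = 1e-9)
  expect_error(estimate_affine(landmark_set(letters[1:3], diag(3)),
                               landmark_set(letters[1:3], diag(3))),
               "at least 4")
  flat <- landmark_set(letters[1:5],
                       cbind(c(0, 1, 0, 1, 2), c(0, 0, 1, 1, 2), 0))
  expect_error(estimate_affine(flat, flat), "coplanar")
})

test_that("transforms survive a JSON round trip", {
  tr <- maybe_with_seed(5L, random_rigid(20, 4))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform_json(tr, f)
  tr2 <- read_transform_json(f)
  expect_s3_class(tr2, "rigid_transform")
  expect_equal(as_matrix4(tr2), as_matrix4(tr), tolerance = 1e-12)
})
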