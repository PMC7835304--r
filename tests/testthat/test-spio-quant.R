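test_that("brain extraction recovers the phantom brain and keeps only the largest blob", {
  atl <- small_atlas()
  g <- generate_spio_mri(atl, c(cerebellum = 10), seed = 3)
  mask <- extract_brain(g$mri)
  truth <- atl$labels$data > 0
  dice <- 2 * sum(mask$data > 0 & truth) / (sum(mask$data > 0) + sum(truth))
  expect_gt(dice, 0.95)
  expect_error(extract_brain(volume3d(array(0, c(8, 8, 8)))), "empty foreground")
  # two blobs, one much larger: only the large one survives
  x <- array(0, c(24, 24, 24))
  x[4:18, 4:18, 4:18] <- 100        # large
  x[21:22, 21:22, 21:22] <- 100     # small
  m <- extract_brain(volume3d(x))
  expect_true(all(m$data[21:22, 21:22, 21:22] == 0))
  expect_true(all(m$data[5:17, 5:17, 5:17] == 1))
})

test_that("bias correction recovers a known second-order field", {
  atl <- small_atlas()
  g <- generate_spio_mri(atl, c(cerebellum = 0), bias_amplitude = 0.2,
                         noise_sd = 0, seed = 4)
  brain <- atl$labels$data > 0
  bc <- correct_bias(g$mri, brain)
  vals <- bc$corrected$data[brain]
  expect_lt(stats::sd(vals) / mean(vals), 0.02)       # within-mask CV < 2%
  expect_gt(stats::cor(bc$bias_field$data[brain],
                       g$truth$true_bias_field$data[brain]), 0.99)
})

test_that("bias correction is a near no-op on flat-field input and idempotent", {
  atl <- small_atlas()
  g <- generate_spio_mri(atl, c(cerebellum = 0), bias_amplitude = 0,
                         noise_sd = 0, seed = 5)
  brain <- atl$labels$data > 0
  bc <- correct_bias(g$mri, brain)
  expect_lt(max(abs(bc$corrected$data[brain] - g$mri$data[brain])), 1e-6)
  expect_lt(max(abs(bc$bias_field$data - 1)), 1e-6)
  # idempotence on a biased noisy image: second pass changes < 0.5% RMS
  g2 <- generate_spio_mri(atl, c(cerebellum = 10), bias_amplitude = 0.2,
                          noise_sd = 0.05, seed = 6)
  b1 <- correct_bias(g2$mri, brain)
  b2 <- correct_bias(b1$corrected, brain)
  rel <- sqrt(mean((b2$corrected$data[brain] - b1$corrected$data[brain])^2)) /
    mean(b1$corrected$data[brain])
  expect_lt(rel, 0.005)
  neg <- g2$mri; neg$data[which(brain)[1]] <- -1
  expect_error(correct_bias(neg, brain), "non-positive")
})

test_that("histogram thresholding finds punctate hypointensities with high sensitivity", {
  # constructed scene: tissue N(100, 5), lesions at 30 (contrast 0.7)
  withr::with_seed(7L, {
    d <- c(48, 48, 48)
    x <- array(rnorm(prod(d), 100, 5), d)
    mask <- array(TRUE, d)
    truth <- array(FALSE, d)
    ctr <- matrix(sample(5:44, 60, replace = TRUE), ncol = 3)
    for (i in seq_len(nrow(ctr)))
      truth[ctr[i, 1] + (-1:1), ctr[i, 2] + (-1:1), ctr[i, 3] + (-1:1)] <- TRUE
    x[truth] <- rnorm(sum(truth), 30, 5)
  })
  lab <- label_spio(volume3d(x), mask)
  det <- lab$labels$data > 0
  expect_gt(sum(det & truth) / sum(truth), 0.99)
  expect_lt(sum(det & !truth) / sum(!truth), 0.001)
  expect_lt(lab$threshold_used, lab$mu_tissue)
})

test_that("labelled fraction under the null stays below the Gaussian tail bound", {
  withr::with_seed(8L, {
    x <- array(rnorm(64^3, 100, 5), c(64, 64, 64))
  })
  mask <- array(TRUE, dim(x))
  lab <- label_spio(volume3d(x), mask)
  expect_lt(mean(lab$labels$data > 0), 0.0015)
  # k -> infinity labels nothing
  lab_inf <- label_spio(volume3d(x), mask, k = 50)
  expect_equal(sum(lab_inf$labels$data), 0)
  expect_error(label_spio(volume3d(array(1, c(6, 6, 6))), array(TRUE, c(6, 6, 6))),
               "degenerate")
})

test_that("labelling is invariant to global intensity scaling", {
  withr::with_seed(9L, {
    x <- array(rnorm(32^3, 100, 5), c(32, 32, 32))
    x[10:12, 10:12, 10:12] <- 30
  })
  mask <- array(TRUE, dim(x))
  l1 <- label_spio(volume3d(x), mask)
  l2 <- label_spio(volume3d(x * 3.7), mask)
  expect_identical(l1$labels$data, l2$labels$data)
  expect_equal(l2$threshold_used, 3.7 * l1$threshold_used, tolerance = 1e-9)
})

test_that("fractional volumes follow the counting definition and are monotone", {
  atl <- small_atlas()
  d <- dim(atl$labels)
  m <- region_mask(atl, "thalamus")
  lab <- array(FALSE, d)
  idx <- which(m)
  lab[idx[seq_len(round(0.1 * length(idx)))]] <- TRUE
  frac <- spio_fractional_volume(lab, atl, "thalamus")
  expect_equal(frac, 100 * round(0.1 * length(idx)) / length(idx),
               tolerance = 1e-12)
  expect_equal(spio_fractional_volume(array(FALSE, d), atl, "thalamus"), 0)
  # adding labelled voxels never decreases any fraction
  lab2 <- lab; lab2[idx[length(idx)]] <- TRUE
  for (r in region_names(atl))
    expect_gte(spio_fractional_volume(lab2, atl, r),
               spio_fractional_volume(lab, atl, r))
})

test_that("labelled voxels are conserved across region accounting", {
  atl <- small_atlas()
  withr::with_seed(10L, {
    lab <- array(runif(prod(dim(atl$labels))) < 0.01, dim(atl$labels))
  })
  per_region <- vapply(region_names(atl), function(r) {
    m <- region_mask(atl, r)
    sum(lab & m)
  }, 0)
  outside <- sum(lab & atl$labels$data == 0)
  expect_equal(sum(per_region) + outside, sum(lab))
})

test_that("connected components and hole filling behave on known shapes", {
  x <- array(FALSE, c(10, 10, 10))
  x[2:4, 2:4, 2:4] <- TRUE
  x[7:9, 7:9, 7:9] <- TRUE
  cc <- label_components(x)
  expect_equal(max(cc), 2)
  expect_equal(sum(cc > 0), 54)
  shell <- array(FALSE, c(10, 10, 10))
  shell[3:7, 3:7, 3:7] <- TRUE
  shell[4:6, 4:6, 4:6] <- FALSE       # enclosed cavity
  filled <- petspio:::fill_holes(shell)
  expect_true(all(filled[4:6, 4:6, 4:6]))
  expect_equal(sum(filled), 125)
})
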