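test_that("atlas contains exactly the six regions plus background, deterministically", {
  atl <- default_atlas()
  expect_setequal(unique(as.vector(atl$labels$data)), 0:6)
  atl2 <- generate_atlas()
  expect_identical(atl$labels$data, atl2$labels$data)
  expect_identical(as.data.frame(atl$landmarks), as.data.frame(atl2$landmarks))
  expect_error(generate_atlas(c(8, 8, 8)), "too small")
})

test_that("atlas landmarks lie outside the brain label", {
  atl <- default_atlas()
  vox <- round(world_to_voxel(atl$labels, as.matrix(atl$landmarks[, c("x", "y", "z")])))
  expect_true(all(atl$labels$data[vox] == 0))
})

test_that("noiseless PSF-free PET frames reproduce the uptake profile exactly", {
  atl <- small_atlas()
  g <- generate_pet(atl, eae_profile, psf_fwhm_mm = 0, noise_sd = 0, seed = 1)
  fr <- volume3d(g$pet$frames[, , , 1], affine = g$pet$affine)
  cer <- voi_mean(fr, atl, "cerebellum")
  neo <- voi_mean(fr, atl, "neocortex")
  expect_equal(cer / neo, 2.4, tolerance = 1e-12)
  # within-brain uniformity for an all-ones profile
  u <- generate_pet(atl, setNames(rep(1, 6), names(eae_profile)),
                    psf_fwhm_mm = 0, noise_sd = 0, seed = 1)
  vals <- u$pet$frames[, , , 1][atl$labels$data > 0]
  expect_equal(diff(range(vals)), 0, tolerance = 1e-12)
})

test_that("PET generation is reproducible for a fixed seed and varies across seeds", {
  atl <- small_atlas()
  a <- generate_pet(atl, eae_profile, seed = 7)
  b <- generate_pet(atl, eae_profile, seed = 7)
  c <- generate_pet(atl, eae_profile, seed = 8)
  expect_identical(a$pet$frames, b$pet$frames)
  expect_false(identical(a$pet$frames, c$pet$frames))
  expect_error(generate_pet(atl, eae_profile[-2], seed = 1), "missing region")
  bad <- eae_profile; bad["neocortex"] <- 1.1
  expect_error(generate_pet(atl, bad, seed = 1), "ratio 1")
})

test_that("recorded lesion fractions equal exact mask recomputation and honour the request", {
  atl <- small_atlas()
  g <- generate_spio_mri(atl, c(cerebellum = 14.5), seed = 7)
  m <- region_mask(atl, "cerebellum")
  recomputed <- 100 * sum(g$truth$true_lesion_mask$data > 0 & m) / sum(m)
  expect_identical(g$truth$true_lesion_fraction[["cerebellum"]], recomputed)
  expect_lt(abs(g$truth$true_lesion_fraction[["cerebellum"]] - 14.5), 0.5)
  # all lesion voxels lie inside their region
  expect_true(all(m[g$truth$true_lesion_mask$data > 0]))
})

test_that("a lesion-free noise-free unbiased phantom is constant inside the brain", {
  atl <- small_atlas()
  g <- generate_spio_mri(atl, c(cerebellum = 0), bias_amplitude = 0,
                         noise_sd = 0, seed = 1)
  vals <- g$mri$data[atl$labels$data > 0]   # identity misalignment: same grid
  expect_equal(diff(range(vals)), 0, tolerance = 1e-12)
  expect_true(all(g$truth$true_bias_field$data == 1))
})

test_that("identity misalignment leaves landmark coordinates identical across modalities", {
  atl <- small_atlas()
  g <- generate_spio_mri(atl, c(cerebellum = 5), seed = 2)
  expect_equal(as.data.frame(g$landmarks_mri), as.data.frame(atl$landmarks),
               tolerance = 1e-12)
})

test_that("bias field is strictly positive with mean 1 and the requested peak deviation", {
  atl <- small_atlas()
  g <- generate_spio_mri(atl, c(cerebellum = 5), bias_amplitude = 0.2,
                         noise_sd = 0, seed = 5)
  f <- g$truth$true_bias_field$data
  brain <- atl$labels$data > 0
  expect_true(all(f > 0))
  expect_equal(mean(f[brain]), 1, tolerance = 1e-12)
  expect_equal(max(abs(f[brain] - 1)), 0.2, tolerance = 0.25)
})

test_that("cohort has the requested composition and a monotone severity structure", {
  ch <- generate_cohort(7, 5, images = FALSE, seed = 3)
  expect_length(ch$animals, 12)
  expect_equal(sum(ch$cohort$group == "EAE"), 7)
  expect_true(all(ch$cohort$cs %in% seq(0, 4, by = 0.5)))
  expect_true(all(ch$cohort$cs[ch$cohort$group == "CTR"] == 0))
  expect_error(generate_cohort(1, 5), "at least 2")
  # strictly monotone (unquantised) link: CS rank order == burden rank order
  ch2 <- generate_cohort(8, 2, images = FALSE, seed = 4,
                         cs_link = function(b) b / 10)
  eae <- Filter(function(a) a$record$group == "EAE", ch2$animals)
  burden <- vapply(eae, function(a) mean(a$truth$true_spio), 0)
  cs <- vapply(eae, function(a) a$record$cs, 0)
  expect_equal(order(cs), order(burden))
})

test_that("a constant clinical-score link yields no CS variance to correlate", {
  ch <- generate_cohort(5, 2, images = FALSE, seed = 6,
                        cs_link = function(b) 2)
  eae_cs <- ch$cohort$cs[ch$cohort$group == "EAE"]
  expect_true(all(eae_cs == 2))
  r <- spearman_rank(c(eae_cs, 2, 2), c(1, 2, 3, 4, 5, 6, 7))
  expect_true(r$flagged)
})

test_that("fluorescence generator hits the requested double-positive fraction", {
  g1 <- generate_fluorescence(n_cells = 40, frac_double = 1, seed = 1)
  expect_true(all(g1$cells$positive_a & g1$cells$positive_b))
  g0 <- generate_fluorescence(n_cells = 40, frac_double = 0, seed = 1)
  expect_true(!any(g0$cells$positive_a & g0$cells$positive_b))
  g <- generate_fluorescence(n_cells = 50, frac_double = 0.4, seed = 9)
  pct <- 100 * mean(g$cells$positive_a & g$cells$positive_b)
  expect_lt(abs(pct - 40), 5)
  expect_error(generate_fluorescence(frac_double = 1.4), "frac_double")
})
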