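# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

default_atlas <- function() {
  if (is.null(.fixtures$atlas)) .fixtures$atlas <- generate_atlas()
  .fixtures$atlas
}

small_atlas <- function() {
  if (is.null(.fixtures$small_atlas))
    .fixtures$small_atlas <- generate_atlas(c(48, 48, 48), 0.25)
  .fixtures$small_atlas
}

eae_profile <- c(neocortex = 1, caudate_putamen = 1.2, hippocampus = 1.6,
                 thalamus = 1.5, cerebellum = 2.4, brainstem = 2.0)

eae_lesions <- c(caudate_putamen = 5.4, hippocampus = 5.7, thalamus = 7.3,
                 cerebellum = 14.5, brainstem = 9.0, neocortex = 0.5)

# six well-spread non-coplanar fiducials (mm)
fixture_landmarks <- function() {
  landmark_set(
    c("eye_L", "eye_R", "condyle_L", "condyle_R", "cochlea_L", "cochlea_R"),
    rbind(c(-2.5, 6.5, 0.7), c(2.5, 6.5, 0.7),
          c(-5.3, 2.4, -4.2), c(5.3, 2.4, -4.2),
          c(-3.7, -6.0, -1.2), c(3.7, -6.0, -1.2)))
}

# independent Mann-Whitney oracle: exact two-sided p by full enumeration of
# all rank partitions (doubled one-sided tail, capped at 1)
mw_enumeration_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  ranks <- rank(pool)
  idx <- utils::combn(length(pool), n)
  u_all <- apply(idx, 2, function(i) sum(ranks[i]) - n * (n + 1) / 2)
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  pl <- mean(u_all <= u_obs)
  pg <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pg))
}
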