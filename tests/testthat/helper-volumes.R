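# small volume builders shared across tests

vol3d <- function(values, dim = NULL) {
  if (is.null(dim)) dim <- c(length(values), 1, 1)
  array(values, dim = dim)
}

random_volume <- function(dim = c(4, 5, 6), lo = 1, hi = 255) {
  array(runif(prod(dim), lo, hi), dim = dim)
}

# tiny fast phantom spec for tests
test_spec <- function(shape = c(12, 24, 24), noise_sigma = 0, ...) {
  phantom_spec(shape = shape, n_cases = 1, noise_sigma = noise_sigma,
               affine_tilt_deg = 0, ...)
}

# "well-separated" phantom: every tumor class brighter than brain tissue in
# every channel, and a tumor large enough that the pooled mean intensity
# falls between brain and tumor levels -- so FD2 + a 0.5 cut recovers WT
separable_contrasts <- function() {
  m <- rbind(
    T1    = c(0, 100, 170, 180, 200),
    T1CE  = c(0, 100, 160, 170, 220),
    T2    = c(0, 100, 180, 190, 170),
    FLAIR = c(0, 100, 200, 170, 180))
  colnames(m) <- c("background", "brain", "edema", "necrotic", "enhancing")
  m
}

separable_spec <- function(noise_sigma = 0, seed = 1, n_cases = 1,
                           shape = c(12, 24, 24), ...) {
  phantom_spec(shape = shape, n_cases = n_cases,
               brain_radius_frac = 0.8, wt_radius_frac = 0.5,
               tc_radius_frac = 0.35, et_radius_frac = 0.2,
               modality_contrasts = separable_contrasts(),
               noise_sigma = noise_sigma, affine_tilt_deg = 0,
               seed = seed, ...)
}
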