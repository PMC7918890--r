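#' Default modality contrast table for the tumor phantom
#'
#' Mean intensities (arbitrary units on a uint8-like 0-255 scale) per
#' modality channel and tissue class. The pattern mimics the qualitative
#' contrast of real multimodal brain MRI: the FLAIR-like channel brightens
#' peritumoral edema, the contrast-enhanced T1 channel brightens the
#' enhancing tumor, T2 brightens fluid-rich tissue.
#'
#' @return A 4x5 numeric matrix, rows `T1`, `T1CE`, `T2`, `FLAIR`; columns
#'   `background`, `brain`, `edema`, `necrotic`, `enhancing`.
#' @export
default_contrasts <- function() {
  m <- rbind(
    T1    = c(0, 120,  90,  60, 110),
    T1CE  = c(0, 120,  90,  60, 220),
    T2    = c(0,  90, 160, 180, 140),
    FLAIR = c(0,  90, 200, 120, 140))
  colnames(m) <- c("background", "brain", "edema", "necrotic", "enhancing")
  m
}

# fixed in-plane anisotropy of the ellipsoids (third-axis semi-axis
# multiplier); non-spherical in-plane shape makes the affine tilt visible
PHANTOM_ANISOTROPY <- 0.75

#' Specification of a synthetic multimodal tumor phantom
#'
#' Describes a skull-stripped-like brain volume containing nested ellipsoidal
#' tumor compartments: an enhancing core (code 4) inside a necrotic/
#' non-enhancing shell (code 1) inside peritumoral edema (code 2), all inside
#' healthy brain tissue, with an exact-zero background outside the brain.
#' Radius fractions are relative to the half-extent of each axis and must
#' nest strictly: `et < tc < wt < brain`.
#'
#' @param shape integer vector `(depth, height, width)`.
#' @param n_cases number of cases in the dataset.
#' @param brain_radius_frac,wt_radius_frac,tc_radius_frac,et_radius_frac
#'   nested radius fractions in (0, 1\].
#' @param modality_contrasts contrast matrix as from [default_contrasts()].
#' @param noise_sigma standard deviation of additive Gaussian noise applied
#'   inside the brain (intensity units; 0 disables noise).
#' @param affine_tilt_deg half-range of the per-case in-plane rotation of the
#'   tumor ellipsoids, in degrees (emulates affine-augmentation inclination).
#' @param seed master seed; each case derives its own reproducible stream
#'   from `(seed, case_index)`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 160, 160), n_cases = 1,
                         brain_radius_frac = 0.85, wt_radius_frac = 0.37,
                         tc_radius_frac = 0.25, et_radius_frac = 0.14,
                         modality_contrasts = default_contrasts(),
                         noise_sigma = 5, affine_tilt_deg = 5, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), all(shape == round(shape)),
            n_cases >= 1, noise_sigma >= 0, affine_tilt_deg >= 0,
            is.matrix(modality_contrasts),
            nrow(modality_contrasts) == 4L, ncol(modality_contrasts) == 5L,
            all(modality_contrasts >= 0))
  r <- c(et_radius_frac, tc_radius_frac, wt_radius_frac, brain_radius_frac)
  if (any(diff(r) <= 0) || any(r <= 0) || any(r > 1))
    stop("radius fractions must satisfy 0 < et < tc < wt < brain <= 1",
         call. = FALSE)
  structure(
    list(shape = as.integer(shape), n_cases = as.integer(n_cases),
         brain_radius_frac = brain_radius_frac,
         wt_radius_frac = wt_radius_frac, tc_radius_frac = tc_radius_frac,
         et_radius_frac = et_radius_frac,
         modality_contrasts = modality_contrasts,
         noise_sigma = noise_sigma, affine_tilt_deg = affine_tilt_deg,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

# per-case RNG stream derived from (seed, case_index); stays below 2^31
case_seed <- function(seed, case_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(case_index) * 7919) %%
               2147483647)
}

#' Generate one phantom case
#'
#' Builds the label volume and the four modality channels of a single case.
#' Tumor compartments are nested ellipsoids (anisotropic in-plane, rotated by
#' a per-case tilt, offset from the brain center), intensities follow the
#' per-class contrast table with additive Gaussian noise inside the brain,
#' and everything outside the brain ellipsoid is exactly 0 (skull-stripped
#' emulation). Fully reproducible from `(spec$seed, case_index)`.
#'
#' @param spec a [phantom_spec].
#' @param case_index 1-based case number within the dataset.
#' @return A list with `case_id`, `channels` (named list of 3D arrays `T1`,
#'   `T1CE`, `T2`, `FLAIR`) and `labels` (3D integer array, codes
#'   \{0, 1, 2, 4\}).
#' @export
generate_case <- function(spec, case_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"),
            case_index >= 1, case_index <= spec$n_cases)
  set.seed(case_seed(spec$seed, case_index))
  d <- spec$shape
  # normalized centered coordinates in [-1, 1] per axis
  ud <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
  uh <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
  uw <- (seq_len(d[3]) - (d[3] + 1) / 2) / (d[3] / 2)
  UD <- array(rep(ud, times = d[2] * d[3]), dim = d)
  UH <- array(rep(rep(uh, each = d[1]), times = d[3]), dim = d)
  UW <- array(rep(uw, each = d[1] * d[2]), dim = d)

  brain <- UD^2 + UH^2 + UW^2 <= spec$brain_radius_frac^2

  # tumor geometry: per-case tilt and center offset, anisotropic in-plane
  theta <- runif(1, -spec$affine_tilt_deg, spec$affine_tilt_deg) * pi / 180
  off <- runif(3, -0.15, 0.15)
  td <- UD - off[1]
  th <- cos(theta) * (UH - off[2]) - sin(theta) * (UW - off[3])
  tw <- (sin(theta) * (UH - off[2]) + cos(theta) * (UW - off[3])) /
    PHANTOM_ANISOTROPY
  r2 <- td^2 + th^2 + tw^2

  labels <- array(0L, dim = d)
  labels[r2 <= spec$wt_radius_frac^2] <- 2L
  labels[r2 <= spec$tc_radius_frac^2] <- 1L
  labels[r2 <= spec$et_radius_frac^2] <- 4L
  labels[!brain] <- 0L

  class_idx <- array(2L, dim = d)           # brain tissue
  class_idx[labels == 2L] <- 3L             # edema
  class_idx[labels == 1L] <- 4L             # necrotic / non-enhancing
  class_idx[labels == 4L] <- 5L             # enhancing
  class_idx[!brain] <- 1L                   # background

  channels <- lapply(rownames(spec$modality_contrasts), function(ch) {
    v <- array(spec$modality_contrasts[ch, ][class_idx], dim = d)
    if (spec$noise_sigma > 0) {
      noise <- array(stats::rnorm(prod(d), 0, spec$noise_sigma), dim = d)
      v[brain] <- pmax(v[brain] + noise[brain], 0)
    }
    v
  })
  names(channels) <- rownames(spec$modality_contrasts)

  list(case_id = sprintf("phantom_%03d", as.integer(case_index)),
       channels = channels, labels = labels)
}

#' Threshold segmenter over the channel maximum
#'
#' A trivial reference predictor standing in for a trained network so the
#' evaluation harness runs end to end on a CPU: a voxel is predicted
#' tumor-positive when the maximum intensity across channels exceeds the
#' threshold. On corrected inputs (values in (0, 1)) a threshold in (0, 1)
#' separates above-mean from below-mean tissue.
#'
#' @param channels a single 3D array or a named list of 3D channel arrays of
#'   common shape.
#' @param threshold scalar cut on the channel-maximum intensity.
#' @return A binary 3D array (1 = predicted tumor).
#' @export
threshold_segmenter <- function(channels, threshold = 0.5) {
  if (is.array(channels)) channels <- list(channels)
  stopifnot(length(channels) >= 1L, is.numeric(threshold),
            length(threshold) == 1L)
  lapply(channels, check_volume)
  for (ch in channels[-1L]) check_same_shape(channels[[1L]], ch)
  vmax <- Reduce(pmax, channels)
  array((vmax > threshold) * 1L, dim = dim(channels[[1L]]))
}
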