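#' Correction parameters for the Fermi-Dirac family
#'
#' Bundles the two pseudo-energy parameters of the Fermi-Dirac (FD)
#' correction family: `epsilon_F`, the pseudo-Fermi energy, assigned to the
#' global mean voxel intensity of a testing set, and `epsilon_b`, the
#' dimensional-balance energy, assigned to *minus* the global standard
#' deviation of intensity (so `epsilon_b <= 0` always).
#'
#' @param epsilon_F global mean intensity (intensity units).
#' @param epsilon_b minus the global standard deviation of intensity; must be
#'   `<= 0`. The FD2, z-score, Bose-Einstein and Maxwell-Boltzmann transforms
#'   additionally require `|epsilon_b| > 0`.
#' @param stats_scope `"dataset"` if the statistics were pooled over a whole
#'   testing set, `"volume"` if computed from a single volume.
#' @param exclude_zeros whether exact-zero voxels (skull-stripped background)
#'   were excluded from the estimation pool.
#' @param n_voxels number of voxels that participated in the estimate
#'   (`NA` when parameters are supplied by hand).
#' @return An object of class `fd_params`.
#' @seealso [estimate_fd_params()], [fd_correct()]
#' @export
fd_params <- function(epsilon_F, epsilon_b, stats_scope = "dataset",
                      exclude_zeros = TRUE, n_voxels = NA_integer_) {
  stopifnot(is.numeric(epsilon_F), length(epsilon_F) == 1L,
            is.numeric(epsilon_b), length(epsilon_b) == 1L)
  if (!is.finite(epsilon_F) || !is.finite(epsilon_b))
    stop("fd_params must be finite", call. = FALSE)
  if (epsilon_b > 0)
    stop("'epsilon_b' is minus a standard deviation and must be <= 0",
         call. = FALSE)
  stats_scope <- match.arg(stats_scope, c("dataset", "volume"))
  structure(
    list(epsilon_F = epsilon_F, epsilon_b = epsilon_b,
         stats_scope = stats_scope, exclude_zeros = isTRUE(exclude_zeros),
         n_voxels = n_voxels),
    class = "fd_params")
}

#' @export
print.fd_params <- function(x, ...) {
  cat("Fermi-Dirac correction parameters\n")
  cat(sprintf("  epsilon_F (mean intensity):  %.6g\n", x$epsilon_F))
  cat(sprintf("  epsilon_b (-std intensity):  %.6g\n", x$epsilon_b))
  cat(sprintf("  scope: %s; zeros excluded: %s; pool size: %s\n",
              x$stats_scope, x$exclude_zeros, format(x$n_voxels)))
  invisible(x)
}

#' Estimate Fermi-Dirac correction parameters from intensity volumes
#'
#' Pools voxel intensities over the given scope and returns
#' `epsilon_F = mean` and `epsilon_b = -population standard deviation` of the
#' pool. Skull-stripped brain volumes carry a large exact-zero background;
#' with `exclude_zeros = TRUE` (default) those voxels do not participate, so
#' the mean reflects brain tissue rather than background.
#'
#' @param volumes a single 3D array, or a list of 3D arrays (e.g. all
#'   modality channels of all cases in a testing set).
#' @param stats_scope `"dataset"` (default) pools all supplied volumes into
#'   one estimate; `"volume"` returns one `fd_params` per volume (a list,
#'   unless a single volume was supplied).
#' @param exclude_zeros drop exact-zero voxels from the pool (default `TRUE`).
#' @return An [fd_params] object (`"dataset"` scope or single volume), or a
#'   list of them (`"volume"` scope with several volumes).
#' @examples
#' v <- array(c(100, 150), dim = c(2, 1, 1))
#' estimate_fd_params(v, exclude_zeros = FALSE)  # epsilon_F 125, epsilon_b -25
#' @export
estimate_fd_params <- function(volumes, stats_scope = c("dataset", "volume"),
                               exclude_zeros = TRUE) {
  stats_scope <- match.arg(stats_scope)
  single <- is.array(volumes)
  if (single) volumes <- list(volumes)
  if (length(volumes) == 0L) stop("at least one volume required", call. = FALSE)
  lapply(volumes, check_volume)

  est_one <- function(pool, scope) {
    if (exclude_zeros) pool <- pool[pool != 0]
    if (length(pool) == 0L) stop("no foreground voxels", call. = FALSE)
    s <- pop_sd(pool)
    if (s == 0) stop("degenerate intensity distribution", call. = FALSE)
    fd_params(mean(pool), -s, stats_scope = scope,
              exclude_zeros = exclude_zeros, n_voxels = length(pool))
  }

  if (stats_scope == "dataset")
    return(est_one(unlist(volumes, use.names = FALSE), "dataset"))
  out <- lapply(volumes, function(v) est_one(as.vector(v), "volume"))
  if (single) out[[1L]] else out
}
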