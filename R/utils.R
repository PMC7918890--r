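#' Round half away from zero at a fixed number of decimals
#'
#' Printed confusion-matrix tables in this field report accuracy to 4 and
#' recall/precision to 2 decimal places with conventional half-up rounding,
#' which differs from [base::round()]'s round-half-even. Isolated here so any
#' comparison against a printed table is explicit about the rounding rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.905, 2)  # 0.91, where round(0.905, 2) gives 0.9
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # 1e-9 guard absorbs binary representation error (e.g. 0.825*100 < 82.5)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# shared validation: a numeric 3D array with all-finite values
check_volume <- function(x, name = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("'%s' must be a 3D array", name), call. = FALSE)
  if (!is.numeric(x))
    stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(x)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(NULL)
}

check_binary <- function(x, name = "mask") {
  if (!all(x %in% c(0, 1)))
    stop(sprintf("'%s' must be binary (values in {0, 1})", name),
         call. = FALSE)
  invisible(x)
}

# population standard deviation (divide by N, not N-1); the correction-energy
# parameter is defined over the whole voxel pool, not a sample from it
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
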