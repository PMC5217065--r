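# Abundance extrapolation from a reference block to the mapped extent of a
# bed: specimens per unit bedding-plane area of the block, scaled to the
# extension area. The ratio is computed exactly, with no rounding.

#' Extrapolate specimen abundance to a bed's mapped extent
#'
#' `extrapolated = count_block / footprint_block_m2 * extension_m2`, exactly.
#'
#' @param count_block Specimens counted in the reference block (>= 0).
#' @param footprint_block_m2 Bedding-plane footprint of the block, m^2 (> 0).
#' @param extension_m2 Mapped extension of the bed, m^2 (> 0).
#' @return Object of class `abundance_estimate` with fields `count_block`,
#'   `footprint_block_m2`, `extension_m2`, `extrapolated`.
#' @export
#' @examples
#' # a 0.150 x 0.140 m block face over a 5 km^2 bed
#' extrapolate_abundance(3253, 0.150 * 0.140, 5e6)
extrapolate_abundance <- function(count_block, footprint_block_m2, extension_m2) {
  stopifnot(count_block >= 0)
  if (!is.finite(footprint_block_m2) || footprint_block_m2 <= 0)
    stop("footprint_block_m2 must be positive")
  if (!is.finite(extension_m2) || extension_m2 <= 0)
    stop("extension_m2 must be positive")
  structure(list(count_block = count_block,
                 footprint_block_m2 = footprint_block_m2,
                 extension_m2 = extension_m2,
                 extrapolated = count_block / footprint_block_m2 * extension_m2),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf(
    "<abundance_estimate> %g specimens / %g m^2 block x %g m^2 extension = %.4g\n",
    x$count_block, x$footprint_block_m2, x$extension_m2, x$extrapolated))
  invisible(x)
}
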