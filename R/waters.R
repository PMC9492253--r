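#' Water molecules between adjacent filter ions
#'
#' In a soft knock-on conduction mechanism, ions inside the selectivity
#' filter stay separated by at least one water molecule. Counting the water
#' oxygens strictly between each adjacent ion pair along the pore axis makes
#' that directly measurable per frame: a count of zero for any pair inside
#' the filter would indicate direct ion-ion contact.
#'
#' @param ions ion axial coordinates (nm), sorted ascending.
#' @param waters water axial coordinates (nm).
#' @param lower_bound,upper_bound axial region considered (nm); only ion
#'   pairs with both ions inside the region are counted.
#' @return integer vector with one count per adjacent ion pair inside the
#'   region (possibly length 0).
#' @examples
#' waters_between_ions(c(0, 0.6), c(0.3), -1, 1)  # 1
#' @export
waters_between_ions <- function(ions, waters, lower_bound = -Inf,
                                upper_bound = Inf) {
  stopifnot(length(ions) >= 1L, all(is.finite(ions)),
            all(is.finite(waters)) || length(waters) == 0L)
  if (is.unsorted(ions, strictly = FALSE))
    stop("ion coordinates must be sorted ascending", call. = FALSE)
  inside <- ions >= lower_bound & ions <= upper_bound
  counts <- integer(0)
  if (length(ions) >= 2L) {
    for (i in seq_len(length(ions) - 1L)) {
      if (!inside[i] || !inside[i + 1L]) next
      counts <- c(counts,
                  sum(waters > ions[i] & waters < ions[i + 1L]))
    }
  }
  counts
}
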