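#' Classify ambulatory ability from three self-reported mobility items
#'
#' Patients reporting the ability to walk 150 feet, walk one block, and climb
#' one flight of stairs are classified as ambulatory; patients able to do none
#' of the three are non-ambulatory. Patients with partial ability (some but
#' not all items) are excluded from the group comparison.
#'
#' @param walk_150ft,walk_one_block,climb_one_flight Logical vectors of equal
#'   length. `NA` in any item propagates to an `NA` classification.
#' @return A factor with levels `ambulatory`, `non_ambulatory`, `excluded`.
#' @examples
#' classify_ambulation(TRUE, TRUE, TRUE)    # ambulatory
#' classify_ambulation(FALSE, FALSE, FALSE) # non_ambulatory
#' classify_ambulation(TRUE, FALSE, TRUE)   # excluded
#' @export
classify_ambulation <- function(walk_150ft, walk_one_block, climb_one_flight) {
  if (!is.logical(walk_150ft) || !is.logical(walk_one_block) ||
      !is.logical(climb_one_flight)) {
    abort("mobility items must be logical")
  }
  n <- length(walk_150ft)
  if (length(walk_one_block) != n || length(climb_one_flight) != n) {
    abort("mobility items must have equal length")
  }
  k <- as.integer(walk_150ft) + as.integer(walk_one_block) +
    as.integer(climb_one_flight)
  out <- ifelse(k == 3L, "ambulatory",
                ifelse(k == 0L, "non_ambulatory", "excluded"))
  factor(out, levels = c("ambulatory", "non_ambulatory", "excluded"))
}
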