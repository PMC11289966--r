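#' Controlled vocabulary of sentinel-node fields
#'
#' The 12 node fields used to classify breast SLNs on SPECT/CT: five axilla
#' level I subfields, axilla levels II and III, internal mammary,
#' supraclavicular, mediastinal, interval and contralateral. All cohort and
#' contingency structures in the package index node fields in this fixed
#' order; no other labels are accepted anywhere.
#'
#' @return Character vector of the 12 node-field labels, in canonical order.
#' @export
node_fields <- function() {
  c("axilla-I-anterior", "axilla-I-central", "axilla-I-lateral",
    "axilla-I-posterior", "axilla-I-interpectoral", "axilla-II",
    "axilla-III", "internal-mammary", "supraclavicular", "mediastinal",
    "interval", "contralateral")
}

#' Clockface breast regions
#'
#' Tumour positions are coded as clockface regions 1-12 (left-breast frame
#' after reflection: 3 = lateral, 6 = inferior, 9 = medial, 12 = superior)
#' plus region 0 for retroareolar tumours (within 1 cm of the nipple).
#'
#' @return Integer vector `0:12`.
#' @export
breast_regions <- function() 0:12

n_regions <- function() 13L

assert_node_fields <- function(labels, context = "node field") {
  bad <- setdiff(unique(labels), node_fields())
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s label(s): %s", context,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(labels)
}

assert_regions <- function(clockface) {
  ok <- is.finite(clockface) & clockface == as.integer(clockface) &
    clockface >= 0 & clockface <= 12
  if (!all(ok)) {
    stop("clockface region must be an integer in 0..12", call. = FALSE)
  }
  invisible(clockface)
}

region_label <- function(r) {
  lab <- as.character(r)
  lab[r == 0] <- "0 (retroareolar)"
  lab[r == 3] <- "3 (lateral)"
  lab[r == 6] <- "6 (inferior)"
  lab[r == 9] <- "9 (medial)"
  lab[r == 12] <- "12 (superior)"
  lab
}
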