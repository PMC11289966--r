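# Reference cohort: 869 tumours from 861 patients imaged with
# lymphoscintigraphy + SPECT/CT, summarised as region totals and per-region
# node-field counts (left-breast frame after reflection).

anmu_field_counts <- function() {
  nf <- node_fields()
  m <- rbind(
    `axilla-I-anterior`      = c(87, 66, 164, 69, 44, 31, 20, 21, 19, 19, 42, 41, 48),
    `axilla-I-central`       = c(37, 19,  59, 29, 18, 11, 10,  5,  7,  6, 16, 14, 22),
    `axilla-I-lateral`       = c( 1,  3,   2,  1,  0,  0,  1,  0,  0,  0,  1,  1,  1),
    `axilla-I-posterior`     = c( 9,  6,  22, 12,  7,  7,  5,  1,  2,  0,  3,  7,  4),
    `axilla-I-interpectoral` = c( 5,  3,   5,  2,  1,  2,  0,  0,  0,  0,  0,  1,  2),
    `axilla-II`              = c(14,  9,  13,  7,  3,  3,  0,  2,  3,  1,  5,  4,  8),
    `axilla-III`             = c( 1,  0,   1,  1,  0,  0,  0,  0,  0,  0,  0,  0,  1),
    `internal-mammary`       = c(37, 19,  28, 14, 16, 16, 16, 17, 15, 11, 28, 29, 18),
    `supraclavicular`        = c( 1,  1,   1,  0,  0,  0,  0,  0,  0,  0,  1,  1,  0),
    `mediastinal`            = c( 1,  0,   0,  0,  0,  0,  1,  0,  0,  1,  0,  1,  0),
    `interval`               = c(13,  4,  16, 11,  4, 10,  5,  4,  1,  1,  3,  6,  5),
    `contralateral`          = c( 1,  0,   0,  0,  0,  0,  0,  0,  0,  0,  1,  0,  0)
  )
  m <- t(m)  # regions x fields
  storage.mode(m) <- "integer"
  dimnames(m) <- list(region = as.character(0:12), node_field = nf)
  m
}

anmu_region_totals <- function() {
  tot <- c(111L, 85L, 199L, 94L, 56L, 41L, 31L, 24L, 23L, 23L, 56L, 60L, 66L)
  names(tot) <- as.character(0:12)
  tot
}

#' Reference SLN contingency table (869 tumours)
#'
#' The published summary of the reference cohort: for each clockface region,
#' the number of tumours and the number draining to each of the 12 node
#' fields, after reflection of right-sided data to the left. 869 tumours
#' from 861 patients (8 bilateral).
#'
#' @return An `sln_contingency`.
#' @export
anmu_contingency <- function() {
  structure(list(field_counts = anmu_field_counts(),
                 region_totals = anmu_region_totals(),
                 N = 869L),
            class = "sln_contingency")
}

#' Reconstructed reference cohort (869 tumour records)
#'
#' Patient-level drainage sets behind the reference contingency table were
#' not published, so this is a deterministic *synthetic reconstruction*:
#' 869 tumour records whose region totals and per-region node-field counts
#' reproduce [anmu_contingency()] exactly. Within each region, field
#' memberships are assigned cyclically (each field's count is laid down
#' starting where the previous field's run ended), which matches every
#' marginal cell and guarantees each record at least one drained field.
#'
#' All single-field statistics (drainage probabilities, tumour prevalence,
#' per-field prevalence) depend only on these marginals, so the
#' reconstruction reproduces them exactly. Joint-drainage statistics (e.g.
#' how often two specific fields co-occur) are *not* determined by the
#' published counts and must not be read off this cohort.
#'
#' The cohort is returned in its raw (unreflected) form: 417 right-sided
#' records carry clockface `12 - h`, 452 left-sided records carry `h`, and
#' 8 patients have bilateral (opposite-side) tumour pairs, so that
#' [preprocess_cohort()] reproduces the published marginals.
#'
#' @return An `sln_cohort` of 869 rows / 861 patients.
#' @export
anmu_cohort <- function() {
  counts <- anmu_field_counts()
  totals <- anmu_region_totals()
  nf <- node_fields()

  regions <- rep(0:12, totals)
  fields <- character(length(regions))
  pos <- 1L
  for (r in 0:12) {
    n_r <- totals[[as.character(r)]]
    member <- matrix(FALSE, n_r, length(nf))
    offset <- 0L
    for (f in seq_along(nf)) {
      cf <- counts[as.character(r), f]
      if (cf > 0L) {
        idx <- ((offset + 0:(cf - 1L)) %% n_r) + 1L
        member[idx, f] <- TRUE
        offset <- (offset + cf) %% n_r
      }
    }
    fields[pos:(pos + n_r - 1L)] <-
      apply(member, 1L, function(m) paste(nf[m], collapse = ";"))
    pos <- pos + n_r
  }

  n <- length(regions)                  # 869
  n_bilateral <- 8L
  n_patients <- n - n_bilateral         # 861
  patient_id <- sprintf("P%04d", c(seq_len(n_patients),
                                   seq_len(n_bilateral)))
  # bilateral partners are the trailing 8 tumours, paired with patients 1..8
  side <- rep("L", n)
  side[(n - n_bilateral + 1L):n] <- "R"
  side[9:417] <- "R"                    # 417 right-sided tumours in total
  # raw clockface: right-sided records are stored pre-reflection
  clockface <- regions
  mid <- side == "R" & regions >= 1L & regions <= 11L
  clockface[mid] <- 12L - regions[mid]
  sex <- rep("F", n)
  sex[patient_id %in% sprintf("P%04d", 857:861)] <- "M"

  sln_cohort(
    patient_id = patient_id,
    side = side,
    clockface = clockface,
    nipple_distance_cm = ifelse(regions == 0L, 0.5, 3.0),
    node_fields = fields,
    sex = sex,
    age_years = 60
  )
}
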