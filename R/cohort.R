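#' Construct a tumour cohort
#'
#' A cohort is a data frame with one row per tumour (the unit of analysis;
#' a patient with bilateral tumours contributes two rows, and the two
#' drainage systems are treated as independent). `node_fields` is a
#' semicolon-separated string of node-field labels from [node_fields()].
#'
#' @param patient_id character; opaque patient identifiers. A patient id may
#'   appear at most twice (bilateral tumours), and then on opposite sides.
#' @param side `"L"` or `"R"`.
#' @param clockface integer 0..12 (0 = retroareolar).
#' @param nipple_distance_cm non-negative tumour-to-nipple distance, cm.
#' @param node_fields semicolon-separated draining node fields per tumour.
#' @param sex `"F"`, `"M"` or `"unknown"`; carried but never used in
#'   estimation.
#' @param age_years optional non-negative age.
#' @return An `sln_cohort` data frame.
#' @export
sln_cohort <- function(patient_id, side, clockface, nipple_distance_cm,
                       node_fields, sex = "F", age_years = NA_real_) {
  df <- data.frame(
    patient_id = as.character(patient_id),
    sex = as.character(sex),
    age_years = as.numeric(age_years),
    side = as.character(side),
    clockface = as.integer(clockface),
    nipple_distance_cm = as.numeric(nipple_distance_cm),
    node_fields = as.character(node_fields),
    stringsAsFactors = FALSE
  )
  validate_cohort(df)
  class(df) <- c("sln_cohort", "data.frame")
  df
}

split_fields <- function(node_fields) {
  lapply(strsplit(node_fields, ";", fixed = TRUE),
         function(x) x[nzchar(trimws(x))])
}

validate_cohort <- function(df, check_sides = TRUE) {
  stopifnot(is.data.frame(df))
  need <- c("patient_id", "side", "clockface", "nipple_distance_cm",
            "node_fields")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (!all(df$side %in% c("L", "R"))) {
    bad <- which(!df$side %in% c("L", "R"))[1]
    stop(sprintf("row %d: side must be 'L' or 'R'", bad), call. = FALSE)
  }
  assert_regions(df$clockface)
  if (any(!is.finite(df$nipple_distance_cm) | df$nipple_distance_cm < 0)) {
    bad <- which(!is.finite(df$nipple_distance_cm) |
                   df$nipple_distance_cm < 0)[1]
    stop(sprintf("row %d: nipple_distance_cm must be finite and >= 0", bad),
         call. = FALSE)
  }
  fl <- split_fields(df$node_fields)
  for (i in seq_along(fl)) {
    bad <- setdiff(fl[[i]], node_fields())
    if (length(bad) > 0L) {
      stop(sprintf("row %d: unknown node field label(s): %s", i,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  tab <- table(df$patient_id)
  if (any(tab > 2L)) {
    stop("a patient_id may appear at most twice (bilateral tumours)",
         call. = FALSE)
  }
  if (check_sides) {
    bil <- names(tab)[tab == 2L]
    for (pid in bil) {
      sides <- df$side[df$patient_id == pid]
      if (sides[1] == sides[2]) {
        stop(sprintf("bilateral patient %s must have tumours on opposite sides",
                     pid), call. = FALSE)
      }
    }
  }
  invisible(df)
}

#' Reclassify tumours close to the nipple as retroareolar
#'
#' Tumours recorded at most 1 cm from the nipple are reassigned to the
#' 0 o'clock (retroareolar) region regardless of their clockface position;
#' the boundary is inclusive.
#'
#' @param cohort an `sln_cohort` (or any data frame with the cohort columns).
#' @param threshold_cm reclassification distance, cm (default 1).
#' @return The cohort with `clockface` set to 0 where
#'   `nipple_distance_cm <= threshold_cm`.
#' @export
reclassify_retroareolar <- function(cohort, threshold_cm = 1.0) {
  if (any(!is.finite(cohort$nipple_distance_cm) |
            cohort$nipple_distance_cm < 0)) {
    stop("nipple_distance_cm must be finite and >= 0", call. = FALSE)
  }
  cohort$clockface[cohort$nipple_distance_cm <= threshold_cm] <- 0L
  cohort
}

#' Reflect right-sided tumours to the left breast frame
#'
#' Drainage probabilities and tumour prevalence are left-right symmetric, so
#' all right-sided data are mirrored into the left-breast frame before
#' analysis: side becomes `"L"` and clockface `h` maps to `12 - h` for
#' `h` in 1..11 (0 and 12 lie on the mirror axis and are unchanged; e.g.
#' right 10 o'clock pairs with left 2 o'clock). Node-field labels are
#' side-agnostic and unchanged. Left-sided rows pass through untouched, so
#' the operation is idempotent.
#'
#' @param cohort an `sln_cohort`.
#' @return The reflected cohort, all rows side `"L"`.
#' @export
reflect_to_left <- function(cohort) {
  if (!all(cohort$side %in% c("L", "R"))) {
    stop("side must be 'L' or 'R'", call. = FALSE)
  }
  r <- cohort$side == "R"
  mid <- cohort$clockface >= 1L & cohort$clockface <= 11L
  cohort$clockface[r & mid] <- 12L - cohort$clockface[r & mid]
  cohort$side[r] <- "L"
  cohort
}

#' Preprocess a raw cohort for analysis
#'
#' Applies, in order: retroareolar reclassification, reflection to the left
#' side, and the enrolment filter (tumours with no drained node fields did
#' not proceed to SPECT/CT and are dropped with a warning).
#'
#' @param cohort raw `sln_cohort`.
#' @return Preprocessed cohort; every row has at least one drained field.
#' @export
preprocess_cohort <- function(cohort) {
  validate_cohort(cohort)
  cohort <- reclassify_retroareolar(cohort)
  cohort <- reflect_to_left(cohort)
  nf <- lengths(split_fields(cohort$node_fields))
  if (any(nf == 0L)) {
    warning(sprintf("dropping %d tumour(s) with no drained node fields",
                    sum(nf == 0L)))
    cohort <- cohort[nf > 0L, , drop = FALSE]
  }
  class(cohort) <- c("sln_cohort", "data.frame")
  cohort
}

#' Build the region-by-node-field contingency table
#'
#' Counts, for each clockface region, the number of tumours located there
#' (`region_totals`) and the number whose drainage includes each node field
#' (`field_counts`). Drainage is multi-label: a tumour draining to three
#' fields increments three cells of its region row but the region total by
#' one, so column sums may exceed the number of tumours.
#'
#' @param cohort a preprocessed cohort (reflected, reclassified, every row
#'   with at least one drained field).
#' @return An `sln_contingency`: list with `field_counts` (13 x 12 integer
#'   matrix, rows clockface 0..12, columns [node_fields()]),
#'   `region_totals` (13-vector) and `N` (total tumours).
#' @export
build_contingency <- function(cohort) {
  validate_cohort(cohort, check_sides = FALSE)
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  fl <- split_fields(cohort$node_fields)
  if (any(lengths(fl) == 0L)) {
    stop("cohort must be preprocessed: every tumour needs >= 1 drained field",
         call. = FALSE)
  }
  nf <- node_fields()
  counts <- matrix(0L, nrow = n_regions(), ncol = length(nf),
                   dimnames = list(region = as.character(0:12),
                                   node_field = nf))
  totals <- integer(n_regions())
  names(totals) <- as.character(0:12)
  for (i in seq_len(nrow(cohort))) {
    r <- cohort$clockface[i] + 1L
    totals[r] <- totals[r] + 1L
    counts[r, unique(fl[[i]])] <- counts[r, unique(fl[[i]])] + 1L
  }
  structure(list(field_counts = counts, region_totals = totals,
                 N = nrow(cohort)),
            class = "sln_contingency")
}

#' @export
print.sln_contingency <- function(x, ...) {
  cat(sprintf("SLN contingency table: %d tumours, 13 regions x 12 node fields\n",
              x$N))
  cat("Node-field totals:\n")
  print(colSums(x$field_counts))
  cat("Region totals:\n")
  print(x$region_totals)
  invisible(x)
}

cohort_columns <- c("patient_id", "sex", "age_years", "side", "clockface",
                    "nipple_distance_cm", "node_fields")

#' Read / write a cohort CSV
#'
#' Schema: columns `patient_id, sex, age_years, side, clockface,
#' nipple_distance_cm, node_fields`; `node_fields` is a semicolon-separated
#' list over the controlled vocabulary. Round trips are lossless.
#'
#' @param path CSV file path.
#' @return `read_cohort_csv` returns an `sln_cohort`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       node_fields = "character"))
  miss <- setdiff(cohort_columns, names(df))
  if (length(miss) > 0L) {
    stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$node_fields[is.na(df$node_fields)] <- ""
  validate_cohort(df)
  class(df) <- c("sln_cohort", "data.frame")
  df
}

#' @rdname read_cohort_csv
#' @param cohort an `sln_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, cohort_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a contingency-table CSV
#'
#' 13 rows (clockface 0..12) with one column per node field plus a
#' `region_total` column.
#'
#' @param path CSV file path.
#' @return `read_contingency_csv` returns an `sln_contingency`.
#' @export
read_contingency_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  nf <- node_fields()
  miss <- setdiff(c("region", nf, "region_total"), names(df))
  if (length(miss) > 0L) {
    stop("contingency CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$region), ]
  counts <- as.matrix(df[, nf])
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(region = as.character(0:12), node_field = nf)
  totals <- as.integer(df$region_total)
  names(totals) <- as.character(0:12)
  if (any(counts > totals)) {
    stop("field count exceeds region total", call. = FALSE)
  }
  structure(list(field_counts = counts, region_totals = totals,
                 N = sum(totals)),
            class = "sln_contingency")
}

#' @rdname read_contingency_csv
#' @param ct an `sln_contingency`.
#' @export
write_contingency_csv <- function(ct, path) {
  df <- data.frame(region = 0:12, ct$field_counts,
                   region_total = as.integer(ct$region_totals),
                   check.names = FALSE)
  names(df) <- c("region", node_fields(), "region_total")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
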