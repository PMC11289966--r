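#' Landmark set constructor
#'
#' A set of named skeletal landmarks annotated by one observer on one
#' subject's CT (typically 13 landmarks). Names must be unique within a
#' set; two sets are comparable through their shared names.
#'
#' @param observer_id,subject_id identifiers.
#' @param name landmark names.
#' @param x,y,z coordinates, mm.
#' @return A `landmark_set` data frame.
#' @export
landmark_set <- function(observer_id, subject_id, name, x, y, z) {
  if (anyDuplicated(name)) {
    stop("landmark names must be unique within a set", call. = FALSE)
  }
  stopifnot(all(is.finite(c(x, y, z))))
  df <- data.frame(observer_id = observer_id, subject_id = subject_id,
                   name = as.character(name), x = x, y = y, z = z,
                   stringsAsFactors = FALSE)
  class(df) <- c("landmark_set", "data.frame")
  df
}

#' Landmark registration error between two point sets
#'
#' Euclidean distances between corresponding (same-named) landmarks of two
#' sets in a common frame, e.g. before vs after registration, or two
#' observers' annotations. Symmetric in its arguments and invariant under a
#' joint rigid transform.
#'
#' @param a,b `landmark_set`s with at least one shared name.
#' @return List with `per_landmark` (name, distance_mm), `mean_mm`, `sd_mm`
#'   (sample SD; `NA` for a single shared landmark) and `n`.
#' @export
landmark_errors <- function(a, b) {
  shared <- intersect(a$name, b$name)
  if (length(shared) == 0L) {
    stop("landmark sets share no names", call. = FALSE)
  }
  pa <- a[match(shared, a$name), c("x", "y", "z")]
  pb <- b[match(shared, b$name), c("x", "y", "z")]
  d <- sqrt(rowSums((pa - pb)^2))
  list(per_landmark = data.frame(name = shared, distance_mm = d,
                                 stringsAsFactors = FALSE),
       mean_mm = mean(d),
       sd_mm = if (length(d) >= 2L) stats::sd(d) else NA_real_,
       n = length(d))
}

#' Pairwise inter-observer annotation variability
#'
#' For each pair of observers, pools the per-landmark distances over all
#' subjects annotated by both and reports mean and SD. Subjects annotated
#' by a single observer are skipped with a warning.
#'
#' @param landmarks data frame with columns `observer_id, subject_id,
#'   landmark_name (or name), x_mm/x, y_mm/y, z_mm/z`.
#' @return Data frame: `observer_a, observer_b, mean_mm, sd_mm, n`.
#' @export
interobserver_summary <- function(landmarks) {
  df <- normalise_landmark_df(landmarks)
  obs <- sort(unique(df$observer_id))
  if (length(obs) < 2L) stop("need >= 2 observers", call. = FALSE)
  singles <- names(Filter(function(x) length(unique(x)) < 2L,
                          split(df$observer_id, df$subject_id)))
  if (length(singles) > 0L) {
    warning("skipping subject(s) annotated by a single observer: ",
            paste(singles, collapse = ", "))
    df <- df[!df$subject_id %in% singles, , drop = FALSE]
  }
  pairs <- utils::combn(obs, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    oa <- pairs[1, j]; ob <- pairs[2, j]
    dists <- c()
    for (s in unique(df$subject_id)) {
      sa <- df[df$subject_id == s & df$observer_id == oa, ]
      sb <- df[df$subject_id == s & df$observer_id == ob, ]
      if (nrow(sa) == 0L || nrow(sb) == 0L) next
      e <- landmark_errors(
        landmark_set(oa, s, sa$name, sa$x, sa$y, sa$z),
        landmark_set(ob, s, sb$name, sb$x, sb$y, sb$z))
      dists <- c(dists, e$per_landmark$distance_mm)
    }
    data.frame(observer_a = oa, observer_b = ob,
               mean_mm = mean(dists),
               sd_mm = if (length(dists) >= 2L) stats::sd(dists) else NA_real_,
               n = length(dists), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

normalise_landmark_df <- function(df) {
  nm <- names(df)
  if ("landmark_name" %in% nm) df$name <- df$landmark_name
  if ("x_mm" %in% nm) { df$x <- df$x_mm; df$y <- df$y_mm; df$z <- df$z_mm }
  need <- c("observer_id", "subject_id", "name", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("landmark table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Select the reference subject by median scapula length
#'
#' Picks the subject whose scapula length equals the sample median (scapula
#' length is a body-height predictor, so this selects an anatomically
#' central reference). For an even number of subjects the lower of the two
#' middle values is used, so a real subject is always selected; ties on
#' length are broken by lexicographic subject id.
#'
#' @param lengths named numeric vector, subject id -> scapula length (mm).
#' @return The selected subject id.
#' @export
select_reference_by_scapula <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length map", call. = FALSE)
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    stop("lengths must be named by subject id", call. = FALSE)
  }
  ord <- order(lengths, names(lengths))
  med_value <- lengths[ord][ceiling(length(lengths) / 2)]
  cand <- sort(names(lengths)[lengths == med_value])
  cand[1]
}

#' Read a landmark CSV
#'
#' Schema: `observer_id, subject_id, landmark_name, x_mm, y_mm, z_mm`.
#'
#' @param path CSV path.
#' @return Data frame suitable for [interobserver_summary()] /
#'   [landmark_errors()].
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  normalise_landmark_df(utils::read.csv(path, stringsAsFactors = FALSE))
}
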