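#' CTV voxel labelmap
#'
#' A clinical target volume stored as a binary 3D voxel array with its
#' physical-space metadata: anisotropic voxel `spacing` (mm), `origin` (mm,
#' physical coordinates of the centre of voxel `[1,1,1]`) and an orthonormal
#' `direction` matrix. Voxel index `(i,j,k)` (1-based) has physical position
#' `origin + direction %*% (spacing * (c(i,j,k) - 1))`. Masks are used in
#' their stored orientation; no reorientation is applied.
#'
#' @param array 3D array, nonzero = foreground.
#' @param spacing length-3 positive voxel spacing, mm.
#' @param origin length-3 origin, mm.
#' @param direction 3x3 orthonormal direction matrix (default identity).
#' @param label CTV name (e.g. `"L1"`, `"INTPECT"`, `"L2"`, `"L3"`, `"L4"`,
#'   `"IMN"`, `"IC4"`).
#' @param side `"L"` or `"R"`.
#' @return A `ctv_mask` object.
#' @export
ctv_mask <- function(array, spacing, origin = c(0, 0, 0),
                     direction = diag(3), label = "CTV", side = "L") {
  stopifnot(length(dim(array)) == 3L, length(spacing) == 3L,
            all(spacing > 0), length(origin) == 3L,
            all(dim(direction) == c(3L, 3L)))
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6) {
    stop("direction matrix must be orthonormal", call. = FALSE)
  }
  if (!side %in% c("L", "R")) stop("side must be 'L' or 'R'", call. = FALSE)
  fg <- array != 0
  if (!any(fg)) warning(sprintf("mask '%s' has empty foreground", label))
  structure(list(array = fg, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = direction,
                 label = label, side = side),
            class = "ctv_mask")
}

# physical (mm) -> 0-based continuous voxel index
phys_to_index <- function(mask, p) {
  # p: 3 x n matrix of points
  d <- t(mask$direction) %*% (p - mask$origin)
  d / mask$spacing
}

index_to_phys <- function(mask, idx0) {
  mask$origin + mask$direction %*% (idx0 * mask$spacing)
}

# nearest-neighbour foreground lookup for a 3 x n matrix of physical points
mask_contains <- function(mask, p) {
  idx <- round(phys_to_index(mask, p)) + 1
  dm <- dim(mask$array)
  ok <- idx[1, ] >= 1 & idx[1, ] <= dm[1] &
    idx[2, ] >= 1 & idx[2, ] <= dm[2] &
    idx[3, ] >= 1 & idx[3, ] <= dm[3]
  out <- logical(ncol(p))
  if (any(ok)) {
    out[ok] <- mask$array[cbind(idx[1, ok], idx[2, ok], idx[3, ok])]
  }
  out
}

#' SLN point set constructor
#'
#' @param x,y,z physical coordinates, mm, in the reference frame of the
#'   masks.
#' @param node_field node-field labels from [node_fields()].
#' @param side `"L"` or `"R"` per point.
#' @param diameter_mm modelled SLN diameter (default 5 mm).
#' @return An `sln_points` data frame.
#' @export
sln_points <- function(x, y, z, node_field, side, diameter_mm = 5.0) {
  stopifnot(all(is.finite(c(x, y, z))), all(diameter_mm > 0))
  assert_node_fields(node_field)
  if (!all(side %in% c("L", "R"))) stop("side must be 'L' or 'R'",
                                        call. = FALSE)
  df <- data.frame(x_mm = x, y_mm = y, z_mm = z,
                   node_field = as.character(node_field),
                   side = as.character(side),
                   diameter_mm = rep_len(diameter_mm, length(x)),
                   stringsAsFactors = FALSE)
  class(df) <- c("sln_points", "data.frame")
  df
}

# fixed generic rotation applied to the sampling lattice so that no lattice
# axis aligns with voxel-grid planes; keeps the plane-crossing error of the
# volume-fraction estimate smooth in the cut position
lattice_rotation <- function() {
  a <- 0.61; b <- 0.43
  rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  ry %*% rx
}

# deterministic symmetric lattice of offsets covering a sphere of diameter d
# centred at 0: points_per_axis^3 cubic candidates, those inside the sphere
# kept, then rotated by the fixed generic rotation (symmetry about the
# centre is preserved, so a centred planar cut still scores one half)
sphere_lattice <- function(diameter_mm, points_per_axis = 20L) {
  o <- ((seq_len(points_per_axis)) - (points_per_axis + 1) / 2) /
    points_per_axis * diameter_mm
  g <- as.matrix(expand.grid(x = o, y = o, z = o))
  keep <- rowSums(g^2) <= (diameter_mm / 2)^2
  lattice_rotation() %*% t(g[keep, , drop = FALSE])
}

#' Fraction of an SLN sphere inside CTV masks
#'
#' Deterministic subvoxel estimate of the volume fraction of a 5 mm sphere
#' (diameter per the point) lying inside the union of the given masks: a
#' fixed symmetric lattice of ~4,200 points inside the sphere is mapped
#' through each mask's physical-to-index transform with nearest-neighbour
#' lookup, and the fraction is the share of lattice points covered by at
#' least one mask. Seed-free and reproducible bit-exactly.
#'
#' @param point one-row `sln_points` (or list with `x_mm,y_mm,z_mm`,
#'   `diameter_mm`).
#' @param masks a `ctv_mask` or list of them.
#' @param points_per_axis lattice refinement (default 20, ~4,200 points).
#' @return Volume fraction in `[0, 1]`.
#' @export
sphere_fraction_inside <- function(point, masks, points_per_axis = 20L) {
  if (inherits(masks, "ctv_mask")) masks <- list(masks)
  if (length(masks) == 0L) return(0)
  lat <- sphere_lattice(point$diameter_mm %||% 5.0, points_per_axis)
  centre <- c(point$x_mm, point$y_mm, point$z_mm)
  pts <- lat + centre
  inside <- rep(FALSE, ncol(pts))
  for (m in masks) {
    if (!any(m$array)) next
    inside <- inside | mask_contains(m, pts)
  }
  mean(inside)
}

#' Covered / not-covered classification
#'
#' An SLN is *inside* a CTV set when strictly more than half of its sphere
#' volume lies within the contours; exactly 50% is not covered.
#'
#' @param fraction volume fraction in `[0, 1]`.
#' @param threshold coverage threshold (default 0.5).
#' @return Logical.
#' @export
classify_covered <- function(fraction, threshold = 0.5) {
  stopifnot(all(fraction >= 0), all(fraction <= 1))
  fraction > threshold
}

# physical coordinates (3 x n) of a mask's foreground voxel centres
mask_foreground_phys <- function(mask) {
  idx <- which(mask$array, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 3, 0))
  mask$origin + mask$direction %*% (t(idx - 1) * mask$spacing)
}

#' Distance from an SLN centroid to the nearest CTV
#'
#' Minimum over masks of the Euclidean distance (mm, honouring anisotropic
#' spacing via physical coordinates) from the centroid to the nearest
#' foreground voxel centre; 0 when the centroid's containing voxel is
#' foreground in any mask. For an outside point the nearest foreground
#' voxel is a boundary voxel, so this is the distance to the CTV boundary
#' at voxel resolution.
#'
#' @param point one-row `sln_points`.
#' @param masks a `ctv_mask` or list of them.
#' @return Distance, mm.
#' @export
centroid_distance_to_ctv <- function(point, masks) {
  if (inherits(masks, "ctv_mask")) masks <- list(masks)
  masks <- Filter(function(m) any(m$array), masks)
  if (length(masks) == 0L) stop("all masks are empty", call. = FALSE)
  centre <- matrix(c(point$x_mm, point$y_mm, point$z_mm), 3, 1)
  best <- Inf
  for (m in masks) {
    if (mask_contains(m, centre)) return(0)
    fg <- mask_foreground_phys(m)
    d2 <- colSums((fg - as.vector(centre))^2)
    best <- min(best, sqrt(min(d2)))
  }
  best
}

#' Node-field to CTV correspondence
#'
#' The standard mapping between SLN node fields and consensus nodal CTVs:
#' the four non-interpectoral axilla level I subfields map to L1, the
#' interpectoral subfield to INTPECT, axilla II/III to L2/L3,
#' supraclavicular to L4, and internal mammary to the internal mammary
#' chain (IMN and IC4). Mediastinal, interval and contralateral node fields
#' have no corresponding CTV and are excluded from coverage scoring.
#'
#' @return Named list: node field -> character vector of CTV labels (may be
#'   empty).
#' @export
default_correspondence <- function() {
  list(
    "axilla-I-anterior" = "L1",
    "axilla-I-central" = "L1",
    "axilla-I-lateral" = "L1",
    "axilla-I-posterior" = "L1",
    "axilla-I-interpectoral" = "INTPECT",
    "axilla-II" = "L2",
    "axilla-III" = "L3",
    "supraclavicular" = "L4",
    "internal-mammary" = c("IMN", "IC4"),
    "mediastinal" = character(0),
    "interval" = character(0),
    "contralateral" = character(0)
  )
}

summarise_coverage_rows <- function(df, node_field, side, scope) {
  n <- nrow(df)
  n_inside <- sum(df$covered)
  out_d <- df$distance_mm[!df$covered]
  data.frame(
    node_field = node_field, side = side, scope = scope,
    n = n, n_inside = n_inside,
    pct_inside = 100 * n_inside / n,
    dist_mean_mm = if (length(out_d) >= 1L) mean(out_d) else NA_real_,
    dist_sd_mm = if (length(out_d) >= 2L) stats::sd(out_d) else NA_real_,
    n_flagged_inside_centroid = sum(!df$covered & df$distance_mm == 0),
    stringsAsFactors = FALSE
  )
}

#' SLN-CTV coverage report
#'
#' Scores every SLN sphere against (a) the CTVs corresponding to its node
#' field and (b) all CTVs on its side, classifies coverage (> 50% volume
#' inside), and summarises per node field, side (`L`, `R` and `both`) and
#' scope: `n`, number and percentage inside, and mean +/- SD distance of
#' non-covered SLN centroids to the nearest CTV. The SD is omitted when
#' exactly one SLN is non-covered and distances are omitted when none is.
#' A non-covered SLN whose centroid nevertheless lies inside a CTV
#' contributes distance 0 and is counted in
#' `n_flagged_inside_centroid`. Node fields with no corresponding CTV
#' (mediastinal, interval, contralateral) are excluded from scoring; their
#' count is reported in the `excluded` attribute.
#'
#' @param points an `sln_points` data frame.
#' @param masks list of `ctv_mask`.
#' @param map correspondence list as [default_correspondence()].
#' @param points_per_axis lattice refinement passed to
#'   [sphere_fraction_inside()].
#' @return Data frame of coverage summaries (one row per node field x side
#'   x scope present, plus `all-SLNs` rows), with an `excluded` attribute.
#' @export
coverage_report <- function(points, masks, map = default_correspondence(),
                            points_per_axis = 20L) {
  assert_node_fields(points$node_field)
  unknown <- setdiff(points$node_field, names(map))
  if (length(unknown) > 0L) {
    stop("node field(s) missing from correspondence map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  excluded <- lengths(map[points$node_field]) == 0L
  scored <- points[!excluded, , drop = FALSE]
  if (nrow(scored) == 0L) {
    out <- data.frame()
    attr(out, "excluded") <- sum(excluded)
    return(out)
  }
  per <- do.call(rbind, lapply(seq_len(nrow(scored)), function(i) {
    p <- scored[i, ]
    side_masks <- Filter(function(m) m$side == p$side, masks)
    corr <- Filter(function(m) m$label %in% map[[p$node_field]], side_masks)
    res <- lapply(list(corresponding = corr, all = side_masks), function(ms) {
      if (length(Filter(function(m) any(m$array), ms)) == 0L) {
        return(data.frame(fraction = 0, covered = FALSE,
                          distance_mm = NA_real_))
      }
      fr <- sphere_fraction_inside(p, ms, points_per_axis)
      cov <- classify_covered(fr)
      data.frame(fraction = fr, covered = cov,
                 distance_mm = if (cov) NA_real_
                               else centroid_distance_to_ctv(p, ms))
    })
    data.frame(node_field = p$node_field, side = p$side,
               scope = c("corresponding", "all"),
               rbind(res$corresponding, res$all),
               stringsAsFactors = FALSE)
  }))
  rows <- list()
  for (scope in c("corresponding", "all")) {
    sub_scope <- per[per$scope == scope, ]
    for (f in unique(sub_scope$node_field)) {
      for (s in c("both", "L", "R")) {
        sub <- sub_scope[sub_scope$node_field == f &
                           (s == "both" | sub_scope$side == s), ]
        if (nrow(sub) == 0L) next
        rows[[length(rows) + 1L]] <-
          summarise_coverage_rows(sub, f, s, scope)
      }
    }
    for (s in c("both", "L", "R")) {
      sub <- sub_scope[s == "both" | sub_scope$side == s, ]
      if (nrow(sub) == 0L) next
      rows[[length(rows) + 1L]] <-
        summarise_coverage_rows(sub, "all-SLNs", s, scope)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- sum(excluded)
  attr(out, "per_sln") <- per
  out
}

#' Read / write CTV masks as NIfTI
#'
#' Masks are stored as NIfTI labelmaps; physical metadata (spacing, origin,
#' direction) is taken from the sform/qform affine and preserved exactly on
#' round trip.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param label,side CTV label and side to attach.
#' @param label_value optional voxel value selecting one label from a
#'   multi-label map; default treats any nonzero voxel as foreground.
#' @return `read_mask` returns a `ctv_mask`.
#' @export
read_mask <- function(path, label = "CTV", side = "L", label_value = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("mask must be a 3D volume", call. = FALSE)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(sp <= 0)) stop("mask has missing or zero spacing", call. = FALSE)
  dir <- sweep(aff[1:3, 1:3], 2, sp, "/")
  fg <- if (is.null(label_value)) arr != 0 else arr == label_value
  ctv_mask(fg, spacing = sp, origin = aff[1:3, 4], direction = dir,
           label = label, side = side)
}

#' @rdname read_mask
#' @param mask a `ctv_mask`.
#' @export
write_mask <- function(mask, path) {
  aff <- rbind(cbind(sweep(mask$direction, 2, mask$spacing, "*"),
                     mask$origin),
               c(0, 0, 0, 1))
  img <- RNifti::asNifti(mask$array + 0L)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write SLN point CSV
#'
#' Schema: `x_mm, y_mm, z_mm, node_field, side` (optional `diameter_mm`,
#' default 5).
#'
#' @param path CSV path.
#' @return `read_points` returns an `sln_points` data frame (empty with a
#'   warning when the file has a header only).
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_mm", "y_mm", "z_mm", "node_field", "side")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("points CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("points file contains a header only; empty point set")
    return(sln_points(numeric(0), numeric(0), numeric(0),
                      character(0), character(0)))
  }
  if (is.null(df$diameter_mm)) df$diameter_mm <- 5.0
  sln_points(df$x_mm, df$y_mm, df$z_mm, df$node_field, df$side,
             df$diameter_mm)
}

#' @rdname read_points
#' @param points an `sln_points` data frame.
#' @export
write_points <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
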