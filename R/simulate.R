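#' Cohort simulation specification
#'
#' Generative counterpart of the analysis models: tumour regions are
#' multinomial over the 13 clockface regions and drainage to each of the 12
#' node fields is an independent region-conditional Bernoulli (multi-label;
#' the published data provide only marginals, so field-wise independence is
#' the default joint structure). Tumours drawing zero drained fields are
#' redrawn, mirroring the enrolment filter (imaging proceeded only when
#' SLNs were seen on lymphoscintigraphy); this induces a small, documented
#' upward bias relative to the matrix entries.
#'
#' Defaults reproduce the reference cohort's observed conditions: 861
#' patients, bilateral rate 8/861, right-side fraction 417/869, region
#' probabilities and drainage matrix equal to the reference contingency
#' proportions.
#'
#' @param n_patients number of patients.
#' @param bilateral_rate probability a patient has bilateral tumours.
#' @param region_probs 13-simplex of region probabilities (clockface 0..12).
#' @param drainage_matrix 13 x 12 matrix of per-field drainage
#'   probabilities, rows = regions, columns = [node_fields()].
#' @param right_fraction probability a (unilateral) tumour is right-sided.
#' @param seed optional integer seed.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_patients = 861L,
                            bilateral_rate = 8 / 861,
                            region_probs = NULL,
                            drainage_matrix = NULL,
                            right_fraction = 417 / 869,
                            seed = NULL) {
  ct <- anmu_contingency()
  if (is.null(region_probs)) {
    region_probs <- as.vector(ct$region_totals) / ct$N
  }
  if (is.null(drainage_matrix)) {
    drainage_matrix <- ct$field_counts / as.vector(ct$region_totals)
  }
  stopifnot(length(region_probs) == n_regions(),
            abs(sum(region_probs) - 1) < 1e-12,
            all(region_probs >= 0),
            all(dim(drainage_matrix) == c(n_regions(), length(node_fields()))),
            all(drainage_matrix >= 0), all(drainage_matrix <= 1),
            n_patients >= 1, bilateral_rate >= 0, bilateral_rate <= 1,
            right_fraction >= 0, right_fraction <= 1)
  if (any(rowSums(drainage_matrix) == 0 & region_probs > 0)) {
    stop("a reachable region has an all-zero drainage row; redraw would not terminate",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 bilateral_rate = bilateral_rate,
                 region_probs = region_probs,
                 drainage_matrix = drainage_matrix,
                 right_fraction = right_fraction, seed = seed),
            class = "cohort_sim_spec")
}

# vectorised multi-label drainage draw with redraw of empty rows
draw_tumours <- function(n, spec) {
  nf <- node_fields()
  regions <- integer(n)
  drained <- matrix(FALSE, n, length(nf))
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    regions[todo] <- sample.int(n_regions(), length(todo), replace = TRUE,
                                prob = spec$region_probs) - 1L
    u <- matrix(stats::runif(length(todo) * length(nf)),
                length(todo), length(nf))
    drained[todo, ] <- u < spec$drainage_matrix[regions[todo] + 1L, ,
                                                drop = FALSE]
    todo <- todo[rowSums(drained[todo, , drop = FALSE]) == 0L]
  }
  fields <- apply(drained, 1L, function(m) paste(nf[m], collapse = ";"))
  list(regions = regions, fields = fields)
}

#' Simulate a raw SLN cohort
#'
#' Draws patients (side, bilaterality) and tumours (region, multi-label
#' drainage) per the spec. The returned cohort is *raw* (right-sided
#' records carry mirrored clockface values, bilateral pairs have opposite
#' sides) so that [preprocess_cohort()] exercises the same pipeline as real
#' data. Reproducible for a fixed `spec$seed`.
#'
#' @param spec a [cohort_sim_spec()].
#' @return An `sln_cohort`.
#' @export
simulate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  np <- spec$n_patients
  bilateral <- stats::runif(np) < spec$bilateral_rate
  first_side <- ifelse(stats::runif(np) < spec$right_fraction, "R", "L")
  pat <- c(seq_len(np), which(bilateral))
  side <- c(first_side, ifelse(first_side[bilateral] == "R", "L", "R"))
  ord <- order(pat)                     # keep a patient's tumours adjacent
  pat <- pat[ord]
  side <- side[ord]
  n <- length(pat)
  tm <- draw_tumours(n, spec)
  clock <- tm$regions
  mirror <- side == "R" & clock >= 1L & clock <= 11L
  clock[mirror] <- 12L - clock[mirror]
  df <- data.frame(
    patient_id = sprintf("S%05d", pat), sex = "F", age_years = 60,
    side = side, clockface = clock,
    nipple_distance_cm = ifelse(tm$regions == 0L, 0.5, 3.0),
    node_fields = tm$fields, stringsAsFactors = FALSE)
  class(df) <- c("sln_cohort", "data.frame")
  df
}

#' Geometry simulation specification
#'
#' Defines a voxel grid, a set of geometric CTV primitives (axis-aligned
#' boxes, spheres, half-spaces) and per-node-field SLN placement rules
#' (centre, isotropic scatter SD, count). Primitives are rasterised to
#' labelmaps while ground truth (covered / not covered, centroid distance)
#' is computed analytically from the primitives themselves, giving an
#' oracle independent of the voxel pipeline.
#'
#' @param grid_dim length-3 integer grid size.
#' @param spacing length-3 voxel spacing, mm.
#' @param origin length-3 grid origin, mm.
#' @param primitives list of lists: `type` (`"box"`, `"sphere"`,
#'   `"halfspace"`), `label`, `side`, and parameters (`lower`/`upper` for
#'   box; `centre`/`radius` for sphere; `point`/`normal` (outward) for
#'   halfspace).
#' @param sln_rules list of lists: `node_field`, `side`, `centre`,
#'   `sigma_mm` (isotropic scatter SD), `count`.
#' @param seed optional integer seed for the scatter.
#' @return A `geometry_sim_spec` list.
#' @export
geometry_sim_spec <- function(grid_dim = c(48L, 48L, 48L),
                              spacing = c(2, 2, 2.5),
                              origin = c(0, 0, 0),
                              primitives = list(),
                              sln_rules = list(),
                              seed = NULL) {
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 2L),
            length(spacing) == 3L, all(spacing > 0))
  structure(list(grid_dim = as.integer(grid_dim), spacing = spacing,
                 origin = origin, primitives = primitives,
                 sln_rules = sln_rules, seed = seed),
            class = "geometry_sim_spec")
}

# signed distance (negative inside) from points (3 x n) to a primitive
primitive_signed_distance <- function(prim, p) {
  switch(prim$type,
    halfspace = {
      n <- prim$normal / sqrt(sum(prim$normal^2))
      colSums(n * (p - prim$point))
    },
    sphere = sqrt(colSums((p - prim$centre)^2)) - prim$radius,
    box = {
      q_lo <- prim$lower - p
      q_hi <- p - prim$upper
      q <- pmax(q_lo, q_hi)          # per-axis excess, 3 x n
      outside <- sqrt(colSums(pmax(q, 0)^2))
      inside <- pmin(apply(q, 2, max), 0)
      ifelse(outside > 0, outside, inside)
    },
    stop("unknown primitive type: ", prim$type, call. = FALSE)
  )
}

# analytic sphere volume fraction inside a primitive, treating the nearest
# surface as locally planar (exact for half-spaces; exact for boxes when at
# most one face cuts the sphere, which the generator's placement ensures)
analytic_sphere_fraction <- function(prim, centre, radius) {
  s <- primitive_signed_distance(prim, matrix(centre, 3, 1))
  cap <- function(t) (radius - t)^2 * (2 * radius + t) / (4 * radius^3)
  if (s <= -radius) return(1)
  if (s >= radius) return(0)
  if (s <= 0) 1 - cap(abs(s)) else cap(s)
}

rasterise_primitive <- function(prim, spec) {
  ax <- lapply(1:3, function(k) {
    spec$origin[k] + spec$spacing[k] * (seq_len(spec$grid_dim[k]) - 1)
  })
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  inside <- primitive_signed_distance(prim, t(g)) <= 0
  arr <- array(inside, dim = spec$grid_dim)
  ctv_mask(arr, spacing = spec$spacing, origin = spec$origin,
           label = prim$label, side = prim$side)
}

#' Simulate SLN points, CTV masks and ground-truth coverage
#'
#' Rasterises the spec's primitives into `ctv_mask` labelmaps, scatters SLN
#' points per the placement rules, and computes an analytic ground-truth
#' table: per SLN, the covered/not-covered classification (union over the
#' corresponding and all same-side primitive sets; nearest-cut spherical-cap
#' fraction) and the exact distance from the centroid to the nearest
#' primitive surface (0 inside). The truth comes from the primitives, not
#' the rasterised masks, so it is an independent oracle for the voxel
#' pipeline.
#'
#' @param spec a [geometry_sim_spec()].
#' @param map correspondence list, default [default_correspondence()].
#' @return List: `points` (`sln_points`), `masks` (list of `ctv_mask`),
#'   `truth` (data frame: per SLN and scope, analytic fraction, covered,
#'   distance_mm).
#' @export
simulate_geometry <- function(spec, map = default_correspondence()) {
  stopifnot(inherits(spec, "geometry_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  masks <- lapply(spec$primitives, rasterise_primitive, spec = spec)
  lo <- spec$origin
  hi <- spec$origin + spec$spacing * (spec$grid_dim - 1)
  pts <- list()
  for (rule in spec$sln_rules) {
    cnt <- rule$count %||% 1L
    if (cnt < 1L) next
    sig <- rule$sigma_mm %||% 0
    xyz <- matrix(rep(rule$centre, cnt), 3, cnt) +
      matrix(stats::rnorm(3 * cnt, 0, sig), 3, cnt)
    out_of_grid <- xyz[1, ] < lo[1] | xyz[1, ] > hi[1] |
      xyz[2, ] < lo[2] | xyz[2, ] > hi[2] |
      xyz[3, ] < lo[3] | xyz[3, ] > hi[3]
    if (any(out_of_grid)) {
      stop("simulated SLN centre falls outside the grid", call. = FALSE)
    }
    pts[[length(pts) + 1L]] <- sln_points(
      xyz[1, ], xyz[2, ], xyz[3, ],
      node_field = rule$node_field, side = rule$side %||% "L")
  }
  points <- if (length(pts) > 0L) {
    out <- do.call(rbind, pts)
    class(out) <- c("sln_points", "data.frame")
    out
  } else {
    sln_points(numeric(0), numeric(0), numeric(0), character(0),
               character(0))
  }
  truth <- if (nrow(points) == 0L) data.frame() else {
    do.call(rbind, lapply(seq_len(nrow(points)), function(i) {
      p <- points[i, ]
      centre <- c(p$x_mm, p$y_mm, p$z_mm)
      r <- p$diameter_mm / 2
      side_prims <- Filter(function(q) (q$side %||% "L") == p$side,
                           spec$primitives)
      corr <- Filter(function(q) q$label %in% (map[[p$node_field]] %||%
                                                 character(0)), side_prims)
      one <- function(prims, scope) {
        if (length(prims) == 0L) {
          return(data.frame(sln = i, node_field = p$node_field,
                            side = p$side, scope = scope,
                            fraction = 0, covered = FALSE,
                            distance_mm = NA_real_))
        }
        sd_all <- vapply(prims, function(q)
          primitive_signed_distance(q, matrix(centre, 3, 1)), numeric(1))
        # union fraction via the nearest (least signed distance) surface
        frac <- analytic_sphere_fraction(prims[[which.min(sd_all)]],
                                         centre, r)
        cov <- frac > 0.5
        data.frame(sln = i, node_field = p$node_field, side = p$side,
                   scope = scope, fraction = frac, covered = cov,
                   distance_mm = if (cov) NA_real_
                                 else max(min(sd_all), 0))
      }
      rbind(one(corr, "corresponding"), one(side_prims, "all"))
    }))
  }
  list(points = points, masks = masks, truth = truth)
}
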