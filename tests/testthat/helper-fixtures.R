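# in-code fixtures shared across test files

# one-row cohort builder
one_record <- function(clockface = 4L, side = "L", distance = 3.0,
                       fields = "axilla-I-anterior", id = "P1") {
  sln_cohort(patient_id = id, side = side, clockface = clockface,
             nipple_distance_cm = distance, node_fields = fields)
}

# toy cohort: n tumours, n_drain of them draining to `field`, one per patient
toy_cohort <- function(n, n_drain, field = "internal-mammary",
                       region = 5L) {
  fields <- c(rep(paste0("axilla-I-anterior;", field), n_drain),
              rep("axilla-I-anterior", n - n_drain))
  sln_cohort(patient_id = sprintf("T%03d", seq_len(n)), side = "L",
             clockface = region, nipple_distance_cm = 3,
             node_fields = fields)
}

# axis-aligned solid box mask on a regular grid
box_mask <- function(lower, upper, grid_dim = c(40L, 40L, 40L),
                     spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     label = "L1", side = "L") {
  ax <- lapply(1:3, function(k) origin[k] + spacing[k] *
                 (seq_len(grid_dim[k]) - 1))
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  inside <- g[, 1] >= lower[1] & g[, 1] <= upper[1] &
    g[, 2] >= lower[2] & g[, 2] <= upper[2] &
    g[, 3] >= lower[3] & g[, 3] <= upper[3]
  ctv_mask(array(inside, grid_dim), spacing, origin, diag(3), label, side)
}

# half-space mask: foreground where x <= plane_x (voxel-centre test)
halfspace_mask <- function(plane_x, grid_dim = c(40L, 40L, 40L),
                           spacing = c(0.5, 0.5, 0.5), origin = c(0, 0, 0),
                           label = "L1", side = "L") {
  xs <- origin[1] + spacing[1] * (seq_len(grid_dim[1]) - 1)
  arr <- array(rep(xs <= plane_x, times = grid_dim[2] * grid_dim[3]),
               grid_dim)
  ctv_mask(arr, spacing, origin, diag(3), label, side)
}

# single SLN point helper
one_point <- function(x, y, z, field = "axilla-I-anterior", side = "L",
                      diameter = 5) {
  sln_points(x, y, z, node_field = field, side = side,
             diameter_mm = diameter)
}

# exact spherical-cap volume fraction beyond a plane at distance t >= 0
# from the centre of a sphere of radius r
cap_fraction <- function(t, r) (r - t)^2 * (2 * r + t) / (4 * r^3)
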