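# Independent brute-force oracles and small fixture builders.
# The oracles deliberately use naive per-voxel enumeration, not the
# package's vectorised code paths.

# per-voxel enumeration of the summary metrics
oracle_metrics <- function(doses, voxel_vol_mm3, n_fractions,
                           vx_levels = c(10, 20, 30, 40, 45, 50, 60, 70)) {
  dmin <- Inf; dmax <- -Inf; total <- 0
  counts <- setNames(numeric(length(vx_levels)), paste0("v", vx_levels))
  for (d in doses) {
    if (d < dmin) dmin <- d
    if (d > dmax) dmax <- d
    total <- total + d
    for (i in seq_along(vx_levels))
      if (d >= vx_levels[i]) counts[i] <- counts[i] + 1
  }
  list(d_min = dmin, d_max = dmax, d_mean = total / length(doses),
       fractionated_dose = (total / length(doses)) / n_fractions,
       vx = 100 * counts / length(doses),
       volume_cc = length(doses) * voxel_vol_mm3 / 1000)
}

# per-edge enumeration of the cumulative DVH
oracle_dvh <- function(doses, edges) {
  vapply(edges, function(x) 100 * sum(doses >= x) / length(doses),
         numeric(1))
}

# random small phantom: random lattice, random doses, random non-empty mask
random_phantom <- function() {
  shape <- sample(2:7, 3, replace = TRUE)
  values <- array(round(stats::runif(prod(shape), 0, 70), 2), dim = shape)
  include <- array(stats::runif(prod(shape)) < 0.5, dim = shape)
  if (!any(include)) include[sample(length(include), 1)] <- TRUE
  spacing <- stats::runif(3, 0.5, 3)
  list(grid = dose_grid(values, spacing = spacing),
       mask = structure_mask(include))
}

# mean of a normal truncated to [a, b] (closed form)
truncnorm_mean <- function(mean, sd, a, b) {
  al <- (a - mean) / sd
  be <- (b - mean) / sd
  mean + sd * (stats::dnorm(al) - stats::dnorm(be)) /
    (stats::pnorm(be) - stats::pnorm(al))
}

uniform_grid <- function(dose, shape = c(3, 3, 3), dose_kind = "physical") {
  dose_grid(array(dose, dim = shape), dose_kind = dose_kind)
}

full_mask <- function(shape = c(3, 3, 3)) {
  structure_mask(array(TRUE, dim = shape))
}
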