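# Independent brute-force oracles used to validate the fast implementation
# paths. These deliberately use naive explicit counting over the voxel dose
# multiset rather than the package's cumulative-table arithmetic.

# Exceedance count at every distinct dose, by explicit per-candidate counting.
oracle_dvh_curve <- function(doses) {
  cand <- sort(unique(doses))
  n_ge <- vapply(cand, function(d) sum(doses >= d), numeric(1))
  data.frame(dose = cand, n_ge = n_ge, frac_ge = n_ge / length(doses))
}

# D_x%: smallest dose whose exceedance fraction is <= x/100 (the minimum dose
# of the hottest x% of the structure); the hottest voxel when x spans less
# than one voxel.
oracle_d_percent <- function(doses, x) {
  cand <- sort(unique(doses))
  for (d in cand) {
    if (sum(doses >= d) / length(doses) <= x / 100 + 1e-12) return(d)
  }
  max(doses)
}

oracle_v_dose <- function(doses, x_gy) 100 * sum(doses >= x_gy) / length(doses)

oracle_d_cm3 <- function(doses, vol_cm3, voxel_cm3) {
  oracle_d_percent(doses, 100 * vol_cm3 / (length(doses) * voxel_cm3))
}

# Random dose grid + mask pair; doses rounded to a coarse lattice so ties occur.
random_grid_mask <- function(n_side = NULL, tie_digits = 1) {
  if (is.null(n_side)) n_side <- sample(3:12, 3, replace = TRUE)
  v <- array(round(stats::runif(prod(n_side), 0, 70), tie_digits), dim = n_side)
  m <- array(stats::runif(prod(n_side)) > 0.3, dim = n_side)
  if (!any(m)) m[1] <- TRUE
  list(
    grid = dose_grid(v, spacing = c(2, 2, 2)),
    mask = structure_mask(m, "S", "PTV", spacing = c(2, 2, 2)),
    doses = v[m]
  )
}

# Uniform-dose phantom helpers.
uniform_grid <- function(dose, dims = c(4, 4, 4), spacing = c(1, 1, 1)) {
  dose_grid(array(dose, dims), spacing = spacing)
}
full_mask <- function(dims = c(4, 4, 4), spacing = c(1, 1, 1), role = "PTV") {
  structure_mask(array(TRUE, dims), "S", role, spacing = spacing)
}
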