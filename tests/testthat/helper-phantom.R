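# Shared fixtures: phantoms are generated in code, never stored.

noiseless_spec <- function(seed = 1, ...) {
  phantom_spec(tissue_sds = c(fat = 0, muscle = 0, marrow = 0, cortex = 0),
               pet_noise_sd = 0, seed = seed, ...)
}

# tiny volume wrapping a numeric vector, for quantify-level tests
vector_volume <- function(values, unit = "SUV") {
  volume3d(array(values, c(1, length(values), 1)), unit = unit)
}

vector_mask <- function(labels) {
  region_mask(array(as.integer(labels), c(1, length(labels), 1)))
}

# build an suv_map carrying given SUV voxel values through the real
# Bq/mL -> SUV conversion; the default meta has dose/weight_g = 1 MBq/g so
# the round trip is exact at machine precision
suv_from_values <- function(values, meta = patient_meta(1, 0.001, 170)) {
  scale <- meta$injected_dose_MBq / (meta$body_weight_kg * 1000) * 1e6
  pet <- volume3d(array(values * scale, c(1, length(values), 1)),
                  unit = "Bq/mL")
  suv_map(pet, meta, "bw")
}

# exhaustive minimum of the Chan-Vese energy (epsilon = 0) over all
# two-region labellings of a small image, vectorized over bit patterns
brute_force_cv_min <- function(image) {
  v <- as.numeric(image)
  n <- length(v)
  stopifnot(n <= 16)
  n_masks <- 2^n
  bits <- matrix(0, n_masks, n)
  for (j in seq_len(n)) bits[, j] <- bitwAnd(seq_len(n_masks) - 1L,
                                             bitwShiftL(1L, j - 1L)) > 0
  n1 <- rowSums(bits)
  keep <- n1 > 0 & n1 < n
  bits <- bits[keep, , drop = FALSE]
  n1 <- n1[keep]
  s1 <- as.numeric(bits %*% v)
  ss1 <- as.numeric(bits %*% v^2)
  s2 <- sum(v) - s1
  ss2 <- sum(v^2) - ss1
  n2 <- n - n1
  # sum (x - mean)^2 = sum x^2 - (sum x)^2 / n
  energy <- (ss1 - s1^2 / n1) + (ss2 - s2^2 / n2)
  min(energy)
}
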