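# Shared fixtures, all generated in code.

# n random k-point configurations as a k x 2 x n array.
toy_array <- function(n = 6L, k = 8L, seed = 1L) {
  set.seed(seed)
  array(rnorm(k * 2L * n), dim = c(k, 2L, n),
        dimnames = list(NULL, c("x", "y"), sprintf("spec_%d", seq_len(n))))
}

toy_configs <- function(n = 6L, k = 8L, seed = 1L) {
  arr <- toy_array(n, k, seed)
  lapply(seq_len(n), function(i)
    landmark_config(arr[, , i], specimen_id = sprintf("spec_%d", i),
                    fixed = if (k >= 5L) standard_fixed_indices(k)
                            else c(1L, 2L, k)))
}

# apply a random similarity transform to every slice of an array
similarity_transform <- function(arr, angle, scale = 1, shift = c(0, 0)) {
  rot <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2L, 2L)
  out <- arr
  for (i in seq_len(dim(arr)[3L]))
    out[, , i] <- scale * arr[, , i] %*% rot +
      matrix(shift, dim(arr)[1L], 2L, byrow = TRUE)
  out
}

# small noisy tooth sample for end-to-end style unit tests
toy_teeth <- function(n = 10L, k = 40L, seed = 1L, noise_sd = 0.01,
                      crown_height = 1.5, crown_sd = 0.15) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    make_tooth(tooth_params(crown_height = max(crown_height +
                                                 crown_sd * rnorm(1), 0.2),
                            recurvature = 0.2, noise_sd = noise_sd),
               k = k, specimen_id = sprintf("tooth_%02d", i)))
}
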