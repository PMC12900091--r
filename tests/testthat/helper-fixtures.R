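# Shared fixtures and independent oracles, built in code at test time.

# cube with one pixel per row of `values` (n_pixels x n_bands matrix)
make_cube <- function(values, stage = "reflectance", bands = NULL) {
  values <- as.matrix(values)
  n <- ncol(values)
  if (is.null(bands))
    bands <- band_set(seq(400, by = 50, length.out = n))
  spectral_cube(array(values, dim = c(nrow(values), 1, n)), bands,
                stage = stage)
}

all_mask <- function(cube) roi_mask(matrix(TRUE, dim(cube$pixels)[1],
                                           dim(cube$pixels)[2]))

# Direct-sum phasor oracle: plain double loop over Eq.-style sums with the
# uniform band-index phase; independent of the package's vectorized path.
phasor_oracle <- function(spectrum, k) {
  n <- length(spectrum)
  gs <- 0; ss <- 0; dn <- 0
  for (m in 0:(n - 1)) {
    gs <- gs + spectrum[m + 1] * cos(2 * pi * k * m / n)
    ss <- ss + spectrum[m + 1] * sin(2 * pi * k * m / n)
    dn <- dn + spectrum[m + 1]
  }
  c(g = gs / dn, s = ss / dn)
}

# Hotelling T^2 oracle for the two-group MANOVA equivalence
hotelling_oracle <- function(X, y) {
  X <- as.matrix(X)
  g <- unique(y)
  X1 <- X[y == g[1], , drop = FALSE]
  X2 <- X[y == g[2], , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2); n <- n1 + n2; d <- ncol(X)
  S <- (crossprod(sweep(X1, 2, colMeans(X1))) +
        crossprod(sweep(X2, 2, colMeans(X2)))) / (n - 2)
  diff <- colMeans(X1) - colMeans(X2)
  t2 <- (n1 * n2 / n) * drop(t(diff) %*% solve(S, diff))
  Fstat <- t2 * (n - d - 1) / ((n - 2) * d)
  list(lambda = 1 / (1 + t2 / (n - 2)), F = Fstat,
       p = stats::pf(Fstat, d, n - d - 1, lower.tail = FALSE))
}

# Small dataset shared across tests (generated once per test run)
local_test_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds))
      ds <<- generate_dataset(synthetic_config(
        n_healthy = 12, n_diseased = 10, image_size = c(48, 48), seed = 7))
    ds
  }
})
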