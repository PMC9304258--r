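# Independent brute-force oracles shared across test files.

# independent brute-force Laplacian: replicate pad + direct stencil loops
naive_laplacian <- function(m) {
  H <- nrow(m); W <- ncol(m)
  cl <- function(v, n) pmin(pmax(v, 1L), n)
  out <- matrix(0, H, W)
  for (i in seq_len(H))
    for (j in seq_len(W))
      out[i, j] <- -4 * m[i, j] +
        m[cl(i - 1L, H), j] + m[cl(i + 1L, H), j] +
        m[i, cl(j - 1L, W)] + m[i, cl(j + 1L, W)]
  out
}


# independent direct-DFT radial profile for small rasters
naive_radial_profile <- function(m) {
  N <- nrow(m); M <- ncol(m)
  Fm <- matrix(0 + 0i, N, M)
  for (v in 0:(N - 1)) for (u in 0:(M - 1)) {
    s <- 0 + 0i
    for (y in 0:(N - 1)) for (x in 0:(M - 1))
      s <- s + m[y + 1, x + 1] * exp(-2i * pi * (u * x / M + v * y / N))
    Fm[v + 1, u + 1] <- s
  }
  iu <- ifelse(0:(M - 1) <= M %/% 2, 0:(M - 1), 0:(M - 1) - M)
  iv <- ifelse(0:(N - 1) <= N %/% 2, 0:(N - 1), 0:(N - 1) - N)
  d <- sqrt(outer((iv * M / N)^2, iu^2, `+`))
  r <- floor(d)
  tapply(as.numeric(Mod(Fm)), r, mean)
}

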