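test_that("the Laplacian matches its closed-form cases", {
  expect_equal(laplacianEdgeMap(matrix(7, 8, 8)), matrix(0, 8, 8))
  # linear ramp: zero at interior pixels (second difference of a line)
  ramp <- outer(1:10, 1:12, function(y, x) 3 * x + 2 * y)
  lap <- laplacianEdgeMap(ramp)
  expect_equal(lap[2:9, 2:11], matrix(0, 8, 10))
  # unit impulse reproduces the stencil on the interior
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  lap <- laplacianEdgeMap(imp)
  expect_equal(lap[3, 3], -4)
  expect_equal(lap[2, 3], 1); expect_equal(lap[4, 3], 1)
  expect_equal(lap[3, 2], 1); expect_equal(lap[3, 4], 1)
  expect_equal(sum(abs(lap[2:4, 2:4])), 8)
  expect_error(laplacianEdgeMap(matrix(0, 2, 2)), "3x3")
})

test_that("the Laplacian agrees with a brute-force oracle on random rasters", {
  for (s in 1:50) {
    set.seed(s)
    m <- matrix(stats::rnorm(16 * 16), 16, 16)
    expect_lt(max(abs(laplacianEdgeMap(m) - naive_laplacian(m))), 1e-6)
  }
})

test_that("the Laplacian is translation covariant away from borders", {
  set.seed(4)
  m <- matrix(stats::rnorm(20 * 20), 20, 20)
  shifted <- m[c(2:20, 20), ]           # shift up one row
  a <- laplacianEdgeMap(m)[3:18, 3:18]
  b <- laplacianEdgeMap(shifted)[2:17, 3:18]
  expect_lt(max(abs(a - b)), 1e-9)
})

# naive direct convolution over a (H,W,Cin,N) array, zero padding
naive_conv <- function(x, w, b, k, stride, pad) {
  d <- dim(x)
  Cout <- ncol(w)
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(Cout))
    for (oh in seq_len(Ho)) for (ow in seq_len(Wo)) {
      acc <- b[co]
      for (ci in seq_len(d[3])) for (kj in 0:(k - 1)) for (ki in 0:(k - 1)) {
        ih <- (oh - 1) * stride + ki - pad + 1
        iw <- (ow - 1) * stride + kj - pad + 1
        if (ih >= 1 && ih <= d[1] && iw >= 1 && iw <= d[2])
          acc <- acc + x[ih, iw, ci, n] *
            w[ki + k * kj + k * k * (ci - 1) + 1, co]
      }
      out[oh, ow, co, n] <- acc
    }
  out
}

test_that("the convolution kernel matches a direct-summation oracle", {
  set.seed(11)
  for (case in list(list(k = 3L, s = 1L, p = 1L, cin = 3L, cout = 2L),
                    list(k = 3L, s = 2L, p = 1L, cin = 2L, cout = 4L),
                    list(k = 1L, s = 1L, p = 0L, cin = 4L, cout = 3L))) {
    x <- array(stats::rnorm(8 * 10 * case$cin * 2), c(8, 10, case$cin, 2))
    w <- matrix(stats::rnorm(case$k^2 * case$cin * case$cout),
                case$k^2 * case$cin, case$cout)
    b <- stats::rnorm(case$cout)
    got <- eedn:::nn_conv_fwd(x, w, b, case$k, case$s, case$p)
    want <- naive_conv(x, w, b, case$k, case$s, case$p)
    expect_lt(max(abs(got - want)), 1e-4)
  }
})

test_that("model building is deterministic and validates its configuration", {
  cfg <- ModelConfig(seed = 5L)
  m1 <- buildModel(cfg); m2 <- buildModel(cfg)
  expect_equal(eedn:::p_checksum(m1@params), eedn:::p_checksum(m2@params))
  m3 <- buildModel(ModelConfig(seed = 6L))
  expect_false(isTRUE(all.equal(eedn:::p_checksum(m1@params),
                                eedn:::p_checksum(m3@params))))
  expect_error(ModelConfig(nUdbsTotal = 6L, nUdbsDenoiser = 2L,
                           nUdbsEdge = 3L), "nUdbsTotal")
})

test_that("the 6-UDB baseline exists and EEDN (3+3) matches its parameter budget", {
  uddn <- buildModel(ModelConfig(variant = "uddn", nUdbsTotal = 6L))
  expect_length(uddn@params$dudb, 6L)
  expect_null(uddn@params$att)
  eedn <- buildModel(ModelConfig(variant = "eedn"))
  expect_length(eedn@params$dudb, 3L)
  expect_length(eedn@params$eudb, 3L)
  ratio <- parameterCount(eedn) / parameterCount(uddn)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("attention weights are sigmoid-bounded and exactly 0.5 at zero input", {
  cfg <- deskModelConfig(3L)
  m <- buildModel(cfg)
  set.seed(1)
  feats <- array(stats::rnorm(8 * 8 * cfg@edgeChannels), c(8, 8, cfg@edgeChannels, 1))
  w <- attentionWeights(m, feats)
  expect_true(all(w > 0 & w < 1))
  w2 <- attentionWeights(m, feats)
  expect_identical(w, w2)    # deterministic given parameters and input
  # zeroed block: constant-zero pre-activation -> sigmoid(0) = 0.5
  m0 <- m
  for (j in seq_along(m0@params$att)) {
    m0@params$att[[j]]$conv$w[] <- 0
    m0@params$att[[j]]$conv$b[] <- 0
  }
  expect_true(all(attentionWeights(m0, feats) == 0.5))
})

test_that("composeOutput is exact elementwise arithmetic", {
  ii <- matrix(c(10, 30, 20, 40), 2, 2)
  ie <- matrix(c(1, 0, 0, 1), 2, 2)
  ip <- matrix(c(2, 0, 0, 3), 2, 2)
  expect_equal(composeOutput(ii, ie, ip), matrix(c(11, 30, 20, 42), 2, 2))
  expect_equal(composeOutput(ii, ie, ie), ii)
  z <- matrix(0, 3, 3)
  expect_equal(composeOutput(z, z, z), z)
  expect_error(composeOutput(ii, ie, matrix(0, 3, 2)), "shape")
})

test_that("denoise preserves shape and satisfies the composition identity", {
  m <- buildModel(deskModelConfig(2L))
  for (sz in list(c(96L, 96L), c(64L, 80L), c(50L, 46L))) {
    f <- ImageFrame(matrix(stats::runif(prod(sz), 0, 255), sz[1], sz[2]))
    tr <- denoise(m, f)
    expect_equal(dim(tr@iOutput), as.integer(sz))
    expect_equal(dim(tr@iInter), as.integer(sz))
    resid <- max(abs(tr@iOutput - (tr@iInter + tr@iEdgePlus - tr@iEdge)))
    expect_lte(resid, 1e-4)
  }
  # pure function of (parameters, input)
  f <- ImageFrame(matrix(stats::runif(96 * 96, 0, 255), 96, 96))
  expect_identical(denoise(m, f)@iOutput, denoise(m, f)@iOutput)
})

test_that("the uddn variant denoises without an edge branch", {
  m <- buildModel(ModelConfig(variant = "uddn", nUdbsTotal = 2L,
                              growthChannels = 8L, baseChannels = 8L,
                              seed = 4L))
  f <- ImageFrame(matrix(stats::runif(64 * 64, 0, 255), 64, 64))
  tr <- denoise(m, f)
  expect_equal(tr@iOutput, tr@iInter)
  expect_true(all(tr@iEdge == 0))
})

test_that("the fused dense-block kernel agrees with the layer-by-layer reference", {
  cfg <- ModelConfig(variant = "uddn", nUdbsTotal = 1L, udbLayers = 3L,
                     growthChannels = 4L, baseChannels = 5L, seed = 2L)
  pu <- buildModel(cfg)@params$dudb$u1
  set.seed(8)
  x <- array(stats::rnorm(10 * 12 * 5 * 2), c(10, 12, 5, 2))
  ref <- eedn:::udb_fwd_ref(x, pu)
  got <- eedn:::udb_call_fwd(901L, x, pu)
  expect_lt(max(abs(ref$out - got)), 1e-5)
  dout <- array(stats::rnorm(10 * 12 * 5 * 2), c(10, 12, 5, 2))
  bref <- eedn:::udb_bwd_ref(dout, pu, ref$cache)
  bgot <- eedn:::udb_call_bwd(901L, dout, pu)
  expect_lt(max(abs(bref$dx - bgot$dx)), 1e-4)
  for (l in 1:3) {
    expect_lt(max(abs(bref$grads$layers[[l]]$conv$w -
                        bgot$grads$layers[[l]]$conv$w)), 1e-4)
    expect_lt(abs(bref$grads$layers[[l]]$a - bgot$grads$layers[[l]]$a), 1e-4)
  }
  expect_lt(max(abs(bref$grads$fuse$w - bgot$grads$fuse$w)), 1e-4)
})

test_that("analytic gradients match finite differences through the whole network", {
  cfg <- ModelConfig(variant = "eedn", nUdbsTotal = 2L, nUdbsDenoiser = 1L,
                     nUdbsEdge = 1L, udbLayers = 2L, growthChannels = 3L,
                     baseChannels = 4L, edgeChannels = 2L, seed = 3L)
  m <- buildModel(cfg)
  set.seed(42)
  # the exit convolutions are zero-initialized; perturb them so gradient
  # flow through every branch is exercised
  m@params$dout$w[] <- stats::rnorm(length(m@params$dout$w), sd = 0.1)
  m@params$dout$b[] <- 0.01
  m@params$eout$w[] <- stats::rnorm(length(m@params$eout$w), sd = 0.1)
  m@params$eout$b[] <- -0.01
  x <- array(stats::runif(12 * 12 * 2), c(12, 12, 1, 2))
  y <- array(stats::runif(12 * 12 * 2), c(12, 12, 1, 2))
  eps <- 1e-3
  lossfun <- function(p) {
    f <- eedn:::model_fwd(p, cfg, x)
    sum(sqrt((f$i_output - y)^2 + eps^2))
  }
  fwd <- eedn:::model_fwd(m@params, cfg, x, keep_cache = TRUE)
  diffv <- fwd$i_output - y
  grads <- eedn:::model_bwd(m@params, cfg, x, fwd$cache,
                            diffv / sqrt(diffv^2 + eps^2))
  paths <- list(c("din", "w"), c("dudb", "u1", "layers", "l1", "conv", "w"),
                c("dudb", "u1", "fuse", "w"), c("dout", "b"),
                c("enc1", "w"), c("eudb", "u1", "layers", "l2", "conv", "w"),
                c("att", "a3", "conv", "w"), c("merge", "w"),
                c("dec1", "w"), c("eout", "w"), c("din_a", "a"))
  setv <- function(tree, path, i, v) {
    if (length(path) == 1L) { tree[[path[1]]][i] <- v; return(tree) }
    tree[[path[1]]] <- setv(tree[[path[1]]], path[-1], i, v)
    tree
  }
  h <- 5e-3
  set.seed(99)
  for (path in paths) {
    p <- m@params; g <- grads
    for (k in path) { p <- p[[k]]; g <- g[[k]] }
    i <- sample(length(p), 1L)
    num <- (lossfun(setv(m@params, path, i, p[i] + h)) -
              lossfun(setv(m@params, path, i, p[i] - h))) / (2 * h)
    # single-precision forward: compare at float-level tolerance
    expect_lt(abs(num - g[i]) / max(1, abs(num) + abs(g[i])), 0.08)
  }
})
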