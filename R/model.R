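#' @include AllClasses.R layers.R
NULL

#' Laplacian edge map of a raster
#'
#' Discrete 4-neighbor Laplacian (center -4, N/S/E/W +1) approximating the
#' sum of second derivatives; borders are replicate-padded so the output has
#' the input's size. Edges appear as steep zero crossings. This is the edge
#' extractor applied to the intermediate denoised frame inside the network,
#' exposed as a standalone operation.
#'
#' @param frame an [ImageFrame-class] or numeric matrix, at least 3x3
#' @return numeric matrix of the same size
#' @examples
#' laplacianEdgeMap(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3))
#' @export
laplacianEdgeMap <- function(frame) {
  m <- if (is(frame, "ImageFrame")) frame@pixels else as.matrix(frame)
  if (nrow(m) < 3L || ncol(m) < 3L)
    stop("the Laplacian needs a frame of at least 3x3")
  x <- array(m, c(nrow(m), ncol(m), 1L, 1L))
  matrix(nn_lap_fwd(x), nrow(m), ncol(m))
}

#' Compose the final output from its three components
#'
#' The composition rule of the framework: the enhanced edge map replaces the
#' over-smoothed edges of the intermediate result,
#' `iOutput = iInter + iEdgePlus - iEdge`, elementwise and without clipping
#' (quantization is deferred to write time).
#'
#' @param iInter intermediate denoised raster
#' @param iEdge its Laplacian edge map
#' @param iEdgePlus the enhanced edge map
#' @return numeric matrix
#' @export
composeOutput <- function(iInter, iEdge, iEdgePlus) {
  iInter <- as.matrix(iInter); iEdge <- as.matrix(iEdge)
  iEdgePlus <- as.matrix(iEdgePlus)
  if (!all(dim(iInter) == dim(iEdge)) || !all(dim(iInter) == dim(iEdgePlus)))
    stop("all three rasters must share the same shape")
  iInter + iEdgePlus - iEdge
}

udb_param <- function(cin, growth, layers) {
  ls <- vector("list", layers)
  for (l in seq_len(layers)) {
    ls[[l]] <- list(conv = conv_param(cin + (l - 1L) * growth, growth),
                    a = 0.25)
  }
  names(ls) <- paste0("l", seq_len(layers))
  list(layers = ls, fuse = conv_param(cin + layers * growth, cin, k = 1L,
                                      stride = 1L, pad = 0L))
}

#' Build a network
#'
#' Constructs an EEDN (initial denoiser of `nUdbsDenoiser` ultra-dense
#' blocks, Laplacian edge extraction, a stride-2 convolutional encoder, a
#' parallel UDB stack and 6-layer attention block merged by gating, a
#' deconvolutional decoder, and the final composition) or the UDDN baseline
#' (all UDBs in a single stack). Parameter initialization is deterministic
#' from `config@seed`.
#'
#' @param config a [ModelConfig-class]
#' @return an [EEDNModel-class]
#' @examples
#' m <- buildModel(ModelConfig(variant = "uddn", nUdbsTotal = 1L,
#'                             growthChannels = 4L, baseChannels = 4L))
#' @export
buildModel <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  old <- local_rng_seed(config@seed)
  on.exit(restore_rng(old))
  C <- config@baseChannels
  g <- config@growthChannels
  L <- config@udbLayers
  p <- list(
    din = conv_param(1L, C),
    din_a = list(a = 0.25),
    dudb = local({
      n <- if (config@variant == "eedn") config@nUdbsDenoiser else config@nUdbsTotal
      u <- lapply(seq_len(n), function(i) udb_param(C, g, L))
      names(u) <- paste0("u", seq_len(n))
      u
    }),
    dout = conv_param(C, 1L)
  )
  if (config@variant == "eedn") {
    Ce <- config@edgeChannels
    p$enc1 <- conv_param(1L, Ce, k = 3L, stride = 2L, pad = 1L)
    p$enc1_a <- list(a = 0.25)
    p$enc2 <- conv_param(Ce, Ce, k = 3L, stride = 2L, pad = 1L)
    p$enc2_a <- list(a = 0.25)
    p$eudb <- local({
      u <- lapply(seq_len(config@nUdbsEdge), function(i) udb_param(Ce, g, L))
      names(u) <- paste0("u", seq_len(config@nUdbsEdge))
      u
    })
    p$att <- local({
      a <- lapply(seq_len(config@attentionLayers), function(i)
        list(conv = conv_param(Ce, Ce), a = 0.25))
      names(a) <- paste0("a", seq_len(config@attentionLayers))
      a
    })
    p$merge <- conv_param(Ce, Ce, k = 1L, stride = 1L, pad = 0L)
    p$dec1 <- deconv_param(Ce, Ce)
    p$dec1_a <- list(a = 0.25)
    p$dec2 <- deconv_param(Ce, Ce)
    p$dec2_a <- list(a = 0.25)
    p$eout <- conv_param(Ce, 1L)
    # the branch predicts a residual enhancement of the edge map; starting
    # it at zero makes the untrained network an identity refinement of the
    # initial denoiser instead of injecting decoder noise
    p$eout$w[] <- 0
    p$eout$b[] <- 0
  }
  # likewise the denoiser's exit conv: the untrained model then passes the
  # input through unchanged (global residual)
  p$dout$w[] <- 0
  p$dout$b[] <- 0
  new("EEDNModel", config = config, params = p, steps = 0L)
}

#' @describeIn buildModel number of trainable parameters
#' @param model an [EEDNModel-class]
#' @aliases parameterCount,EEDNModel-method
#' @export
setMethod("parameterCount", "EEDNModel", function(model) {
  as.integer(p_count(model@params))
})

# Reference (pure layer-by-layer) UDB forward/backward. The production path
# runs inside the C++ kernel (nn_udb_fwd/nn_udb_bwd, which build the dense
# block's im2col columns incrementally); these reference versions express the
# same computation through the generic layer primitives and serve as the
# independent check in the test suite.
udb_fwd_ref <- function(x, pu) {
  feats <- list(x)
  ins <- list(); zs <- list()
  for (l in seq_along(pu$layers)) {
    inp <- cat4(feats)
    z <- conv_f(inp, pu$layers[[l]]$conv)
    ins[[l]] <- inp; zs[[l]] <- z
    feats[[l + 1L]] <- prelu_f(z, pu$layers[[l]]$a)
  }
  catall <- cat4(feats)
  out <- conv_f(catall, pu$fuse) + x
  list(out = out,
       cache = list(ins = ins, zs = zs, catall = catall,
                    widths = vapply(feats, function(f) dim(f)[3], integer(1))))
}

udb_bwd_ref <- function(dout, pu, cache) {
  g <- list(layers = vector("list", length(pu$layers)))
  names(g$layers) <- names(pu$layers)
  fb <- conv_b(cache$catall, pu$fuse, dout)
  g$fuse <- list(w = fb$dw, b = fb$db)
  gfeats <- split4(fb$dx, cache$widths)
  for (l in rev(seq_along(pu$layers))) {
    pb <- prelu_b(cache$zs[[l]], pu$layers[[l]]$a, gfeats[[l + 1L]])
    cb <- conv_b(cache$ins[[l]], pu$layers[[l]]$conv, pb$dx)
    g$layers[[l]] <- list(conv = list(w = cb$dw, b = cb$db), a = pb$da)
    dsplit <- split4(cb$dx, cache$widths[seq_len(l)])
    for (j in seq_len(l)) gfeats[[j]] <- gfeats[[j]] + dsplit[[j]]
  }
  list(dx = gfeats[[1L]] + dout, grads = g)
}

udb_call_fwd <- function(id, x, pu) {
  nn_udb_fwd(id, x,
             lapply(pu$layers, function(l) l$conv$w),
             lapply(pu$layers, function(l) l$conv$b),
             vapply(pu$layers, function(l) l$a, numeric(1)),
             pu$fuse$w, pu$fuse$b, ncol(pu$layers[[1L]]$conv$w))
}

udb_call_bwd <- function(id, dout, pu) {
  r <- nn_udb_bwd(id, lapply(pu$layers, function(l) l$conv$w),
                  vapply(pu$layers, function(l) l$a, numeric(1)),
                  pu$fuse$w, dout)
  g <- list(layers = lapply(seq_along(pu$layers), function(l)
    list(conv = list(w = r$dw[[l]], b = r$db[[l]]), a = r$da[l])))
  names(g$layers) <- names(pu$layers)
  g$fuse <- list(w = r$fuse_dw, b = r$fuse_db)
  list(dx = r$dx, grads = g)
}

udb_stack_fwd <- function(x, stack, id_base) {
  for (i in seq_along(stack)) x <- udb_call_fwd(id_base + i, x, stack[[i]])
  list(out = x)
}

udb_stack_bwd <- function(dout, stack, id_base) {
  grads <- vector("list", length(stack))
  names(grads) <- names(stack)
  for (i in rev(seq_along(stack))) {
    r <- udb_call_bwd(id_base + i, dout, stack[[i]])
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

# Full forward pass on a normalized (H,W,1,N) batch. Returns the trace
# tensors and (when keep_cache) everything backward needs.
model_fwd <- function(p, config, x, keep_cache = FALSE) {
  cc <- list()
  z0 <- conv_f(x, p$din)
  h0 <- prelu_f(z0, p$din_a$a)
  den <- udb_stack_fwd(h0, p$dudb, 0L)
  r <- conv_f(den$out, p$dout)
  i_inter <- x + r
  if (config@variant == "uddn") {
    if (keep_cache) cc <- list(z0 = z0, h0 = h0, u = den$out)
    return(list(i_inter = i_inter, i_edge = NULL, i_edge_plus = NULL,
                i_output = i_inter, cache = cc))
  }
  i_edge <- nn_lap_fwd(i_inter)
  e1z <- conv_f(i_edge, p$enc1); e1 <- prelu_f(e1z, p$enc1_a$a)
  e2z <- conv_f(e1, p$enc2);     e2 <- prelu_f(e2z, p$enc2_a$a)
  eud <- udb_stack_fwd(e2, p$eudb, 100L)
  a_in <- e2
  azs <- list(); ains <- list()
  for (j in seq_along(p$att)) {
    ains[[j]] <- a_in
    az <- conv_f(a_in, p$att[[j]]$conv)
    azs[[j]] <- az
    a_in <- prelu_f(az, p$att[[j]]$a)
  }
  w_att <- sigmoid_f(a_in)
  m_in <- eud$out * w_att
  m <- conv_f(m_in, p$merge)
  g1z <- deconv_f(m, p$dec1); g1 <- prelu_f(g1z, p$dec1_a$a)
  g2z <- deconv_f(g1, p$dec2); g2 <- prelu_f(g2z, p$dec2_a$a)
  # the decoder output is a residual enhancement of the edge map
  i_edge_plus <- nn_add(conv_f(g2, p$eout), i_edge)
  i_output <- i_inter + i_edge_plus - i_edge
  if (keep_cache) {
    cc <- list(z0 = z0, h0 = h0, u = den$out,
               i_inter = i_inter, i_edge = i_edge, e1z = e1z, e1 = e1,
               e2z = e2z, e2 = e2, eud_out = eud$out,
               azs = azs, ains = ains, w_att = w_att, m_in = m_in, m = m,
               g1z = g1z, g1 = g1, g2z = g2z, g2 = g2)
  }
  list(i_inter = i_inter, i_edge = i_edge, i_edge_plus = i_edge_plus,
       i_output = i_output, cache = cc)
}

# Backward pass: d_out is the loss gradient w.r.t. i_output. Returns the
# gradient tree (same shape as the trainable parameters).
model_bwd <- function(p, config, x, cache, d_out) {
  g <- list()
  if (config@variant == "eedn") {
    d_inter <- d_out
    # edge branch: eout <- dec2 <- dec1 <- merge <- (udb stack || attention)
    eb <- conv_b(cache$g2, p$eout, d_out)
    g$eout <- list(w = eb$dw, b = eb$db)
    pb2 <- prelu_b(cache$g2z, p$dec2_a$a, eb$dx)
    g$dec2_a <- list(a = pb2$da)
    db2 <- deconv_b(cache$g1, p$dec2, pb2$dx)
    g$dec2 <- list(w = db2$dw, b = db2$db)
    pb1 <- prelu_b(cache$g1z, p$dec1_a$a, db2$dx)
    g$dec1_a <- list(a = pb1$da)
    db1 <- deconv_b(cache$m, p$dec1, pb1$dx)
    g$dec1 <- list(w = db1$dw, b = db1$db)
    mb <- conv_b(cache$m_in, p$merge, db1$dx)
    g$merge <- list(w = mb$dw, b = mb$db)
    d_eud <- mb$dx * cache$w_att
    d_watt <- mb$dx * cache$eud_out
    d_a <- d_watt * cache$w_att * (1 - cache$w_att)
    g$att <- vector("list", length(p$att))
    names(g$att) <- names(p$att)
    for (j in rev(seq_along(p$att))) {
      pbj <- prelu_b(cache$azs[[j]], p$att[[j]]$a, d_a)
      cbj <- conv_b(cache$ains[[j]], p$att[[j]]$conv, pbj$dx)
      g$att[[j]] <- list(conv = list(w = cbj$dw, b = cbj$db), a = pbj$da)
      d_a <- cbj$dx
    }
    eus <- udb_stack_bwd(d_eud, p$eudb, 100L)
    g$eudb <- eus$grads
    d_e2 <- eus$dx + d_a
    pe2 <- prelu_b(cache$e2z, p$enc2_a$a, d_e2)
    g$enc2_a <- list(a = pe2$da)
    ce2 <- conv_b(cache$e1, p$enc2, pe2$dx)
    g$enc2 <- list(w = ce2$dw, b = ce2$db)
    pe1 <- prelu_b(cache$e1z, p$enc1_a$a, ce2$dx)
    g$enc1_a <- list(a = pe1$da)
    ce1 <- conv_b(cache$i_edge, p$enc1, pe1$dx)
    g$enc1 <- list(w = ce1$dw, b = ce1$db)
    # i_edge feeds the composition (-d_out), the residual inside
    # i_edge_plus (+d_out, cancelling it) and the encoder
    d_edge <- ce1$dx
    d_inter <- d_inter + nn_lap_bwd(d_edge)
  } else {
    d_inter <- d_out
  }
  ob <- conv_b(cache$u, p$dout, d_inter)
  g$dout <- list(w = ob$dw, b = ob$db)
  dus <- udb_stack_bwd(ob$dx, p$dudb, 0L)
  g$dudb <- dus$grads
  p0 <- prelu_b(cache$z0, p$din_a$a, dus$dx)
  g$din_a <- list(a = p0$da)
  c0 <- conv_b(x, p$din, p0$dx)
  g$din <- list(w = c0$dw, b = c0$db)
  g[names(p)[names(p) %in% names(g)]]  # order like p where possible
}

#' Attention weights for an edge feature stack
#'
#' Runs the 6-layer attention block (3x3 convolutions with PReLU, closed by a
#' sigmoid that acts as a soft threshold) on encoder-domain features. All
#' outputs lie strictly in (0, 1).
#'
#' @param model an [EEDNModel-class] with `variant = "eedn"`
#' @param features numeric array `(H, W, edgeChannels, N)` (or a matrix for a
#'   single-channel single-frame input, for convenience)
#' @return array of gating weights with the spatial size of the input
#' @export
attentionWeights <- function(model, features) {
  stopifnot(is(model, "EEDNModel"))
  if (model@config@variant != "eedn")
    stop("attention weights exist only in the eedn variant")
  if (is.matrix(features))
    features <- array(features, c(dim(features), 1L, 1L))
  if (dim(features)[3] != model@config@edgeChannels)
    stop("feature stack must have ", model@config@edgeChannels, " channels")
  a_in <- features
  for (j in seq_along(model@params$att)) {
    a_in <- prelu_f(conv_f(a_in, model@params$att[[j]]$conv),
                    model@params$att[[j]]$a)
  }
  sigmoid_f(a_in)
}

#' @describeIn denoise denoise an ImageFrame
#'
#' The frame is normalized to \eqn{[0, 1]} by \eqn{2^n - 1}, padded by
#' replication to a multiple of 4 (the encoder's total downsampling) when
#' needed, passed through the network, cropped back, and rescaled to the
#' input intensity domain. The returned [ForwardTrace-class] satisfies
#' `iOutput == iInter + iEdgePlus - iEdge` exactly in the working precision.
#' @aliases denoise,EEDNModel,ImageFrame-method
#' @export
setMethod("denoise", signature("EEDNModel", "ImageFrame"), function(model, frame, ...) {
  maxv <- 2^frame@bitDepth - 1
  tr <- denoise_matrix(model, frame@pixels / maxv)
  new("ForwardTrace",
      iInter = tr$i_inter * maxv, iEdge = tr$i_edge * maxv,
      iEdgePlus = tr$i_edge_plus * maxv, iOutput = tr$i_output * maxv)
})

#' @describeIn denoise denoise a plain matrix already in \eqn{[0, 1]}
#' @aliases denoise,EEDNModel,matrix-method
#' @export
setMethod("denoise", signature("EEDNModel", "matrix"), function(model, frame, ...) {
  tr <- denoise_matrix(model, frame)
  new("ForwardTrace", iInter = tr$i_inter, iEdge = tr$i_edge,
      iEdgePlus = tr$i_edge_plus, iOutput = tr$i_output)
})

denoise_matrix <- function(model, m) {
  h <- nrow(m); w <- ncol(m)
  ph <- (4 - h %% 4) %% 4
  pw <- (4 - w %% 4) %% 4
  if (ph > 0) m <- rbind(m, m[rep(h, ph), , drop = FALSE])
  if (pw > 0) m <- cbind(m, m[, rep(w, pw), drop = FALSE])
  x <- array(m, c(dim(m), 1L, 1L))
  fw <- model_fwd(model@params, model@config, x)
  crop <- function(a) {
    if (is.null(a)) return(matrix(0, h, w))
    matrix(a, nrow(m), ncol(m))[seq_len(h), seq_len(w), drop = FALSE]
  }
  if (model@config@variant == "uddn") {
    ii <- crop(fw$i_inter)
    return(list(i_inter = ii, i_edge = matrix(0, h, w),
                i_edge_plus = matrix(0, h, w), i_output = ii))
  }
  list(i_inter = crop(fw$i_inter), i_edge = crop(fw$i_edge),
       i_edge_plus = crop(fw$i_edge_plus), i_output = crop(fw$i_output))
}

#' Save / load a model
#'
#' Checkpoints embed the full [ModelConfig-class] with the parameters.
#'
#' @param model an [EEDNModel-class]
#' @param path file path (RDS)
#' @return `loadModel` returns the [EEDNModel-class]
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "EEDNModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "EEDNModel")) stop("not a model checkpoint: ", path)
  m
}
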