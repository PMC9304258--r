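#' @include AllClasses.R layers.R model.R
NULL

#' Charbonnier loss
#'
#' The robust content loss \eqn{\sum_i \sqrt{(t_i - p_i)^2 + \epsilon^2}}, a
#' differentiable surrogate for the absolute error; the compensation
#' parameter \eqn{\epsilon} defaults to `1e-3`. `reduction = "sum"` sums over
#' every element (so identical inputs with k elements give exactly
#' \eqn{k\epsilon}); `"batchmean"` sums per-pixel means over the batch (last
#' array dimension), which makes learning-rate settings transfer across patch
#' sizes and is what [trainModel()] optimizes.
#'
#' @param pred,target numeric arrays of identical shape
#' @param epsilon compensation parameter (> 0)
#' @param reduction "sum" or "batchmean"
#' @return scalar loss
#' @examples
#' charbonnierLoss(matrix(0, 4, 4), matrix(0, 4, 4))  # 16 * 1e-3
#' @export
charbonnierLoss <- function(pred, target, epsilon = 1e-3,
                            reduction = c("sum", "batchmean")) {
  reduction <- match.arg(reduction)
  if (!all(dim(as.array(pred)) == dim(as.array(target))))
    stop("'pred' and 'target' must have identical shapes")
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  rho <- sqrt((as.numeric(target) - as.numeric(pred))^2 + epsilon^2)
  if (reduction == "sum") return(sum(rho))
  d <- dim(as.array(pred))
  per_item <- prod(d[-length(d)])
  sum(rho) / per_item
}

#' Learning-rate schedule
#'
#' The published step schedule: initialized to `lrInit` (1e-3) and halved
#' every `lrHalveEvery` (2000) steps, floored at `lrFloor` (1e-6):
#' `lr(step) = max(lrFloor, lrInit / 2^floor(step / lrHalveEvery))`.
#'
#' @param step step index (0-based)
#' @param config a [TrainConfig-class]
#' @return the learning rate at that step
#' @examples
#' lrSchedule(0, TrainConfig())      # 1e-3
#' lrSchedule(4000, TrainConfig())   # 2.5e-4
#' @export
lrSchedule <- function(step, config = TrainConfig()) {
  stopifnot(step >= 0)
  pmax(config@lrFloor, config@lrInit / 2^(step %/% config@lrHalveEvery))
}

#' Train a network with the Charbonnier loss
#'
#' Adam optimization (the schedule of [lrSchedule()] overrides the rate each
#' step) of the Charbonnier distance between the network output and the
#' clean target, on seeded shuffled batches from a [PatchDataset-class].
#' Patches are normalized to \eqn{[0, 1]} by the dataset bit depth. Training
#' aborts with a diagnostic error if the loss turns non-finite.
#'
#' @param model an [EEDNModel-class] (fresh from [buildModel()] or resumed)
#' @param dataset a [PatchDataset-class]
#' @param config a [TrainConfig-class]; `maxSteps = 0` returns the model
#'   unchanged
#' @param heldout optional list of `list(noisy = , clean = )` pairs of
#'   [ImageFrame-class] evaluated with [psnr()]/[ssim()] every
#'   `config@evalEvery` steps
#' @param checkpointPath optional path; the final model is written there with
#'   [saveModel()]
#' @return list with elements `model` ([EEDNModel-class]) and `history`
#'   ([TrainHistory-class])
#' @export
trainModel <- function(model, dataset, config = TrainConfig(),
                       heldout = NULL, checkpointPath = NULL) {
  stopifnot(is(model, "EEDNModel"), is(dataset, "PatchDataset"),
            is(config, "TrainConfig"))
  validObject(config)
  n <- dim(dataset@clean)[3]
  if (n < 1L) stop("empty training dataset")
  P <- dim(dataset@clean)[1]
  maxv <- 2^dataset@bitDepth - 1
  steps <- config@maxSteps
  hist_loss <- numeric(steps)
  hist_lr <- numeric(steps)
  ev_steps <- integer(0); ev_psnr <- numeric(0); ev_ssim <- numeric(0)
  if (steps == 0L) {
    return(list(model = model,
                history = new("TrainHistory", loss = numeric(0),
                              lr = numeric(0), evalSteps = integer(0),
                              evalPsnr = numeric(0), evalSsim = numeric(0))))
  }
  old <- local_rng_seed(config@seed)
  on.exit(restore_rng(old))
  p <- model@params
  m_st <- p_zero_like(p)
  v_st <- p_zero_like(p)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  t_adam <- 0
  perm <- sample.int(n)
  cursor <- 1L
  B <- config@batchSize
  for (step in seq_len(steps)) {
    if (cursor + B - 1L > n) { perm <- sample.int(n); cursor <- 1L }
    idx <- perm[cursor:(cursor + B - 1L)]
    cursor <- cursor + B
    x <- array(dataset@noisy[, , idx], c(P, P, 1L, B)) / maxv
    y <- array(dataset@clean[, , idx], c(P, P, 1L, B)) / maxv
    fw <- model_fwd(p, model@config, x, keep_cache = TRUE)
    diff <- fw$i_output - y
    root <- sqrt(diff^2 + config@epsilon^2)
    loss <- sum(root) / (P * P)           # batch sum of per-pixel means
    if (!is.finite(loss)) {
      if (!is.null(checkpointPath))
        saveModel(new("EEDNModel", config = model@config, params = p,
                      steps = model@steps + step - 1L), checkpointPath)
      stop("non-finite loss at step ", step,
           if (!is.null(checkpointPath)) " (diagnostic checkpoint written)" else "")
    }
    d_out <- diff / root / (P * P)
    grads <- model_bwd(p, model@config, x, fw$cache, d_out)
    lr <- lrSchedule(step - 1L, config)
    t_adam <- t_adam + 1
    corr <- sqrt(1 - beta2^t_adam) / (1 - beta1^t_adam)
    upd <- p_walk(p, grads, m_st, v_st, function(pp, gg, mm, vv) {
      mm <- beta1 * mm + (1 - beta1) * gg
      vv <- beta2 * vv + (1 - beta2) * gg^2
      pp <- pp - lr * corr * mm / (sqrt(vv) + adam_eps)
      list(p = pp, m = mm, v = vv)
    })
    p <- upd$params; m_st <- upd$m; v_st <- upd$v
    hist_loss[step] <- loss
    hist_lr[step] <- lr
    if (!is.null(heldout) && config@evalEvery > 0L &&
        step %% config@evalEvery == 0L) {
      mdl <- new("EEDNModel", config = model@config, params = p,
                 steps = model@steps + step)
      ps <- vapply(heldout, function(pair) {
        tr <- denoise(mdl, pair$noisy)
        out <- clipFrame(ImageFrame(tr@iOutput, bitDepth = pair$clean@bitDepth))
        c(psnr(out, pair$clean), ssim(out, pair$clean))
      }, numeric(2))
      ev_steps <- c(ev_steps, step)
      ev_psnr <- c(ev_psnr, mean(ps[1, ]))
      ev_ssim <- c(ev_ssim, mean(ps[2, ]))
    }
  }
  out_model <- new("EEDNModel", config = model@config, params = p,
                   steps = model@steps + steps)
  if (!is.null(checkpointPath)) saveModel(out_model, checkpointPath)
  list(model = out_model,
       history = new("TrainHistory", loss = hist_loss, lr = hist_lr,
                     evalSteps = ev_steps, evalPsnr = ev_psnr,
                     evalSsim = ev_ssim))
}

#' Desk-scale configurations
#'
#' A reduced problem size that exercises the full pipeline on a single CPU:
#' a tiny EEDN (1 denoiser + 1 edge UDB, growth 8, base width 16) trained
#' 500 steps on 2000 phantom patches. The architecture and schedule are
#' otherwise identical to the full-scale defaults.
#'
#' @param seed integer seed
#' @return `deskModelConfig`: a [ModelConfig-class]; `deskTrainConfig`: a
#'   [TrainConfig-class]
#' @export
deskModelConfig <- function(seed = 7L) {
  ModelConfig(variant = "eedn", nUdbsTotal = 2L, nUdbsDenoiser = 1L,
              nUdbsEdge = 1L, growthChannels = 8L, baseChannels = 16L,
              edgeChannels = 8L, seed = seed)
}

#' @rdname deskModelConfig
#' @export
deskTrainConfig <- function(seed = 7L) {
  TrainConfig(maxSteps = 500L, seed = seed)
}
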