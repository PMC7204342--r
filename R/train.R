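#' Training configuration
#'
#' Defaults follow the reference training recipe for this architecture:
#' Adam at learning rate 2e-4 for at most 150 epochs, batch size of a single
#' patch (large input tiles being preferred over large batches, with Adam's
#' high first-moment decay of 0.9 carrying momentum across samples),
#' Xavier-normal kernel initialization with zero biases, and the F-beta loss
#' at beta = 1.
#'
#' @param learning_rate Adam step size (default 2e-4).
#' @param max_epochs maximum training epochs (default 150).
#' @param beta F-beta recall weight (default 1).
#' @param batch_size training batch size (default 1).
#' @param loss_smooth smoothing constant of the training loss (default 0,
#'   the exact ratio; see \code{\link{fbeta_loss}}). The exact ratio has an
#'   identically zero gradient on empty-target patches, so background-only
#'   patches contribute no update -- the behaviour of the formula itself.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decays and epsilon.
#' @param augment apply right-angle rotation augmentation to each drawn
#'   patch (quadruples the per-epoch sample count).
#' @param per_epoch_n patches per class per epoch (default: minority pool
#'   size).
#' @param seed RNG seed controlling initialization and epoch resampling.
#' @return a \code{train_config}.
#' @export
train_config <- function(learning_rate = 2e-4, max_epochs = 150L, beta = 1,
                         batch_size = 1L, loss_smooth = 0,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, augment = TRUE,
                         per_epoch_n = NULL, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), beta = beta,
                 batch_size = as.integer(batch_size),
                 loss_smooth = loss_smooth,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, augment = isTRUE(augment),
                 per_epoch_n = per_epoch_n, seed = as.integer(seed)),
            class = "train_config")
}

adam_state <- function(params) {
  lapply(params, function(p) list(mw = p$w * 0, vw = p$w * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_update <- function(params, grads, state, t, cfg) {
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2; eps <- cfg$adam_eps
  lr <- cfg$learning_rate
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  for (nm in names(grads)) {
    s <- state[[nm]]
    s$mw <- b1 * s$mw + (1 - b1) * grads[[nm]]$w
    s$vw <- b2 * s$vw + (1 - b2) * grads[[nm]]$w^2
    s$mb <- b1 * s$mb + (1 - b1) * grads[[nm]]$b
    s$vb <- b2 * s$vb + (1 - b2) * grads[[nm]]$b^2
    params[[nm]]$w <- params[[nm]]$w -
      lr * (s$mw / corr1) / (sqrt(s$vw / corr2) + eps)
    params[[nm]]$b <- params[[nm]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# Gradient of the F-beta loss w.r.t. the two-class logits, via the softmax
# chain: only the mass-class probability enters the loss.
loss_logit_grad <- function(probs, target, beta, smooth = 0) {
  s <- probs[, , 2]
  gs <- fbeta_loss_grad(s, target, beta, smooth)
  gz_mass <- gs * s * (1 - s)
  glog <- array(0, dim(probs))
  glog[, , 2] <- gz_mass
  glog[, , 1] <- -gz_mass
  glog
}

#' Train the U-Net on a labelled patch set
#'
#' Runs up to \code{max_epochs} epochs. Every epoch draws a fresh balanced
#' sample of patches (same count per class), optionally expands it fourfold
#' by right-angle rotations, shuffles, and performs one Adam step per patch
#' (batch size 1) on the F-beta loss between the predicted mass-probability
#' heatmap and the centre-cropped patch mask. Patch intensities are
#' standardized (z-scored) by the training-set mean and standard deviation,
#' which are stored in the model and reapplied at prediction time.
#'
#' @param net a \code{\link{build_unet}} network.
#' @param patch_set a \code{\link{extract_patches}} result; patches must be
#'   at least \code{net$min_input} pixels square.
#' @param config a \code{\link{train_config}}.
#' @param verbose print the per-epoch loss.
#' @return a \code{unet_model}: list with \code{net}, \code{params},
#'   \code{config}, \code{norm_scale} and \code{loss_trace} (mean loss per
#'   epoch).
#' @export
train_unet <- function(net, patch_set, config = train_config(),
                       verbose = FALSE) {
  patches <- patch_set$patches
  psz <- dim(patches[[1]]$pixels)
  out_sz <- unet_output_size(net$spec, psz[1])
  if (is.na(out_sz))
    stop("patch size ", psz[1], " is inadmissible for this network; ",
         "minimum valid input is ", net$min_input)
  # class pools for balancing are built from the supervised output window:
  # with valid convolutions only the patch centre receives gradient, so a
  # patch whose mass lies entirely in the cropped margin trains as
  # background regardless of its whole-patch label
  labels <- vapply(patches, function(p) {
    ctr <- center_crop(p$target, c(out_sz, out_sz))
    if (mean(ctr) >= 0.05) "mass" else "nonmass"
  }, character(1))
  if (length(unique(labels)) < 2L) {
    # degenerate single-class dataset (e.g. a mass-free volume): balancing
    # is impossible, so draw from the one pool and let the loss speak
    warning("patch set contains a single class ('", labels[1],
            "'); training proceeds without class balancing")
    n_draw <- if (is.null(config$per_epoch_n))
      min(length(patches), 16L) else config$per_epoch_n
    sampler <- structure(list(pools = list(all = seq_along(patches)),
                              per_epoch_n = as.integer(n_draw),
                              seed = derive_seed(config$seed, "sampler")),
                         class = "epoch_sampler")
  } else {
    sampler <- epoch_sampler(labels, per_epoch_n = config$per_epoch_n,
                             seed = derive_seed(config$seed, "sampler"))
  }
  params <- unet_init(net, seed = derive_seed(config$seed, "init"))
  state <- adam_state(params)
  px_all <- unlist(lapply(patches, function(p) as.numeric(p$pixels)))
  norm_center <- mean(px_all)
  norm_scale <- max(stats::sd(px_all), 1e-12)
  rm(px_all)
  loss_trace <- numeric(0)
  t <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    idx <- resample_epoch(sampler, epoch)
    batch <- patches[idx]
    if (config$augment)
      batch <- unlist(lapply(batch, augment_rotations), recursive = FALSE)
    ord <- with_seed(derive_seed(config$seed, paste0("shuffle", epoch)),
                     sample.int(length(batch)))
    losses <- numeric(length(batch))
    for (i in seq_along(ord)) {
      p <- batch[[ord[i]]]
      x <- (p$pixels - norm_center) / norm_scale
      target <- center_crop(p$target, c(out_sz, out_sz))
      fw <- unet_forward(net, params, x, keep_cache = TRUE)
      losses[i] <- fbeta_loss(fw$probs[, , 2], target, config$beta,
                              config$loss_smooth)
      glog <- loss_logit_grad(fw$probs, target, config$beta,
                              config$loss_smooth)
      grads <- unet_backward(net, params, fw$cache, glog)
      t <- t + 1L
      upd <- adam_update(params, grads, state, t, config)
      params <- upd$params; state <- upd$state
    }
    loss_trace[epoch] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f", epoch, loss_trace[epoch]))
  }
  structure(list(net = net, params = params, config = config,
                 norm_center = norm_center, norm_scale = norm_scale,
                 loss_trace = loss_trace),
            class = "unet_model")
}

#' Pooled F-beta of a trained model over a patch set
#'
#' Runs the model on every patch (or a subsample), binarizes the predicted
#' mass probabilities at 0.5, and returns the pooled F-beta measure over all
#' supervised output windows -- the training-fit summary used in smoke
#' checks.
#'
#' @param model a \code{unet_model}.
#' @param patch_set the patch set to score.
#' @param beta recall weight (default 1).
#' @param max_patches optional cap on the number of patches scored (the
#'   mass/nonmass mix is preserved by taking every k-th patch).
#' @return scalar pooled F-beta.
#' @export
training_fbeta <- function(model, patch_set, beta = 1, max_patches = NULL) {
  patches <- patch_set$patches
  if (!is.null(max_patches) && length(patches) > max_patches)
    patches <- patches[seq(1, length(patches),
                           length.out = max_patches)]
  out_sz <- unet_output_size(model$net$spec, dim(patches[[1]]$pixels)[1])
  st <- 0; ssum <- 0; tsum <- 0
  for (p in patches) {
    fw <- unet_forward(model$net, model$params,
                       (p$pixels - model$norm_center) / model$norm_scale)
    s <- as.integer(fw$probs[, , 2] >= 0.5)
    t_ <- center_crop(p$target, c(out_sz, out_sz))
    st <- st + sum(s * t_); ssum <- ssum + sum(s); tsum <- tsum + sum(t_)
  }
  if (ssum + tsum == 0) return(1)
  (1 + beta^2) * st / (ssum + tsum)
}

#' Predict a mass-probability heatmap for a full stack
#'
#' Tiles each slice into the network's valid output windows (the fusion
#' grid), mirror-padding slice borders so every pixel receives a prediction,
#' runs the network per tile, and assembles a per-pixel mass-probability
#' volume. Also returns one probabilistic prediction per patch -- the mean
#' class-probability vector over the patch's output window together with its
#' grid position -- which is the input currency of the voting schemes.
#'
#' @param model a \code{\link{train_unet}} model.
#' @param stack a \code{slice_stack}.
#' @param input_size square tile input size; default the training patch
#'   admissible minimum of 1.5x the output, i.e. the model's training size
#'   is reused when possible. Must be admissible for the network.
#' @return list with \code{heatmap} (3D array of mass probabilities in
#'   [0, 1]; the background probability is its complement) and \code{preds}
#'   (data frame: slice, grid_row, grid_col, p_nonmass, p_mass, label).
#' @export
predict_heatmap <- function(model, stack, input_size = NULL) {
  net <- model$net
  if (is.null(input_size)) input_size <- net$min_input
  out_sz <- unet_output_size(net$spec, input_size)
  if (is.na(out_sz)) stop("inadmissible input_size ", input_size,
                          "; minimum valid input is ", net$min_input)
  v <- (stack$voxels - model$norm_center) / model$norm_scale
  d <- dim(v)
  margin <- (input_size - out_sz) / 2
  n_gr <- ceiling(d[1] / out_sz)
  n_gc <- ceiling(d[2] / out_sz)
  heat <- array(0, d)
  preds <- list()
  for (k in seq_len(d[3])) {
    pad <- mirror_pad(v[, , k], margin, margin + n_gr * out_sz - d[1],
                      margin, margin + n_gc * out_sz - d[2])
    for (gi in seq_len(n_gr))
      for (gj in seq_len(n_gc)) {
        r0 <- (gi - 1L) * out_sz + 1L
        c0 <- (gj - 1L) * out_sz + 1L
        tile <- pad[r0:(r0 + input_size - 1L), c0:(c0 + input_size - 1L)]
        fw <- unet_forward(net, model$params, tile)
        pm <- fw$probs[, , 2]
        rows <- r0:(min(r0 + out_sz - 1L, d[1]))
        cols <- c0:(min(c0 + out_sz - 1L, d[2]))
        heat[rows, cols, k] <- pm[seq_along(rows), seq_along(cols)]
        p_mass <- mean(fw$probs[, , 2])
        preds[[length(preds) + 1L]] <- data.frame(
          slice = k, grid_row = gi, grid_col = gj,
          p_nonmass = 1 - p_mass, p_mass = p_mass,
          label = if (p_mass > 0.5) 2L else 1L)
      }
  }
  list(heatmap = heat, preds = do.call(rbind, preds),
       grid = c(rows = n_gr, cols = n_gc))
}
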