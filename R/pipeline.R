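#' Run the full segmentation pipeline end-to-end
#'
#' Executes the eight stages in fixed order -- phantom (or load), preprocess,
#' patches, train, predict, fuse, postprocess, evaluate -- writing every
#' intermediate artifact plus a JSON manifest (stage, inputs, outputs, seed,
#' wall time, MD5 content hashes) under \code{out_dir}. Deterministic stages
#' reproduce their content hashes on rerun with the same config.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created).
#' @param stack,annotation optional pre-loaded input volume; when NULL a
#'   phantom is generated from \code{config$phantom}.
#' @return the manifest (invisibly a list), with \code{$metrics} holding the
#'   final evaluation.
#' @export
run_pipeline <- function(config, out_dir, stack = NULL, annotation = NULL) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  log_stage <- function(stage, inputs, outputs, t0) {
    hashes <- lapply(outputs, function(f)
      if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_)
    manifest[[stage]] <<- list(stage = stage, inputs = inputs,
                               outputs = outputs, hashes = hashes,
                               seed = derive_seed(config$seed, stage),
                               wall_time = round(as.numeric(
                                 Sys.time()) - t0, 3))
    message(sprintf("[%s] done (%.1fs)", stage,
                    manifest[[stage]]$wall_time))
  }

  # 1. phantom / load ---------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (is.null(stack)) {
    pc <- do.call(phantom_config, c(config$phantom,
                                    list(seed = derive_seed(config$seed,
                                                            "phantom"))))
    ph <- generate_phantom(pc)
    stack <- ph$stack; annotation <- ph$annotation
  }
  stack_path <- file.path(out_dir, "stack.tiff")
  write_stack(stack, stack_path)
  write_mask(annotation$mask, file.path(out_dir, "truth_mask"))
  write_boxes(annotation$boxes, file.path(out_dir, "boxes.csv"))
  log_stage("phantom", character(0),
            c(stack_path, file.path(out_dir, "boxes.csv")), t0)

  # 2. preprocess --------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  work <- stack
  if (isTRUE(config$preprocess$enabled)) {
    work <- preprocess_stack(stack,
                             r_close = config$preprocess$r_close,
                             r_open = config$preprocess$r_open,
                             sigma_mm = config$preprocess$sigma_mm,
                             exclusion_mm = config$preprocess$exclusion_mm,
                             seed = derive_seed(config$seed, "preprocess"))
  }
  enh_path <- file.path(out_dir, "enhanced.tiff")
  write_stack(work, enh_path)
  log_stage("preprocess", stack_path, enh_path, t0)

  # 3. patches -----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  pspec <- do.call(patch_spec, config$patches)
  net <- build_unet(do.call(unet_spec, config$model))
  out_sz <- unet_output_size(net$spec, pspec$patch_h)
  pad <- if (is.na(out_sz)) 0L else (pspec$patch_h - out_sz) %/% 2L
  pset <- extract_patches(work, annotation, pspec, pad = pad)
  man_path <- file.path(out_dir, "patch_manifest.csv")
  write.csv(pset$manifest, man_path, row.names = FALSE)
  log_stage("patches", enh_path, man_path, t0)

  # 4. train -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  tcfg <- do.call(train_config,
                  c(config$training,
                    list(seed = derive_seed(config$seed, "train"))))
  model <- train_unet(net, pset, tcfg)
  loss_path <- file.path(out_dir, "loss_trace.csv")
  write.csv(data.frame(epoch = seq_along(model$loss_trace),
                       loss = model$loss_trace), loss_path,
            row.names = FALSE)
  log_stage("train", man_path, loss_path, t0)

  # 5. predict -----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  pred <- predict_heatmap(model, work)
  heat_stack <- structure(list(voxels = pred$heatmap,
                               pixel_spacing = stack$pixel_spacing,
                               slice_spacing = stack$slice_spacing),
                          class = "slice_stack")
  heat_path <- file.path(out_dir, "heatmap.tiff")
  write_stack(heat_stack, heat_path)
  preds_path <- file.path(out_dir, "patch_predictions.csv")
  write.csv(pred$preds, preds_path, row.names = FALSE)
  log_stage("predict", loss_path, c(heat_path, preds_path), t0)

  # 6. fuse --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  votes <- lapply(seq_len(dim(stack$voxels)[3]), function(k) {
    pk <- pred$preds[pred$preds$slice == k, ]
    grid <- patch_grid(pred$grid["rows"], pred$grid["cols"])
    res <- fuse(as.matrix(pk[, c("p_nonmass", "p_mass")]), grid,
                config$fusion$scheme)
    data.frame(slice = k, label = res$label, scheme = res$scheme)
  })
  votes <- do.call(rbind, votes)
  votes_path <- file.path(out_dir, "slice_votes.csv")
  write.csv(votes, votes_path, row.names = FALSE)
  log_stage("fuse", preds_path, votes_path, t0)

  # 7. postprocess -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  seg <- postprocess_heatmap(pred$heatmap,
                             threshold = config$postprocess$threshold,
                             min_voxels = config$postprocess$min_voxels,
                             window = config$postprocess$window,
                             connectivity = config$postprocess$connectivity)
  seg_dir <- file.path(out_dir, "segmentation")
  write_mask(seg$mask, seg_dir)
  ct_path <- file.path(out_dir, "cluster_table.csv")
  write.csv(seg$cluster_table, ct_path, row.names = FALSE)
  log_stage("postprocess", heat_path,
            c(ct_path, file.path(seg_dir, "mask_0000.png")), t0)

  # 8. evaluate ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  counts <- confusion_from_masks(seg$mask, annotation$mask)
  met <- sen_spe_acc(counts)
  auc <- tryCatch(roc_auc(pred$heatmap, annotation$mask,
                          config$evaluate$n_thresholds)$auc,
                  error = function(e) NA_real_)
  metrics <- c(met, auc = auc, TP = counts$TP, FP = counts$FP,
               TN = counts$TN, FN = counts$FN)
  met_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(as.list(metrics), met_path, auto_unbox = TRUE,
                       digits = NA)
  log_stage("evaluate", ct_path, met_path, t0)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  out <- manifest
  out$metrics <- metrics
  out$votes <- votes
  invisible(out)
}
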