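#' Voxel-wise confusion counts between predicted and true masks
#'
#' @param predicted,truth congruent 3D (or 2D) binary arrays.
#' @return a \code{confusion_counts} list with TP, FP, TN, FN; the four sum
#'   to the voxel count.
#' @export
confusion_from_masks <- function(predicted, truth) {
  if (!all(dim(predicted) == dim(truth)))
    stop("shape mismatch between predicted and truth masks")
  p <- predicted > 0; t <- truth > 0
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 TN = sum(!p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' \deqn{Sen = TP/(TP+FN), \quad Spe = TN/(TN+FP), \quad
#'  Acc = (TP+TN)/(TP+TN+FP+FN).}
#' A metric whose denominator is zero is undefined and reported as
#' \code{NA}, never silently 0 or 1.
#'
#' @param counts a \code{\link{confusion_from_masks}} result (or a list with
#'   TP/FP/TN/FN).
#' @return named numeric vector \code{c(sen, spe, acc)}.
#' @export
sen_spe_acc <- function(counts) {
  with(counts, {
    total <- TP + TN + FP + FN
    c(sen = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
      spe = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
      acc = if (total > 0) (TP + TN) / total else NA_real_)
  })
}

#' ROC curve and AUC by threshold sweep over a heatmap
#'
#' Sweeps the binarization threshold over the sorted unique heatmap scores
#' (optionally subsampled to \code{n_thresholds}), computes
#' (1 - specificity, sensitivity) at each cut, and integrates the curve by
#' the trapezoidal rule. With the full threshold set this equals the
#' rank-statistic (Mann-Whitney) AUC exactly. The heatmap must be the
#' pre-postprocessing probability volume: thresholding or cluster filtering
#' first would destroy the score ordering.
#'
#' @param heatmap array of scores in [0, 1].
#' @param truth congruent binary array; must contain both classes.
#' @param n_thresholds maximum number of thresholds (default: all unique
#'   scores).
#' @return list with \code{roc} (data frame: threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
roc_auc <- function(heatmap, truth, n_thresholds = NULL) {
  if (!all(dim(heatmap) == dim(truth)))
    stop("shape mismatch between heatmap and truth")
  y <- as.logical(truth > 0)
  s <- as.numeric(heatmap)
  if (all(y) || !any(y))
    stop("AUC undefined: truth contains a single class")
  thr <- sort(unique(s), decreasing = TRUE)
  if (!is.null(n_thresholds) && is.finite(n_thresholds) &&
      length(thr) > n_thresholds)
    thr <- thr[unique(round(seq(1, length(thr), length.out = n_thresholds)))]
  np <- sum(y); nn <- sum(!y)
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]; ss <- s[ord]
  cum_tp <- cumsum(ys); cum_fp <- cumsum(!ys)
  last <- cumsum(rle(ss)$lengths)          # index of last tied score
  tpr <- c(0, cum_tp[last] / np, 1)
  fpr <- c(0, cum_fp[last] / nn, 1)
  keep_thr <- rle(ss)$values
  if (!is.null(n_thresholds) && is.finite(n_thresholds)) {
    sel <- keep_thr %in% thr
    tpr <- c(0, (cum_tp[last] / np)[sel], 1)
    fpr <- c(0, (cum_fp[last] / nn)[sel], 1)
    keep_thr <- keep_thr[sel]
  }
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(threshold = c(Inf, keep_thr, -Inf),
                        fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Cross-site experiment plan
#'
#' The six train-test combinations over two sites: same-site (H1->H1,
#' H2->H2), cross-site (H1->H2, H2->H1) and pooled (H1+H2 -> H1, H1+H2 ->
#' H2), each under k-fold cross-validation. Folds partition volumes (never
#' slices or patches), so no slice of a test volume can leak into training.
#'
#' @param sites site identifiers (default c("H1", "H2")).
#' @param folds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return an \code{experiment_plan} with the \code{combos} data frame.
#' @export
experiment_plan <- function(sites = c("H1", "H2"), folds = 5L, seed = 1L) {
  stopifnot(length(sites) == 2)
  combos <- data.frame(
    train = c(sites[1], sites[2], sites[1], sites[2], "both", "both"),
    test = c(sites[1], sites[2], sites[2], sites[1], sites[1], sites[2]))
  structure(list(sites = sites, combos = combos, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

# Random fold assignment of n volumes into k folds, every fold nonempty.
fold_assignment <- function(n, k, seed) {
  if (n < k) stop("fewer volumes (", n, ") than folds (", k, ")")
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' Run the cross-site cross-validation experiment
#'
#' For every train-test combination and fold: trains a fresh model on the
#' training volumes' patches (the test fold of every involved site is
#' excluded, so train and test sets are volume-disjoint and the pooled and
#' cross-site combos use the same per-site training folds), predicts
#' heatmaps for the held-out volumes, postprocesses, and scores voxel-wise
#' Sen/Spe/Acc plus AUC on the pooled held-out voxels.
#'
#' @param plan an \code{\link{experiment_plan}}.
#' @param datasets named list (one entry per site) of volume lists; each
#'   volume is a list with \code{stack} and \code{annotation}.
#' @param net a \code{\link{build_unet}} network (shared architecture).
#' @param pspec a \code{\link{patch_spec}}.
#' @param config a \code{\link{train_config}}.
#' @param preprocess logical: run the enhancement chain before patch
#'   extraction and prediction.
#' @param postprocess_args list of \code{\link{postprocess_heatmap}}
#'   arguments.
#' @return a \code{metrics_report}: list with \code{results} (per
#'   combo/fold data frame of sen, spe, acc, auc), \code{summary} (mean and
#'   SD per combo) and \code{folds} (the per-site fold assignments).
#' @export
run_experiment <- function(plan, datasets, net, pspec, config,
                           preprocess = FALSE,
                           postprocess_args = list(min_voxels = 50L)) {
  sites <- plan$sites
  folds <- lapply(seq_along(sites), function(i)
    fold_assignment(length(datasets[[sites[i]]]), plan$folds,
                    derive_seed(plan$seed, paste0("fold", sites[i]))))
  names(folds) <- sites
  prep <- function(stack) if (preprocess) preprocess_stack(stack) else stack
  rows <- list()
  for (ci in seq_len(nrow(plan$combos))) {
    combo <- plan$combos[ci, ]
    train_sites <- if (combo$train == "both") sites else combo$train
    for (f in seq_len(plan$folds)) {
      test_idx <- which(folds[[combo$test]] == f)
      train_vols <- list()
      for (s in train_sites) {
        keep <- which(folds[[s]] != f)
        train_vols <- c(train_vols, datasets[[s]][keep])
      }
      out_sz <- unet_output_size(net$spec, pspec$patch_h)
      pad <- if (is.na(out_sz)) 0L else (pspec$patch_h - out_sz) %/% 2L
      train_sets <- lapply(train_vols, function(v)
        extract_patches(prep(v$stack), v$annotation, pspec, pad = pad))
      all_patches <- unlist(lapply(train_sets, function(s) s$patches),
                            recursive = FALSE)
      merged <- structure(list(patches = all_patches,
                               manifest = do.call(rbind, lapply(
                                 train_sets, function(s) s$manifest)),
                               grid = train_sets[[1]]$grid),
                          class = "patch_set")
      cfg <- config
      cfg$seed <- derive_seed(config$seed, paste0("combo", ci, "fold", f))
      model <- train_unet(net, merged, cfg)
      counts <- list(TP = 0, FP = 0, TN = 0, FN = 0)
      scores <- c(); truths <- c()
      for (vi in test_idx) {
        vol <- datasets[[combo$test]][[vi]]
        ph <- predict_heatmap(model, prep(vol$stack))
        seg <- do.call(postprocess_heatmap, c(list(ph$heatmap),
                                              postprocess_args))
        cc <- confusion_from_masks(seg$mask, vol$annotation$mask)
        for (nm in names(counts)) counts[[nm]] <- counts[[nm]] + cc[[nm]]
        scores <- c(scores, as.numeric(ph$heatmap))
        truths <- c(truths, as.numeric(vol$annotation$mask))
      }
      met <- sen_spe_acc(counts)
      auc <- tryCatch(roc_auc(array(scores), array(truths))$auc,
                      error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        train = combo$train, test = combo$test, fold = f,
        sen = met["sen"], spe = met["spe"], acc = met["acc"], auc = auc,
        row.names = NULL)
    }
  }
  results <- do.call(rbind, rows)
  summ <- aggregate(cbind(sen, spe, acc, auc) ~ train + test, data = results,
                    FUN = function(x) c(mean = mean(x), sd = sd(x)),
                    na.action = stats::na.pass)
  structure(list(results = results, summary = summ, folds = folds,
                 plan = plan),
            class = "metrics_report")
}

#' Write a metrics report as CSV and JSON
#'
#' The per-combo/per-fold results go to \code{results.csv}, the per-combo
#' mean and SD summary to \code{summary.json}.
#'
#' @param report a \code{\link{run_experiment}} result.
#' @param path output directory (created).
#' @return \code{path}, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$results, file.path(path, "results.csv"),
            row.names = FALSE)
  summ <- lapply(seq_len(nrow(report$summary)), function(i) {
    row <- report$summary[i, ]
    list(train = row$train, test = row$test,
         sen = as.list(setNames(as.numeric(row$sen), c("mean", "sd"))),
         spe = as.list(setNames(as.numeric(row$spe), c("mean", "sd"))),
         acc = as.list(setNames(as.numeric(row$acc), c("mean", "sd"))),
         auc = as.list(setNames(as.numeric(row$auc), c("mean", "sd"))))
  })
  jsonlite::write_json(summ, file.path(path, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
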