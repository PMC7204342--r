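test_that("confusion counts tally voxels cell by cell", {
  p <- array(c(1, 1, 0, 0), c(2, 2, 1))
  t_ <- array(c(1, 0, 1, 0), c(2, 2, 1))
  cc <- confusion_from_masks(p, t_)
  expect_equal(unlist(cc[c("TP", "FP", "FN", "TN")]),
               c(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  same <- confusion_from_masks(t_, t_)
  expect_equal(same$FP + same$FN, 0)
  inv <- confusion_from_masks(1 - t_, t_)
  expect_equal(inv$TP + inv$TN, 0)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 4)
  expect_error(confusion_from_masks(array(0, c(2, 2, 1)),
                                    array(0, c(2, 2, 2))), "mismatch")
})

test_that("Sen/Spe/Acc are the three defining ratios, NA when undefined", {
  m <- sen_spe_acc(list(TP = 2, FN = 2, TN = 3, FP = 1))
  expect_equal(unname(m), c(0.5, 0.75, 0.625))
  perfect <- sen_spe_acc(list(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1))
  nopos <- sen_spe_acc(list(TP = 0, FN = 0, TN = 5, FP = 1))
  expect_true(is.na(nopos["sen"]))
  expect_equal(unname(nopos["spe"]), 5 / 6)
  expect_false(is.na(nopos["acc"]))
})

test_that("threshold-sweep AUC equals the rank-statistic AUC", {
  truth <- array(c(rep(1, 30), rep(0, 70)), c(10, 10, 1))
  sep <- array(ifelse(truth > 0, runif(100, 0.6, 1), runif(100, 0, 0.4)),
               dim(truth))
  expect_equal(roc_auc(sep, truth)$auc, 1)
  expect_equal(roc_auc(1 - sep, truth)$auc, 0)

  set.seed(44)
  n <- 1e4
  truth <- array(rbinom(n, 1, 0.3), c(100, 100, 1))
  score <- array(runif(n), dim(truth))
  ra <- roc_auc(score, truth)
  expect_equal(ra$auc, oracle_rank_auc(as.numeric(score),
                                       as.numeric(truth)),
               tolerance = 1e-9)
  expect_lt(abs(ra$auc - 0.5), 0.02)

  # ties must be handled identically in both formulations
  tied <- array(round(score * 10) / 10, dim(truth))
  expect_equal(roc_auc(tied, truth)$auc,
               oracle_rank_auc(as.numeric(tied), as.numeric(truth)),
               tolerance = 1e-9)

  expect_error(roc_auc(score, array(1, dim(truth))), "single class")
})

test_that("experiment plans enumerate the six combos with volume-level folds", {
  plan <- experiment_plan(folds = 5, seed = 2)
  expect_equal(nrow(plan$combos), 6)
  expect_setequal(paste(plan$combos$train, plan$combos$test),
                  c("H1 H1", "H2 H2", "H1 H2", "H2 H1",
                    "both H1", "both H2"))
  f1 <- dbtseg:::fold_assignment(10, 5, seed = 3)
  f2 <- dbtseg:::fold_assignment(10, 5, seed = 3)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:5)
  expect_true(all(table(f1) == 2))
  expect_error(dbtseg:::fold_assignment(3, 5, seed = 1), "fewer volumes")
})

test_that("metrics reports serialize to CSV results and JSON summary", {
  results <- data.frame(train = rep(c("H1", "H2"), each = 2),
                        test = rep(c("H1", "H2"), each = 2),
                        fold = c(1, 2, 1, 2),
                        sen = c(0.8, 0.9, 0.7, 0.75),
                        spe = c(0.95, 0.9, 0.99, 0.97),
                        acc = c(0.9, 0.91, 0.93, 0.94),
                        auc = c(0.95, 0.96, 0.92, 0.93))
  summ <- aggregate(cbind(sen, spe, acc, auc) ~ train + test,
                    data = results,
                    FUN = function(x) c(mean = mean(x), sd = sd(x)))
  rep_ <- structure(list(results = results, summary = summ),
                    class = "metrics_report")
  d <- tempfile()
  write_metrics_report(rep_, d)
  back <- read.csv(file.path(d, "results.csv"))
  expect_equal(back$sen, results$sen)
  js <- jsonlite::read_json(file.path(d, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(nrow(js), 2)
  expect_equal(js$sen$mean, c(0.85, 0.725))
})
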