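# class labels here are 1-based indices; "class 1" plays the role of the
# lowest-index tie-break winner throughout

probs_from_labels <- function(labels, K = 2) {
  t(vapply(labels, function(l) {
    p <- rep(0.1 / (K - 1), K); p[l] <- 0.9; p / sum(p)
  }, numeric(K)))
}

test_that("worked examples of all four schemes reproduce by hand", {
  p <- probs_from_labels(c(1, 1, 2))
  expect_equal(majority_vote(p)$label, 1L)
  expect_equal(majority_vote(p)$tallies$v, c(2, 1))

  expect_equal(max_probability(rbind(c(0.9, 0.1)))$label, 1L)
  m <- rbind(c(0.6, 0.4), c(0.3, 0.7))
  expect_equal(max_probability(m)$label, 2L)
  expect_equal(sum_probabilities(m)$label, 2L)
  expect_equal(sum_probabilities(rbind(c(0.6, 0.4)))$label,
               max_probability(rbind(c(0.6, 0.4)))$label)

  # ties resolve to the lowest class index
  expect_equal(majority_vote(probs_from_labels(c(1, 2)))$label, 1L)
  u <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(max_probability(u)$label, 1L)
  expect_equal(sum_probabilities(u)$label, 1L)

  # 2x2 grid, labels [[1,1],[1,2]]: the three class-1 patches are pairwise
  # adjacent -> c_1 = 6 ordered pairs, scores (18, 0)
  g22 <- patch_grid(2, 2)
  p22 <- probs_from_labels(c(1, 1, 1, 2))
  cv <- connectivity_vote(p22, g22)
  expect_equal(cv$label, 1L)
  expect_equal(cv$tallies$c, c(6, 0))
  expect_equal(cv$tallies$v, c(3, 1))

  # 1x2 grid with disagreeing labels: no connection, majority fallback, tie
  cv2 <- connectivity_vote(probs_from_labels(c(1, 2)), patch_grid(1, 2))
  expect_equal(cv2$label, 1L)
  expect_match(cv2$scheme, "fallback")
})

test_that("all schemes agree with brute-force enumeration on random grids", {
  set.seed(77)
  for (rep in 1:500) {
    rows <- sample(1:5, 1); cols <- sample(1:5, 1)
    K <- sample(2:3, 1)
    n <- rows * cols
    probs <- matrix(runif(n * K), n, K)
    probs <- probs / rowSums(probs)
    ref <- oracle_votes(probs, rows, cols)
    grid <- patch_grid(rows, cols)
    expect_equal(majority_vote(probs, K)$label, ref$majority)
    expect_equal(max_probability(probs, K)$label, ref$max_prob)
    expect_equal(sum_probabilities(probs, K)$label, ref$sum_prob)
    cv <- connectivity_vote(probs, grid, K)
    expect_equal(cv$label, ref$connectivity)
    # connection counts: even (ordered-pair symmetry) and bounded
    expect_true(all(ref$c %% 2 == 0))
    expect_true(all(ref$c <= ref$v * pmax(ref$v - 1, 0)))
    expect_true(all(ref$c <= 8 * ref$v))
    # normalizing by the constant sum of counts cannot change the argmax
    if (any(ref$c > 0)) {
      norm_score <- (ref$c * ref$v) / sum(ref$c)
      expect_equal(which.max(norm_score), which.max(ref$c * ref$v))
    }
  }
})

test_that("unanimous patches make every scheme agree", {
  set.seed(5)
  for (k in 1:2) {
    p <- probs_from_labels(rep(k, 6))
    g <- patch_grid(2, 3)
    labs <- c(majority_vote(p)$label, max_probability(p)$label,
              sum_probabilities(p)$label, connectivity_vote(p, g)$label,
              fuse(p, g, "connectivity")$label)
    expect_true(all(labs == k))
  }
})

test_that("dispatch validates scheme names and input alignment", {
  p <- probs_from_labels(c(1, 1, 2))
  expect_equal(fuse(p, scheme = "majority")$label, 1L)
  expect_error(fuse(p, scheme = "plurality"), "valid schemes")
  expect_error(fuse(p, scheme = "connectivity"), "patch_grid")
  expect_error(connectivity_vote(p, patch_grid(2, 2)), "misaligned")
  expect_error(majority_vote(matrix(numeric(0), 0, 2)), "empty")
})
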