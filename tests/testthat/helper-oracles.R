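# Independent brute-force oracles used across the suite. Each is a direct,
# unoptimized transcription of the defining rule, deliberately sharing no
# code with the package implementation.

# Grayscale dilation/erosion with a binary structuring element, by explicit
# neighbourhood scan (out-of-image treated as not in the window).
oracle_dilate <- function(img, se) {
  r <- (dim(se) - 1) / 2
  out <- img
  for (i in seq_len(nrow(img)))
    for (j in seq_len(ncol(img))) {
      best <- -Inf
      for (di in -r[1]:r[1])
        for (dj in -r[2]:r[2]) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || jj < 1 || ii > nrow(img) || jj > ncol(img)) next
          if (se[di + r[1] + 1, dj + r[2] + 1] > 0)
            best <- max(best, img[ii, jj])
        }
      out[i, j] <- best
    }
  out
}

oracle_erode <- function(img, se) -oracle_dilate(-img, se)

oracle_tophat <- function(img, r_close, r_open) {
  kc <- EBImage::makeBrush(2 * r_close + 1, "disc")
  ko <- EBImage::makeBrush(2 * r_open + 1, "disc")
  closed <- oracle_erode(oracle_dilate(img, kc), kc)
  opened <- oracle_dilate(oracle_erode(closed, ko), ko)
  out <- img - pmin(opened, img)
  out[out < 0] <- 0
  out
}

# Greedy exclusion selection with an explicit pick order.
oracle_select <- function(marks, r_px, order) {
  pool <- order
  keep <- integer(0)
  while (length(pool)) {
    pick <- pool[1]
    keep <- c(keep, pick)
    d <- sqrt((marks[pool, 1] - marks[pick, 1])^2 +
              (marks[pool, 2] - marks[pick, 2])^2)
    pool <- pool[d > r_px]
  }
  sort(keep)
}

# Brute-force voting: enumerate every rule literally.
oracle_votes <- function(probs, rows, cols) {
  n <- nrow(probs); K <- ncol(probs)
  lab <- integer(n)
  for (i in seq_len(n)) lab[i] <- which(probs[i, ] == max(probs[i, ]))[1]
  v <- sapply(seq_len(K), function(k) sum(lab == k))
  maj <- which(v == max(v))[1]
  mx <- sapply(seq_len(K), function(k) max(probs[, k]))
  mp <- which(mx == max(mx))[1]
  sm <- colSums(probs)
  sp <- which(sm == max(sm))[1]
  # connectivity: ordered pairs of 8-adjacent patches with equal labels
  ck <- integer(K)
  pos <- cbind(rep(seq_len(rows), cols), rep(seq_len(cols), each = rows))
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      if (i == j) next
      if (max(abs(pos[i, ] - pos[j, ])) == 1 && lab[i] == lab[j])
        ck[lab[i]] <- ck[lab[i]] + 1L
    }
  score <- ck * v
  cv <- if (all(score == 0)) maj else which(score == max(score))[1]
  list(majority = maj, max_prob = mp, sum_prob = sp, connectivity = cv,
       v = v, c = ck)
}

# Flood-fill connected components (26-neighbourhood) by recursive scan.
oracle_cluster_sizes <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  sizes <- integer(0)
  for (s0 in which(mask > 0)) {
    if (seen[s0]) next
    frontier <- s0
    seen[s0] <- TRUE
    size <- 0L
    while (length(frontier)) {
      v <- frontier[1]; frontier <- frontier[-1]
      size <- size + 1L
      k <- (v - 1) %/% (d[1] * d[2])
      r <- (v - 1) %% d[1]
      c <- ((v - 1) %/% d[1]) %% d[2]
      for (dk in -1:1) for (dc in -1:1) for (dr in -1:1) {
        if (!dr && !dc && !dk) next
        rr <- r + dr; cc <- c + dc; kk <- k + dk
        if (rr < 0 || cc < 0 || kk < 0 ||
            rr >= d[1] || cc >= d[2] || kk >= d[3]) next
        nv <- rr + d[1] * cc + d[1] * d[2] * kk + 1
        if (mask[nv] > 0 && !seen[nv]) {
          seen[nv] <- TRUE
          frontier <- c(frontier, nv)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Rank-statistic (Mann-Whitney) AUC with midranks for ties.
oracle_rank_auc <- function(scores, labels) {
  r <- rank(scores)
  np <- sum(labels > 0); nn <- sum(labels == 0)
  (sum(r[labels > 0]) - np * (np + 1) / 2) / (np * nn)
}

# Small standard phantom shared by several tests.
tiny_phantom <- function(seed = 7, n_slices = 6, hw = 64, n_masses = 1) {
  generate_phantom(phantom_config(n_slices = n_slices, height = hw,
                                  width = hw, n_masses = n_masses,
                                  mass_radius_range = c(3, 6),
                                  site_profile = "H1", seed = seed))
}
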