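#' Patch adjacency grid
#'
#' Describes the rows x cols layout of per-slice patches and the
#' 8-connectivity neighbourhoods (including diagonals) used by the
#' connectivity voting scheme.
#'
#' @param rows,cols grid dimensions.
#' @return a \code{patch_grid}: list with \code{shape} and \code{adjacency}
#'   (per patch, the indices of its neighbours; symmetric).
#' @export
patch_grid <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  idx <- function(r, c) (c - 1L) * rows + r
  adjacency <- vector("list", n)
  for (c in seq_len(cols))
    for (r in seq_len(rows)) {
      nb <- integer(0)
      for (dc in -1:1)
        for (dr in -1:1) {
          if (!dr && !dc) next
          rr <- r + dr; cc <- c + dc
          if (rr >= 1 && rr <= rows && cc >= 1 && cc <= cols)
            nb <- c(nb, idx(rr, cc))
        }
      adjacency[[idx(r, c)]] <- nb
    }
  structure(list(shape = c(rows = rows, cols = cols), adjacency = adjacency),
            class = "patch_grid")
}

# probs: n x K matrix; labels: argmax with lowest-index tie-break.
labels_from_probs <- function(probs) {
  apply(probs, 1, function(p) which(p == max(p))[1])
}

vote_result <- function(label, tallies, scheme)
  structure(list(label = as.integer(label), tallies = tallies,
                 scheme = scheme), class = "vote_result")

check_preds <- function(probs) {
  if (is.null(probs) || NROW(probs) == 0)
    stop("empty prediction set: at least one patch prediction is required")
  as.matrix(probs)
}

#' Majority voting over patch predictions
#'
#' Counts \eqn{v_k}, the number of patches whose hard label is class
#' \eqn{k}, and returns the most common label. Ties break toward the lowest
#' class index (documented convention; ties are not otherwise specified).
#'
#' @param probs n x K matrix of per-patch class probabilities (rows sum
#'   to 1).
#' @param K number of classes (default \code{ncol(probs)}).
#' @return a \code{vote_result}: \code{label} (1-based class index),
#'   \code{tallies} (\code{v} counts), \code{scheme}.
#' @export
majority_vote <- function(probs, K = ncol(probs)) {
  probs <- check_preds(probs)
  l <- labels_from_probs(probs)
  v <- tabulate(l, nbins = K)
  vote_result(which.max(v), list(v = v), "majority")
}

#' Maximum-probability voting
#'
#' The patch with the highest class probability decides the label:
#' \eqn{\tilde k = \arg\max_k \max_i p_i[k]}.
#'
#' @inheritParams majority_vote
#' @export
max_probability <- function(probs, K = ncol(probs)) {
  probs <- check_preds(probs)
  m <- apply(probs, 2, max)
  vote_result(which.max(m), list(max_prob = m), "max_prob")
}

#' Sum-of-probabilities voting
#'
#' Class probabilities are summed over patches and the largest sum wins:
#' \eqn{\tilde k = \arg\max_k \sum_i p_i[k]}.
#'
#' @inheritParams majority_vote
#' @export
sum_probabilities <- function(probs, K = ncol(probs)) {
  probs <- check_preds(probs)
  s <- colSums(probs)
  vote_result(which.max(s), list(sum_prob = s), "sum_prob")
}

#' Connectivity voting
#'
#' Reinforces spatial consistency: \eqn{c_k} counts the ordered pairs of
#' 8-adjacent patches that share hard label \eqn{k}, and the winning class
#' maximizes \eqn{c_k v_k} (the normalization by \eqn{\sum_{k'} c_{k'}} is
#' constant in \eqn{k} and cannot change the argmax). Counting ordered
#' pairs doubles every undirected connection for all classes alike, so the
#' argmax is convention-independent. When no adjacent pair agrees at all
#' (all \eqn{c_k = 0}) the scheme falls back to majority voting.
#'
#' @inheritParams majority_vote
#' @param grid a \code{\link{patch_grid}} aligned with the prediction rows
#'   (patch i at grid position (r, c) with index (c-1)*rows + r).
#' @export
connectivity_vote <- function(probs, grid, K = ncol(probs)) {
  probs <- check_preds(probs)
  if (nrow(probs) != length(grid$adjacency))
    stop("prediction set and patch grid are misaligned (",
         nrow(probs), " patches vs grid of ", length(grid$adjacency), ")")
  l <- labels_from_probs(probs)
  v <- tabulate(l, nbins = K)
  ck <- integer(K)
  for (i in seq_along(l))
    for (j in grid$adjacency[[i]])
      if (l[i] == l[j]) ck[l[i]] <- ck[l[i]] + 1L
  score <- ck * v
  if (all(score == 0)) {
    out <- majority_vote(probs, K)
    out$tallies$c <- ck
    out$scheme <- "connectivity(majority fallback)"
    return(out)
  }
  vote_result(which.max(score), list(v = v, c = ck, score = score),
              "connectivity")
}

#' Fuse patch predictions into one image label
#'
#' Dispatches to one of the four voting schemes.
#'
#' @inheritParams connectivity_vote
#' @param scheme one of \code{"majority"}, \code{"max_prob"},
#'   \code{"sum_prob"}, \code{"connectivity"}.
#' @export
fuse <- function(probs, grid = NULL, scheme = "max_prob", K = ncol(probs)) {
  schemes <- c("majority", "max_prob", "sum_prob", "connectivity")
  if (!scheme %in% schemes)
    stop("unknown voting scheme '", scheme, "'; valid schemes: ",
         paste(schemes, collapse = ", "))
  switch(scheme,
         majority = majority_vote(probs, K),
         max_prob = max_probability(probs, K),
         sum_prob = sum_probabilities(probs, K),
         connectivity = {
           if (is.null(grid)) stop("connectivity voting requires a patch_grid")
           connectivity_vote(probs, grid, K)
         })
}
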