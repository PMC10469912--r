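# Compact implementation of the UMAP algorithm (cosine k-nearest-neighbour
# graph, smooth-kNN bandwidth calibration, fuzzy set union, spectral
# initialization, vectorized stochastic gradient optimization). Written for
# the moderate cohort sizes of this package (exact kNN via a dense distance
# matrix).

pairwise_distances <- function(x, metric) {
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(x^2))
    nrm[nrm < 1e-12] <- 1e-12
    s <- (x / nrm) %*% t(x / nrm)
    d <- 1 - s
    d[d < 0] <- 0
  } else {
    d <- as.matrix(stats::dist(x))
  }
  diag(d) <- 0
  d
}

smooth_knn_weights <- function(dists, k) {
  # dists: n x k matrix of neighbor distances, ascending
  n <- nrow(dists)
  target <- log2(k)
  w <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- dists[i, ]
    pos <- d[d > 0]
    rho <- if (length(pos) > 0) min(pos) else 0
    lo <- 0; hi <- Inf; sigma <- 1
    for (it in 1:64) {
      val <- sum(exp(-pmax(0, d - rho) / sigma))
      if (abs(val - target) < 1e-5) break
      if (val > target) { hi <- sigma; sigma <- (lo + hi) / 2 }
      else { lo <- sigma; sigma <- if (is.finite(hi)) (lo + hi) / 2 else sigma * 2 }
    }
    w[i, ] <- exp(-pmax(0, d - rho) / sigma)
  }
  w
}

fit_ab <- function(min_dist, spread = 1) {
  xs <- seq(1e-3, 3 * spread, length.out = 300)
  target <- ifelse(xs < min_dist, 1, exp(-(xs - min_dist) / spread))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    sum((1 / (1 + a * xs^(2 * b)) - target)^2)
  }
  p <- stats::optim(c(log(1.6), log(0.9)), obj, method = "BFGS")$par
  c(a = exp(p[1]), b = exp(p[2]))
}

spectral_init <- function(p_sym) {
  deg <- rowSums(p_sym)
  deg[deg < 1e-12] <- 1e-12
  dinv <- 1 / sqrt(deg)
  lap <- diag(nrow(p_sym)) - (dinv * p_sym) %*% diag(dinv)
  eig <- eigen((lap + t(lap)) / 2, symmetric = TRUE)
  n <- nrow(p_sym)
  emb <- eig$vectors[, c(n - 1L, n - 2L), drop = FALSE]
  scale_f <- max(abs(emb))
  if (scale_f < 1e-12) scale_f <- 1
  10 * emb / scale_f
}

#' UMAP embedding of residual features
#'
#' Two-dimensional UMAP embedding with a local neighbourhood size of `k = 15`,
#' cosine distances in the high-dimensional space, and an effective minimal
#' distance between embedded points of `1e-6` (the package's defaults match
#' the visualization settings of the study). The implementation follows the
#' UMAP algorithm: exact k-nearest-neighbour graph, per-point bandwidths
#' calibrated so each point's fuzzy neighbourhood has cardinality log2(k),
#' probabilistic t-conorm symmetrization, spectral initialization from the
#' graph Laplacian, and stochastic gradient optimization of the fuzzy
#' cross-entropy with negative sampling. Reproducible given `seed`.
#'
#' @param x numeric matrix or data frame (rows = ears, columns = residual
#'   features, optionally plus scores).
#' @param k local neighbourhood size; reduced with a warning when fewer than
#'   `k + 1` rows are supplied.
#' @param metric `"cosine"` or `"euclidean"`.
#' @param min_dist effective minimal embedded distance.
#' @param seed integer seed.
#' @param n_epochs optimization epochs.
#' @param n_negative negative samples per positive edge.
#' @return A tibble with columns `x`, `y` (class `umap_embedding`), one row
#'   per input row.
#' @export
umap_embed <- function(x, k = 15L, metric = c("cosine", "euclidean"),
                       min_dist = 1e-6, seed = 0L, n_epochs = 200L,
                       n_negative = 5L) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 rows to embed.", call. = FALSE)
  if (n < k + 1L) {
    k <- n - 1L
    warning("fewer rows than k + 1; reducing k to ", k, ".", call. = FALSE)
  }
  d <- pairwise_distances(x, metric)
  nn_idx <- t(apply(d, 1, function(row) order(row)[2:(k + 1L)]))
  nn_dist <- t(vapply(seq_len(n), function(i) d[i, nn_idx[i, ]],
                      numeric(k)))
  w <- smooth_knn_weights(nn_dist, k)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) p[i, nn_idx[i, ]] <- w[i, ]
  p_sym <- p + t(p) - p * t(p)

  ab <- fit_ab(min_dist)
  a <- ab[["a"]]; b <- ab[["b"]]

  eu <- which(upper.tri(p_sym) & p_sym > 0, arr.ind = TRUE)
  ew <- p_sym[eu]
  ew <- ew / max(ew)

  withr::with_seed(seed, {
    emb <- spectral_init(p_sym)
    emb <- emb + matrix(stats::rnorm(2 * n, 0, 1e-4), n, 2)
    ne <- length(ew)
    for (epoch in seq_len(n_epochs)) {
      alpha <- 1 - (epoch - 1) / n_epochs
      active <- stats::runif(ne) < ew
      if (!any(active)) next
      i <- eu[active, 1]; j <- eu[active, 2]
      diff <- emb[i, , drop = FALSE] - emb[j, , drop = FALSE]
      d2 <- rowSums(diff^2)
      co <- ifelse(d2 > 0, (-2 * a * b * d2^(b - 1)) / (1 + a * d2^b), 0)
      grad <- pmin(pmax(co, -4), 4) * diff
      for (cix in 1:2) {
        emb[, cix] <- emb[, cix] +
          alpha * (tapply_add(grad[, cix], i, n) - tapply_add(grad[, cix], j, n))
      }
      # negative sampling: repel heads from random vertices
      m <- sum(active)
      negs <- matrix(sample.int(n, m * n_negative, replace = TRUE),
                     m, n_negative)
      for (s in seq_len(n_negative)) {
        jn <- negs[, s]
        diff <- emb[i, , drop = FALSE] - emb[jn, , drop = FALSE]
        d2 <- rowSums(diff^2)
        co <- (2 * b) / ((0.001 + d2) * (1 + a * d2^b))
        grad <- pmin(co, 4) * diff
        keep <- jn != i
        for (cix in 1:2) {
          emb[, cix] <- emb[, cix] +
            alpha * tapply_add(grad[keep, cix], i[keep], n)
        }
      }
    }
  })
  out <- tibble::tibble(x = emb[, 1], y = emb[, 2])
  class(out) <- c("umap_embedding", class(out))
  attr(out, "settings") <- list(k = k, metric = metric, min_dist = min_dist,
                                seed = seed, n_epochs = n_epochs,
                                a = a, b = b)
  out
}

tapply_add <- function(values, index, n) {
  out <- numeric(n)
  if (length(values) == 0) return(out)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
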