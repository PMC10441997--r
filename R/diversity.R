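#' Bias-corrected Chao1 richness
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1` and `F2` are the numbers
#' of singleton and doubleton taxa. The bias-corrected form is defined even
#' when no doubletons are observed.
#'
#' @param sample_counts Non-negative integer vector for one sample.
#' @return Chao1 estimate (always `>= S_obs`).
#' @examples
#' chao1(c(1, 1, 1, 1, 2, 2, 5, 9, 13, 21))  # S_obs 10, F1 4, F2 2 -> 12
#' @export
chao1 <- function(sample_counts) {
  if (any(sample_counts < 0) || any(sample_counts != round(sample_counts)))
    stopf("counts must be non-negative integers")
  if (sum(sample_counts) == 0) stopf("all-zero sample")
  s_obs <- sum(sample_counts > 0)
  f1 <- sum(sample_counts == 1)
  f2 <- sum(sample_counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha diversity table
#'
#' @param counts ASV table.
#' @return data.frame with `sample_id`, `chao1`, and observed richness.
#' @export
alpha_diversity <- function(counts) {
  validate_asv_table(counts)
  data.frame(sample_id = colnames(counts),
             chao1 = apply(counts, 2, chao1),
             observed = colSums(counts > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix between samples
#'
#' `BC(u, v) = sum |u_i - v_i| / sum (u_i + v_i)`. Values lie in \[0, 1\];
#' the measure is not metric (the triangle inequality is not guaranteed).
#'
#' @param counts ASV table (or non-negative abundance matrix), taxa x samples.
#' @return Symmetric matrix with zero diagonal, samples in both dimnames.
#' @export
bray_curtis <- function(counts) {
  if (ncol(counts) < 2) stopf("need at least 2 samples")
  zero <- colSums(counts) == 0
  if (sum(zero) >= 2) stopf("two or more all-zero samples: Bray-Curtis undefined")
  d <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  diag(d) <- 0
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Gower-centers `-D^2 / 2` and eigendecomposes it; coordinates are built
#' from the positive eigenvalues only, and negative eigenvalues (possible for
#' non-Euclidean dissimilarities like Bray-Curtis) are reported uncorrected.
#'
#' @param d Symmetric dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param k Number of axes requested (`< n` samples).
#' @return List with `coordinates` (n x k', k' <= k axes from positive
#'   eigenvalues, a warning if truncated), `eigenvalues` (all, descending),
#'   and `proportion_explained` (per returned axis, relative to the sum of
#'   positive eigenvalues).
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) stopf("k must be smaller than the number of samples")
  if (max(abs(d - t(d))) > 1e-12) stopf("distance matrix must be symmetric")
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > 1e-12)
  kk <- min(k, npos)
  if (kk < k) warnf("only %d positive eigenvalues; returning %d axes", npos, kk)
  coords <- fit$points[, seq_len(kk), drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- sprintf("PCo%d", seq_len(kk))
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = eig[seq_len(kk)] / sum(eig[eig > 0]))
}
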