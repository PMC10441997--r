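#' Levins niche breadth
#'
#' `B = 1 / sum_s p_s^2` over resource states; `B = 1` for a point mass and
#' `B = n` for uniform usage of n states. Here the states are, by default,
#' the samples of a group, so usage is a taxon's abundance distribution
#' across them.
#'
#' @param usage Non-negative usage vector over states (normalized
#'   internally).
#' @return Breadth in \[1, n_states\].
#' @export
levins_breadth <- function(usage) {
  if (any(usage < 0)) stopf("usage must be non-negative")
  s <- sum(usage)
  if (s == 0) stopf("all-zero usage")
  p <- usage / s
  1 / sum(p^2)
}

#' Levins niche overlap between two taxa
#'
#' Asymmetric overlap `O_ij = sum_s p_is p_js / sum_s p_is^2`; the
#' symmetrized value is `(O_ij + O_ji) / 2`.
#'
#' @param p_i,p_j Usage vectors over the same states.
#' @param symmetric Return the symmetrized overlap (default TRUE).
#' @return Overlap (0 for disjoint supports; symmetrized value is 1 for
#'   identical usage).
#' @export
levins_overlap <- function(p_i, p_j, symmetric = TRUE) {
  if (sum(p_i) == 0 || sum(p_j) == 0) stopf("all-zero usage")
  p_i <- p_i / sum(p_i)
  p_j <- p_j / sum(p_j)
  o_ij <- sum(p_i * p_j) / sum(p_i^2)
  if (!symmetric) return(o_ij)
  o_ji <- sum(p_i * p_j) / sum(p_j^2)
  (o_ij + o_ji) / 2
}

#' Niche breadth and pairwise overlap for a group's taxa
#'
#' Resource states are the group's samples; each taxon's usage is its
#' count distribution across them. Taxa absent from every sample of the
#' group are excluded.
#'
#' @param counts ASV table for one group of samples.
#' @param symmetric Symmetrize the overlap matrix (default TRUE).
#' @return List of class `niche_metrics`: `breadth` (data.frame `taxon`,
#'   `B`), `overlap` (taxa x taxa matrix, diagonal `NA`), `mean_overlap`
#'   (mean over distinct pairs).
#' @export
niche_metrics <- function(counts, symmetric = TRUE) {
  keep <- rowSums(counts) > 0
  m <- counts[keep, , drop = FALSE]
  if (nrow(m) < 2) stopf("need at least 2 taxa with positive counts")
  P <- m / rowSums(m)                       # usage profiles, rows normalized
  B <- 1 / rowSums(P^2)
  G <- tcrossprod(P)                        # sum_s p_is p_js
  self <- diag(G)
  O <- G / self                             # O_ij = G_ij / sum p_is^2 (rows: i)
  if (symmetric) O <- (O + t(O)) / 2
  diag(O) <- NA
  mean_ov <- mean(O[upper.tri(O)])
  structure(list(breadth = data.frame(taxon = rownames(m), B = B,
                                      row.names = NULL, stringsAsFactors = FALSE),
                 overlap = O, mean_overlap = mean_ov, symmetric = symmetric),
            class = "niche_metrics")
}
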