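#' Null-model-corrected pairwise correlations
#'
#' Observed Pearson correlation between taxa minus the mean correlation over
#' `iterations` taxon-shuffle permutations, in which each taxon's abundance
#' vector is independently permuted across samples. The subtraction removes
#' the correlation structure expected from abundance distributions alone.
#'
#' @param rel Relative abundance matrix (taxa x samples).
#' @param iterations Null permutations (default 200).
#' @param seed Integer seed.
#' @param method Correlation used for the backbone, `"pearson"` (the cohesion
#'   method's choice) or `"spearman"`.
#' @return taxa x taxa corrected-correlation matrix, zero diagonal; constant
#'   taxa get zero rows/columns (with a message).
#' @export
null_corrected_correlations <- function(rel, iterations = 200, seed = 1,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(rel) < 4) stopf("need at least 4 samples")
  constant <- apply(rel, 1, function(x) stats::var(x) == 0)
  if (any(constant))
    msgf("cohesion: %d constant taxa get zero corrected correlations", sum(constant))
  X <- t(rel)                              # samples x taxa
  obs <- suppressWarnings(stats::cor(X, method = method))
  obs[!is.finite(obs)] <- 0
  nullsum <- matrix(0, nrow(rel), nrow(rel))
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      Xp <- apply(X, 2, sample)
      cc <- suppressWarnings(stats::cor(Xp, method = method))
      cc[!is.finite(cc)] <- 0
      nullsum <- nullsum + cc
    }
  })
  out <- obs - nullsum / iterations
  out[constant, ] <- 0
  out[, constant] <- 0
  diag(out) <- 0
  dimnames(out) <- list(rownames(rel), rownames(rel))
  out
}

#' Per-taxon connectedness
#'
#' For each taxon, the mean of its strictly positive corrected correlations
#' (`connectedness_pos`, 0 if none) and of its strictly negative ones
#' (`connectedness_neg`, 0 if none), excluding the self-correlation.
#'
#' @param corrected taxa x taxa matrix from [null_corrected_correlations()].
#' @return data.frame with `taxon`, `connectedness_pos`, `connectedness_neg`.
#' @export
connectedness <- function(corrected) {
  n <- nrow(corrected)
  pos <- neg <- numeric(n)
  for (i in seq_len(n)) {
    v <- corrected[i, -i]
    pos[i] <- if (any(v > 0)) mean(v[v > 0]) else 0
    neg[i] <- if (any(v < 0)) mean(v[v < 0]) else 0
  }
  data.frame(taxon = rownames(corrected), connectedness_pos = pos,
             connectedness_neg = neg, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample cohesion
#'
#' `cohesion_pos(s) = sum_i rel[i, s] * connectedness_pos(i)` and the
#' analogous negative sum: abundance-weighted community-level interaction
#' strength. The per-sample ratio `|cohesion_neg| / cohesion_pos` is the
#' negative:positive cohesion ratio compared between groups.
#'
#' @param rel Relative abundance matrix (taxa x samples).
#' @param conn data.frame from [connectedness()], same taxa.
#' @return List of class `cohesion_result`: `connectedness` (per taxon),
#'   `samples` (data.frame with `sample_id`, `cohesion_pos`, `cohesion_neg`,
#'   `ratio`; ratio is `NA` with a warning where `cohesion_pos` is 0).
#' @export
cohesion_per_sample <- function(rel, conn) {
  if (!identical(as.character(conn$taxon), rownames(rel)))
    stopf("connectedness taxa do not match the abundance table")
  cpos <- as.numeric(crossprod(rel, conn$connectedness_pos))
  cneg <- as.numeric(crossprod(rel, conn$connectedness_neg))
  ratio <- ifelse(cpos > 0, abs(cneg) / cpos, NA_real_)
  if (anyNA(ratio)) warnf("cohesion_pos is 0 in %d sample(s); ratio undefined there",
                          sum(is.na(ratio)))
  structure(list(connectedness = conn,
                 samples = data.frame(sample_id = colnames(rel),
                                      cohesion_pos = cpos, cohesion_neg = cneg,
                                      ratio = ratio, row.names = NULL,
                                      stringsAsFactors = FALSE)),
            class = "cohesion_result")
}

#' One-call cohesion for a count table
#'
#' @param counts ASV table for one group of samples.
#' @param iterations,seed,method See [null_corrected_correlations()].
#' @return A `cohesion_result` (see [cohesion_per_sample()]); the group-level
#'   summary is the median per-sample ratio, in `$ratio_median`.
#' @export
cohesion <- function(counts, iterations = 200, seed = 1, method = "pearson") {
  rel <- to_relative_abundance(counts)
  corrected <- null_corrected_correlations(rel, iterations = iterations,
                                           seed = seed, method = method)
  res <- cohesion_per_sample(rel, connectedness(corrected))
  res$ratio_median <- stats::median(res$samples$ratio, na.rm = TRUE)
  res
}
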