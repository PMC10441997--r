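#' Per-ASV occurrence statistics
#'
#' @param counts ASV table.
#' @return data.frame with `taxon`, `p` (mean per-sample relative abundance)
#'   and `freq` (fraction of samples with count > 0). Taxa absent everywhere
#'   are excluded with a message.
#' @export
occurrence_stats <- function(counts) {
  validate_asv_table(counts)
  if (ncol(counts) < 5) warnf("only %d samples: occurrence frequencies are coarse", ncol(counts))
  rel <- to_relative_abundance(counts)
  p <- rowMeans(rel)
  freq <- rowMeans(counts > 0)
  absent <- p == 0
  if (any(absent))
    msgf("occurrence_stats: excluding %d taxa absent from every sample", sum(absent))
  data.frame(taxon = rownames(counts)[!absent], p = p[!absent], freq = freq[!absent],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sloan neutral prediction of detection frequency
#'
#' Probability that a taxon of mean metacommunity relative abundance `p`
#' exceeds the detection limit `d` in a local community, under the neutral
#' expectation that local abundance follows Beta(Nm p, Nm (1 - p)):
#' `freq = 1 - pbeta(d, Nm p, Nm (1 - p))`.
#'
#' @param p Mean relative abundance(s), in (0, 1).
#' @param Nm Product of local community size and migration rate (> 0).
#' @param d Detection limit, in (0, 1); typically 1 / reads-per-sample.
#' @return Predicted detection frequency in \[0, 1\].
#' @export
predict_frequency <- function(p, Nm, d) {
  if (Nm <= 0) stopf("Nm must be positive")
  if (d <= 0 || d >= 1) stopf("detection limit d must lie in (0, 1)")
  if (any(p <= 0) || any(p >= 1)) stopf("p must lie in (0, 1)")
  1 - stats::pbeta(d, Nm * p, Nm * (1 - p))
}

#' Fit the Sloan neutral community model
#'
#' Estimates `Nm` by least squares of observed vs predicted detection
#' frequency (bounded scalar optimization over `log10(Nm)` in \[-3, 7\]),
#' with migration rate `m = Nm / N`. The default detection limit is the
#' half-count continuity correction `d = 1/(2N)`: a taxon is undetected when
#' its count is 0, i.e. when its latent relative abundance falls below half
#' a count, and using `1/N` instead systematically understates the detection
#' of rare taxa and inflates `Nm`.
#' `R^2 = 1 - SSE/SST` about the mean observed frequency (negative values
#' are reported as-is). Bootstrap confidence intervals and the 95%
#' prediction band partitioning ASVs into above/within/below come from
#' resampling ASVs.
#'
#' @param stats_df data.frame from [occurrence_stats()].
#' @param N Individuals (reads) per sample; uniform after rarefaction.
#' @param bootstrap Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param d Detection limit (default `1/(2N)`).
#' @return List of class `ncm_fit`: `m`, `Nm`, `R2`, `ci95_m`, `ci95_R2`,
#'   `d`, `N`, and `per_asv` (p, freq, predicted, band limits, partition).
#' @export
fit_ncm <- function(stats_df, N, bootstrap = 1000, seed = 1, d = 1 / (2 * N)) {
  df <- stats_df[stats_df$p > 0 & stats_df$p < 1, , drop = FALSE]
  if (nrow(df) < 10) stopf("need at least 10 ASVs with 0 < p < 1")
  if (all(df$freq == 1)) stopf("all detection frequencies are 1: model unidentifiable")
  fit_one <- function(p, freq) {
    obj <- function(lognm) sum((freq - predict_frequency(p, 10^lognm, d))^2)
    opt <- stats::optimize(obj, interval = c(-3, 7))
    if (min(abs(opt$minimum - c(-3, 7))) < 1e-3)
      warnf("Nm estimate at the optimization bound")
    10^opt$minimum
  }
  Nm <- fit_one(df$p, df$freq)
  pred <- predict_frequency(df$p, Nm, d)
  sse <- sum((df$freq - pred)^2)
  sst <- sum((df$freq - mean(df$freq))^2)
  r2 <- 1 - sse / sst
  nb <- nrow(df)
  boot <- with_seed(seed, {
    t(vapply(seq_len(bootstrap), function(b) {
      i <- sample.int(nb, nb, replace = TRUE)
      nm_b <- fit_one(df$p[i], df$freq[i])
      pred_b <- predict_frequency(df$p[i], nm_b, d)
      sst_b <- sum((df$freq[i] - mean(df$freq[i]))^2)
      r2_b <- if (sst_b > 0) 1 - sum((df$freq[i] - pred_b)^2) / sst_b else NA_real_
      c(nm_b, r2_b, predict_frequency(df$p, nm_b, d))
    }, numeric(2 + nb)))
  })
  band <- apply(boot[, -(1:2), drop = FALSE], 2, stats::quantile, probs = c(0.025, 0.975))
  partition <- ifelse(df$freq > band[2, ], "above",
                      ifelse(df$freq < band[1, ], "below", "within"))
  structure(list(
    m = Nm / N, Nm = Nm, R2 = r2, d = d, N = N,
    ci95_m = unname(stats::quantile(boot[, 1], c(0.025, 0.975), na.rm = TRUE)) / N,
    ci95_R2 = unname(stats::quantile(boot[, 2], c(0.025, 0.975), na.rm = TRUE)),
    bootstrap = bootstrap, seed = seed,
    per_asv = data.frame(taxon = df$taxon, p = df$p, freq = df$freq,
                         predicted = pred, lower = band[1, ], upper = band[2, ],
                         partition = partition,
                         row.names = NULL, stringsAsFactors = FALSE)),
    class = "ncm_fit")
}
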