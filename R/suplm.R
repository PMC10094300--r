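# supLM null distribution: p-values for the supremum, over a trimmed time
# interval, of the squared normalized k-dimensional Brownian-bridge process
#   sup_{t in [trim, 1-trim]} ||B(t)||^2 / (t (1 - t)).
# Primary route: interpolation in the tabulated quantiles (R/suplm-table.R);
# beyond the table the upper tail is extrapolated log-linearly in the
# statistic (the exact tail decays like exp(-x/2) times a slowly varying
# factor). A seeded Monte-Carlo fallback covers trimming fractions other
# than the tabulated 0.1.

.suplm_cache <- new.env(parent = emptyenv())

suplm_pvalue <- function(stat, k, trim = 0.1) {
  if (!is.finite(stat)) return(NA_real_)
  if (abs(trim - .supLM_trim) < 1e-9 && k >= 1 && k <= ncol(.supLM_quantiles)) {
    q <- .supLM_quantiles[, k]
    probs <- .supLM_probs
  } else {
    tab <- suplm_mc_table(k, trim)
    q <- tab$q
    probs <- tab$probs
  }
  if (stat <= q[1]) return(1)
  if (stat >= q[length(q)]) {
    # log-linear tail in the statistic, anchored at the last two tabulated
    # tail probabilities
    m <- length(q)
    p1 <- 1 - probs[m - 1]; p2 <- 1 - probs[m]
    slope <- (log(p2) - log(p1)) / (q[m] - q[m - 1])
    return(max(exp(log(p2) + slope * (stat - q[m])), 1e-12))
  }
  cdf <- stats::approx(q, probs, xout = stat, ties = "ordered")$y
  1 - cdf
}

# Monte-Carlo tabulation for non-default trimming, cached per (k, trim).
suplm_mc_table <- function(k, trim, reps = 20000L, grid = 1000L) {
  key <- sprintf("k%d_t%.6f", k, trim)
  if (!is.null(.suplm_cache[[key]])) return(.suplm_cache[[key]])
  lo <- max(1L, ceiling(grid * trim))
  hi <- min(grid - 1L, floor(grid * (1 - trim)))
  tt <- (lo:hi) / grid
  denom <- tt * (1 - tt)
  stats_all <- with_seed(str_seed(271828L, key), {
    out <- numeric(reps)
    chunk <- 500L
    done <- 0L
    while (done < reps) {
      m <- min(chunk, reps - done)
      s <- matrix(0, length(tt), m)
      for (j in seq_len(k)) {
        inc <- matrix(stats::rnorm(grid * m, sd = sqrt(1 / grid)), grid, m)
        cs <- apply(inc, 2, cumsum)
        bb <- cs - outer((1:grid) / grid, cs[grid, ])
        s <- s + bb[lo:hi, , drop = FALSE]^2
      }
      out[done + seq_len(m)] <- apply(s / denom, 2, max)
      done <- done + m
    }
    out
  })
  probs <- c(seq(0.01, 0.98, by = 0.01), seq(0.985, 0.999, by = 0.002))
  tab <- list(q = stats::quantile(stats_all, probs, names = FALSE, type = 8),
              probs = probs)
  .suplm_cache[[key]] <- tab
  tab
}
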