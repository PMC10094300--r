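# internal helpers shared across modules

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic 31-bit string hash (polynomial rolling hash); used to derive
# per-column RNG streams so that adding a covariate leaves the others' draws
# untouched.
str_seed <- function(master, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(master) + h) %% 2147483629)
}

# Case-insensitive, whitespace-trimmed level matching. Returns indices of
# `x` into `levels`, erroring on values that match no level.
match_levels <- function(x, levels, what = "value") {
  norm <- function(v) tolower(trimws(as.character(v)))
  idx <- match(norm(x), norm(levels))
  bad <- !is.na(x) & is.na(idx)
  if (any(bad)) {
    stop("unknown ", what, ": ",
         paste(unique(as.character(x)[bad]), collapse = ", "), call. = FALSE)
  }
  idx
}

is_binary01 <- function(x) all(x %in% c(0, 1))

# Weighted mean/variance/correlation (frequency-weight convention).
wmean <- function(x, w) sum(w * x) / sum(w)
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}
wcor <- function(x, y, w) {
  mx <- wmean(x, w); my <- wmean(y, w)
  cov <- sum(w * (x - mx) * (y - my)) / sum(w)
  cov / sqrt(wvar(x, w) * wvar(y, w))
}

# Gaussian kernel density estimate of `x` evaluated at `at` (chunked so that
# large cohorts do not allocate an n x n matrix at once).
gaussian_kde_at <- function(x, at, bw = stats::bw.nrd0(x)) {
  if (!is.finite(bw) || bw <= 0) stop("degenerate kernel bandwidth", call. = FALSE)
  n <- length(x)
  out <- numeric(length(at))
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1L, length(at), by = chunk)) {
    i <- s:min(s + chunk - 1L, length(at))
    out[i] <- colMeans(matrix(stats::dnorm(outer(x, at[i], "-") / bw), nrow = n)) / bw
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
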