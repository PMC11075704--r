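# Internal helpers shared across modules.

#' @importFrom stats median mad coef lm approx setNames sd
#' @importFrom utils head tail read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed` may be NULL, in which case the current
# stream is used (and advanced).
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

# Theil-Sen estimator: median of pairwise slopes. Robust against steps and
# single-frame segmentation glitches, O(n^2) but tracks are short.
theil_sen_slope <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2L, length(y) == n)
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2L, ]] - x[ij[1L, ]]
  dy <- y[ij[2L, ]] - y[ij[1L, ]]
  keep <- dx != 0
  stats::median(dy[keep] / dx[keep])
}

# Greedy binary segmentation for mean shifts. Returns integer changepoint
# positions (last index of each left segment), at most k_max of them, each
# segment at least min_len points. Used by the stepped-growth classifier.
binseg_changepoints <- function(y, k_max = 6L, min_len = 3L) {
  n <- length(y)
  seg_rss <- function(a, b) {
    yy <- y[a:b]
    sum((yy - mean(yy))^2)
  }
  best_split <- function(a, b) {
    if (b - a + 1L < 2L * min_len) return(NULL)
    cand <- (a + min_len - 1L):(b - min_len)
    gain <- vapply(cand, function(cp) {
      seg_rss(a, b) - seg_rss(a, cp) - seg_rss(cp + 1L, b)
    }, numeric(1))
    i <- which.max(gain)
    list(cp = cand[i], gain = gain[i])
  }
  segs <- list(c(1L, n))
  cps <- integer(0)
  total_rss <- seg_rss(1L, n)
  for (k in seq_len(k_max)) {
    props <- lapply(segs, function(s) best_split(s[1], s[2]))
    gains <- vapply(props, function(p) if (is.null(p)) -Inf else p$gain, numeric(1))
    if (all(!is.finite(gains)) || max(gains) <= 0) break
    i <- which.max(gains)
    cp <- props[[i]]$cp
    s <- segs[[i]]
    segs[[i]] <- c(s[1], cp)
    segs[[length(segs) + 1L]] <- c(cp + 1L, s[2])
    cps <- sort(c(cps, cp))
    total_rss <- total_rss - gains[i]
  }
  list(changepoints = cps, rss = total_rss)
}

# Piecewise-constant RSS for a given set of changepoints.
pwconst_rss <- function(y, cps) {
  bounds <- c(0L, cps, length(y))
  rss <- 0
  means <- numeric(length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    yy <- y[(bounds[i] + 1L):bounds[i + 1L]]
    means[i] <- mean(yy)
    rss <- rss + sum((yy - means[i])^2)
  }
  list(rss = rss, means = means)
}

# First index at which `x` is TRUE for at least `run` consecutive entries,
# or NA_integer_ if never.
first_sustained <- function(x, run) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= run)
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1L]]
}

# Separable Gaussian blur with reflective edges; sigma in pixels.
# sigma = 0 returns the input unchanged.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(half)]), v, rev(v[(n - half + 1L):n]))
    stats::filter(vp, k, sides = 2)[(half + 1L):(half + n)]
  }
  m2 <- apply(m, 2L, pad_conv)
  t(apply(m2, 1L, pad_conv))
}

# Discrete 5-point Laplacian with replicated edges.
laplacian <- function(m) {
  up <- m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nrow(m) - 1L) + 1L, nrow(m)), , drop = FALSE]
  lf <- m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(ncol(m) - 1L) + 1L, ncol(m)), drop = FALSE]
  up + dn + lf + rt - 4 * m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bub <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_bub("`%s` must be a single positive finite number", name)
  invisible(x)
}
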