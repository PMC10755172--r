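# shared fixture builders; everything is generated in code at test time

tiny_map <- function(n_chr = 2, n_markers = 20, len = 100) {
  make_marker_map(n_chr, n_markers, len)
}

# binary mask of a filled ellipse, axes aligned with the grid
ellipse_mask <- function(a, b, pad = 6) {
  W <- 2 * a + 2 * pad; H <- 2 * b + 2 * pad
  cx <- W / 2 + 0.5; cy <- H / 2 + 0.5
  x <- matrix(seq_len(W), W, H); y <- matrix(seq_len(H), W, H, byrow = TRUE)
  m <- matrix(0L, W, H)
  m[((x - cx)^2 / a^2 + (y - cy)^2 / b^2) <= 1] <- 1L
  m
}

# independent RGB->hue oracle: the piecewise sector formula, never rgb2hsv
sector_hue <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b); d <- mx - mn
  h <- numeric(length(r))
  for (i in seq_along(r)) {
    if (d[i] == 0) { h[i] <- 0; next }
    h[i] <- if (mx[i] == r[i]) {
      ((g[i] - b[i]) / d[i]) %% 6
    } else if (mx[i] == g[i]) {
      (b[i] - r[i]) / d[i] + 2
    } else {
      (r[i] - g[i]) / d[i] + 4
    }
    h[i] <- (h[i] * 60) %% 360
  }
  h
}

# independent brute-force enumeration of DH pigment proportion: iterate the
# 2^L classes as bit patterns rather than via expand.grid
bruteforce_dh_proportion <- function(logic, loci) {
  L <- length(loci)
  expr <- str2lang(logic)
  hits <- 0
  for (code in 0:(2^L - 1)) {
    env <- as.list(bitwAnd(bitwShiftR(code, seq_len(L) - 1), 1) == 1)
    names(env) <- loci
    if (isTRUE(eval(expr, envir = env))) hits <- hits + 1
  }
  hits / 2^L
}
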