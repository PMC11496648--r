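# Independent brute-force oracles and small fixture builders.
# These deliberately take the slow, explicit route (full distance matrices,
# explicit sorts, explicit normal equations) so they share no code path
# with the package implementations they check.

# Brute-force simplex projection: explicit distance matrix, explicit sort,
# k = E + 1 neighbors, exponential weights, duplicate handling as
# documented.
oracle_simplex <- function(X, y, E, loocv = TRUE) {
  n <- nrow(X)
  k <- E + 1L
  pred <- rep(NA_real_, n)
  for (p in seq_len(n)) {
    d <- rep(NA_real_, n)
    for (q in seq_len(n)) d[q] <- sqrt(sum((X[p, ] - X[q, ])^2))
    cand <- seq_len(n)
    if (loocv) cand <- cand[cand != p & d[cand] > 0]
    ord <- cand[order(d[cand])]
    nb <- ord[seq_len(k)]
    dk <- d[nb]
    w <- if (dk[1] == 0) as.numeric(dk == 0) else exp(-dk / dk[1])
    pred[p] <- sum(w * y[nb]) / sum(w)
  }
  pred
}

# Weighted ridge via explicit normal equations, intercept unpenalized.
oracle_wridge <- function(X, y, w, lambda) {
  Xi <- cbind(1, X)
  W <- diag(w)
  pen <- diag(c(0, rep(1, ncol(X))))
  solve(t(Xi) %*% W %*% Xi + lambda * pen, t(Xi) %*% W %*% y)
}

# Brute-force regularized S-map coefficients at every row.
oracle_smap <- function(X, y, theta, lambda, exclude_self = TRUE) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, ncol(X) + 1L)
  for (p in seq_len(n)) {
    d <- sqrt(rowSums((X - matrix(X[p, ], n, ncol(X), byrow = TRUE))^2))
    dbar <- mean(d[-p])
    idx <- if (exclude_self) setdiff(seq_len(n), p) else seq_len(n)
    w <- if (theta == 0) rep(1, length(idx)) else exp(-theta * d[idx] / dbar)
    out[p, ] <- oracle_wridge(X[idx, , drop = FALSE], y[idx], w, lambda)
  }
  out
}

# Tiny panel: `frames` is a named list taxon -> list of fragment vectors,
# one fragment per (tank, year) in the given design.
make_panel <- function(frames, tanks = c(C = "C1"), years = 1L) {
  rows <- list()
  for (tx in names(frames)) {
    i <- 0L
    for (trt in names(tanks)) {
      for (yr in seq_len(years)) {
        i <- i + 1L
        v <- frames[[tx]][[i]]
        rows[[length(rows) + 1L]] <- data.frame(
          tank_id = tanks[[trt]], treatment = trt, year = yr,
          census = seq_along(v), taxon = tx, raw_density = v,
          stringsAsFactors = FALSE)
      }
    }
  }
  community_panel(do.call(rbind, rows))
}

# Composite of m fragments of iid N(0, 1) noise.
noise_composite <- function(m = 24L, len = 10L, seed = 1L, taxon = "noise") {
  set.seed(seed)
  as_composite(replicate(m, rnorm(len), simplify = FALSE), taxon = taxon)
}

# Logistic-map composite split into fragments (chaotic, low-dimensional).
logistic_composite <- function(n = 240L, r = 3.8, frag_len = 10L, seed = 1L) {
  set.seed(seed)
  x <- numeric(n + 50L)
  x[1] <- runif(1, 0.2, 0.8)
  for (t in seq_len(n + 49L)) x[t + 1] <- r * x[t] * (1 - x[t])
  x <- x[51:(n + 50L)]
  as_composite(unname(split(x, rep(seq_len(n / frag_len), each = frag_len))),
               taxon = "logistic")
}
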