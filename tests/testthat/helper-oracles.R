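# Independent oracles, kept deliberately naive.

# shock-filter scheme as a plain double loop (checks the vectorized
# implementation against a direct transcription of the update rule)
oracle_shock <- function(x, t_f) {
  n <- length(x)
  for (t in seq_len(t_f)) {
    y <- x
    for (i in 2:(n - 1)) {
      gl <- x[i + 1] - x[i]
      gr <- x[i] - x[i - 1]
      if (sign(gl) == sign(gr) && gl != 0) {
        lap <- x[i + 1] - 2 * x[i] + x[i - 1]
        y[i] <- x[i] - sign(lap) * min(abs(gl), abs(gr))
      }
    }
    x <- y
  }
  x
}

# optimal contiguous 2-split of sorted values by exhaustive search;
# returns the minimal within-cluster sum of squares
oracle_best_split_wcss <- function(values) {
  v <- sort(values)
  n <- length(v)
  wcss <- function(a) sum((a - mean(a))^2)
  best <- Inf
  for (k in 1:(n - 1)) {
    s <- wcss(v[1:k]) + wcss(v[(k + 1):n])
    if (s < best) best <- s
  }
  best
}

kmeans2_wcss <- function(values, fit) {
  sum((values[fit$labels] - mean(values[fit$labels]))^2) +
    sum((values[!fit$labels] - mean(values[!fit$labels]))^2)
}

# brute-force digital-ellipse pixel count over a generous bounding box
oracle_ellipse_count <- function(center, semi, pad = 3) {
  us <- floor(center[1] - semi[1] - pad):ceiling(center[1] + semi[1] + pad)
  vs <- floor(center[2] - semi[2] - pad):ceiling(center[2] + semi[2] + pad)
  g <- expand.grid(u = us, v = vs)
  sum(((g$u - center[1]) / semi[1])^2 + ((g$v - center[2]) / semi[2])^2 <= 1)
}

# sigmoid-edged bump profile with analytically known inflection points
# at e1 and e2 (second derivative of each logistic factor vanishes at its
# center; for well-separated edges the product inherits them)
sigmoid_bump <- function(n, e1, e2, w, lo = 10, hi = 100) {
  x <- seq_len(n) - 1
  lo + (hi - lo) / ((1 + exp(-(x - e1) / w)) * (1 + exp((x - e2) / w)))
}

# jaccard of two (u,v) pixel matrices
jaccard_px <- function(a, b) {
  ka <- a[, "u"] * 1e6 + a[, "v"]
  kb <- b[, "u"] * 1e6 + b[, "v"]
  length(intersect(ka, kb)) / length(union(ka, kb))
}
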