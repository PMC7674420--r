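# Independent brute-force oracles, deliberately naive implementations kept
# separate from the package code paths they validate.

# rasterizer: explicit interval membership per cell, quadratic scan
oracle_rasterize <- function(times, values, g, y_bounds) {
  t0 <- min(times); t1 <- max(times)
  tw <- (t1 - t0) / g
  yw <- (y_bounds[2] - y_bounds[1]) / g
  vals <- pmin(pmax(values, y_bounds[1]), y_bounds[2])
  img <- matrix(0L, nrow = g, ncol = g)  # rows = value bins bottom-up
  for (k in seq_along(times)) {
    for (cc in seq_len(g)) {
      in_col <- if (cc < g)
        times[k] >= t0 + (cc - 1) * tw && times[k] < t0 + cc * tw
      else
        times[k] >= t0 + (cc - 1) * tw && times[k] <= t1
      if (!in_col) next
      for (rr in seq_len(g)) {
        lo <- y_bounds[1] + (rr - 1) * yw
        hi <- y_bounds[1] + rr * yw
        in_row <- if (rr < g) vals[k] >= lo && vals[k] < hi
                  else vals[k] >= lo && vals[k] <= y_bounds[2]
        if (in_row) img[rr, cc] <- 1L
      }
    }
  }
  as.integer(img)  # column-major, bottom-to-top: matches the declared layout
}

# run scanner: walk each column counting consecutive occupied cells
oracle_fluc3 <- function(vec, g, cross_columns = FALSE) {
  count <- 0L
  scan <- function(v) {
    tot <- 0L; run <- 0L
    for (x in c(v, 0L)) {
      if (x == 1L) run <- run + 1L
      else { if (run >= 2L) tot <- tot + run; run <- 0L }
    }
    tot
  }
  if (cross_columns) return(scan(vec))
  for (cc in seq_len(length(vec) / g))
    count <- count + scan(vec[((cc - 1) * g + 1):(cc * g)])
  count
}

# pairwise Mann-Whitney AUC estimator
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
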