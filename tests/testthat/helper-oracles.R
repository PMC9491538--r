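# Brute-force oracles, deliberately written as plain loops / first-principles
# formulas so they share no code with the implementation they check.

oracle_mse <- function(I, K) {
  s <- 0
  for (i in seq_len(nrow(I))) {
    for (j in seq_len(ncol(I))) s <- s + (I[i, j] - K[i, j])^2
  }
  s / (nrow(I) * ncol(I))
}

oracle_psnr <- function(I, K, max_val = 255) {
  m <- oracle_mse(I, K)
  if (m == 0) return(Inf)
  10 * log10(max_val^2 / m)
}

# SSIM oracle over valid uniform windows, one window at a time
oracle_ssim <- function(I, K, w = 7, k1 = 0.01, k2 = 0.03, L = 255) {
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2; C3 <- C2 / 2
  vals <- c()
  for (i in seq_len(nrow(I) - w + 1)) {
    for (j in seq_len(ncol(I) - w + 1)) {
      x <- as.numeric(I[i:(i + w - 1), j:(j + w - 1)])
      y <- as.numeric(K[i:(i + w - 1), j:(j + w - 1)])
      mx <- mean(x); my <- mean(y)
      vx <- mean(x^2) - mx^2; vy <- mean(y^2) - my^2
      vx <- max(vx, 0); vy <- max(vy, 0)
      cxy <- mean(x * y) - mx * my
      l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
      cc <- (2 * sqrt(vx) * sqrt(vy) + C2) / (vx + vy + C2)
      ss <- (cxy + C3) / (sqrt(vx) * sqrt(vy) + C3)
      vals <- c(vals, l * cc * ss)
    }
  }
  mean(vals)
}

oracle_counts <- function(G, P) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_len(nrow(G))) {
    for (j in seq_len(ncol(G))) {
      if (G[i, j] && P[i, j]) tp <- tp + 1
      else if (!G[i, j] && P[i, j]) fp <- fp + 1
      else if (G[i, j] && !P[i, j]) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_iou <- function(G, P) {
  n <- oracle_counts(G, P)
  if (n$tp + n$fp + n$fn == 0) return(1)
  n$tp / (n$tp + n$fp + n$fn)
}

oracle_dice <- function(G, P) {
  n <- oracle_counts(G, P)
  if (2 * n$tp + n$fp + n$fn == 0) return(1)
  2 * n$tp / (2 * n$tp + n$fp + n$fn)
}

oracle_pixel_acc <- function(G, P) {
  n <- oracle_counts(G, P)
  (n$tp + n$tn) / (n$tp + n$tn + n$fp + n$fn)
}

# band of pixels of M within Chebyshev distance `band` of the complement,
# computed from pairwise coordinate distances
oracle_band <- function(M, band) {
  out <- matrix(FALSE, nrow(M), ncol(M))
  comp <- which(!M, arr.ind = TRUE)
  if (nrow(comp) == 0) return(out)
  fg <- which(M, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    d <- pmax(abs(comp[, 1] - fg[k, 1]), abs(comp[, 2] - fg[k, 2]))
    if (min(d) <= band) out[fg[k, 1], fg[k, 2]] <- TRUE
  }
  out
}

oracle_boundary_iou <- function(G, P, band) {
  oracle_iou(oracle_band(G, band), oracle_band(P, band))
}

random_mask <- function(h = 16, w = 16, p = 0.35) {
  matrix(stats::runif(h * w) < p, h, w)
}
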