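# Independent brute-force oracles used to pin expected values.

# Haralick features by explicit double-loop pair counting over the mask,
# followed by the classical formulas written out directly (base-2 logs).
oracle_haralick <- function(img, pixels, levels = 32) {
  vals <- img[pixels]
  rng <- range(vals)
  q <- if (rng[2] > rng[1]) {
    pmin(floor((vals - rng[1]) / (rng[2] - rng[1]) * levels), levels - 1)
  } else rep(0, length(vals))
  nr <- nrow(img)
  coords <- cbind(((pixels - 1) %% nr) + 1, ((pixels - 1) %/% nr) + 1)
  level_of <- new.env()
  for (i in seq_along(pixels)) {
    assign(paste(coords[i, 1], coords[i, 2]), q[i], envir = level_of)
  }
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  feats <- NULL
  for (off in offsets) {
    P <- matrix(0, levels, levels)
    npair <- 0
    for (i in seq_along(pixels)) {
      key <- paste(coords[i, 1] + off[1], coords[i, 2] + off[2])
      if (exists(key, envir = level_of, inherits = FALSE)) {
        j <- get(key, envir = level_of)
        P[q[i] + 1, j + 1] <- P[q[i] + 1, j + 1] + 1
        P[j + 1, q[i] + 1] <- P[j + 1, q[i] + 1] + 1
        npair <- npair + 1
      }
    }
    if (npair == 0) next
    P <- P / sum(P)
    f <- oracle_haralick_formulas(P)
    feats <- rbind(feats, f)
  }
  colMeans(feats)
}

oracle_haralick_formulas <- function(P) {
  L <- nrow(P)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum((0:(L - 1)) * px); mu_y <- sum((0:(L - 1)) * py)
  sd_x <- sqrt(sum(((0:(L - 1)) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((0:(L - 1)) - mu_y)^2 * py))
  asm <- 0; contrast <- 0; cor_num <- 0; varia <- 0; idm <- 0; ent <- 0
  psum <- numeric(2 * L - 1); pdiff <- numeric(L)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    cor_num <- cor_num + (i - 1) * (j - 1) * p
    varia <- varia + ((i - 1) - mu_x)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    ent <- ent - p * lg(p)
    psum[i + j - 1] <- psum[i + j - 1] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
    hxy1 <- hxy1 - p * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  correlation <- if (sd_x > 0 && sd_y > 0) (cor_num - mu_x * mu_y) / (sd_x * sd_y) else 0
  ks <- 0:(2 * L - 2)
  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  sum_ent <- -sum(sapply(seq_along(psum), function(k) psum[k] * lg(psum[k])))
  kd <- 0:(L - 1)
  dmu <- sum(kd * pdiff)
  diff_var <- sum((kd - dmu)^2 * pdiff)
  diff_ent <- -sum(sapply(seq_along(pdiff), function(k) pdiff[k] * lg(pdiff[k])))
  hx <- -sum(sapply(px, function(v) v * lg(v)))
  hy <- -sum(sapply(py, function(v) v * lg(v)))
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(asm, contrast, correlation, varia, idm, sum_avg, sum_var, sum_ent,
    ent, diff_var, diff_ent, imc1, imc2)
}

# Average precision by exhaustive enumeration of every distinct threshold.
oracle_pr_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ts <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (t in ts) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / sum(labels)
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

# Spearman by explicit rank-then-Pearson with mid-ranks for ties.
oracle_spearman <- function(x, y) {
  # mid-rank: average position of equal values in the sorted vector
  midrank <- function(v) sapply(v, function(vi) mean(which(sort(v) == vi)))
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Exposed pixel-edge count by brute force over every pixel's 4 sides.
oracle_perimeter_edges <- function(pixels, dims) {
  nr <- dims[1]; nc <- dims[2]
  inmask <- matrix(FALSE, nr, nc)
  inmask[pixels] <- TRUE
  n <- 0
  for (p in pixels) {
    r <- ((p - 1) %% nr) + 1
    c_ <- ((p - 1) %/% nr) + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + d[1]; c2 <- c_ + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !inmask[r2, c2]) n <- n + 1
    }
  }
  n
}
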