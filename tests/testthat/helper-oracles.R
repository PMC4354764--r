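# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written from first principles (loops, set
# definitions, exhaustive scans), not by calling the package's own code.

# erosion by set definition: p survives iff every p+o is in-bounds and set
oracle_erode <- function(m, offsets) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (r in 1:h) for (c in 1:w) {
    ok <- TRUE
    for (k in seq_len(nrow(offsets))) {
      rr <- r + offsets[k, 1]; cc <- c + offsets[k, 2]
      if (rr < 1 || rr > h || cc < 1 || cc > w || !m[rr, cc]) { ok <- FALSE; break }
    }
    out[r, c] <- ok
  }
  out
}

# dilation as Minkowski sum: q set => q + o set, clipped to bounds
oracle_dilate <- function(m, offsets) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (r in 1:h) for (c in 1:w) {
    if (!m[r, c]) next
    for (k in seq_len(nrow(offsets))) {
      rr <- r + offsets[k, 1]; cc <- c + offsets[k, 2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) out[rr, cc] <- TRUE
    }
  }
  out
}

# 8-connected labelling by explicit flood fill
oracle_components8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (r in 1:h) for (c in 1:w) {
    if (!m[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c)); lab[r, c] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            m[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Otsu: scan every internal bin edge, split the raw values, maximize
# between-class variance directly
oracle_otsu <- function(values, bins = 256L) {
  edges <- seq(min(values), max(values), length.out = bins + 1L)
  best <- -Inf; best_t <- NA_real_
  for (t in edges[2:bins]) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(values); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

# kinetic parameters straight from the defining equations
oracle_params <- function(v) {
  n <- length(v)
  si_mean <- (v[2] + v[3]) / 2
  list(
    si_slope = if (si_mean == 0) NaN else 100 * (v[n] - si_mean) / si_mean,
    msi = max(v[-1] - v[-n]),
    e_initial = if (v[1] <= 0) NaN else 100 * (v[2] - v[1]) / v[1],
    e_peak = if (v[1] <= 0) NaN else 100 * (max(v[2:n]) - v[1]) / v[1],
    eser = if (v[3] == v[1]) NaN else 100 * (v[2] - v[1]) / (v[3] - v[1]),
    sep = if (v[1] <= 0) NaN else 100 * (v[3] - v[1]) / v[1]
  )
}

# AUC by exhaustive pair counting with tie correction
oracle_auc <- function(scores, labels, positive_high = TRUE) {
  pos <- scores[labels == "malignant"]; neg <- scores[labels == "benign"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  a <- tot / (length(pos) * length(neg))
  if (positive_high) a else 1 - a
}

# best Youden J over an exhaustive scan of observed values and midpoints,
# for a given direction
oracle_best_j <- function(scores, labels, direction) {
  cand <- sort(unique(c(scores, (head(sort(scores), -1) + tail(sort(scores), -1)) / 2)))
  n_pos <- sum(labels == "malignant"); n_neg <- sum(labels == "benign")
  best <- -Inf
  for (cc in cand) {
    called <- if (direction == "gt") scores > cc else scores <= cc
    sens <- 100 * sum(called & labels == "malignant") / n_pos
    spec <- 100 * sum(!called & labels == "benign") / n_neg
    best <- max(best, sens + spec - 100)
  }
  best
}

# DeLong variance from structural components (Hanley-style placement values)
oracle_delong_se <- function(scores, labels) {
  x <- scores[labels == "malignant"]; y <- scores[labels == "benign"]
  m <- length(x); n <- length(y)
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  v10 <- vapply(x, function(xi) mean(vapply(y, function(yj) psi(xi, yj), 1)), 1)
  v01 <- vapply(y, function(yj) mean(vapply(x, function(xi) psi(xi, yj), 1)), 1)
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  sqrt(s10 / m + s01 / n)
}

# convex-polygon point test: point is inside iff it is on the same side of
# (or on) every edge of the CCW-ordered hull
oracle_in_convex <- function(pr, pc, vr, vc) {
  n <- length(vr)
  side <- numeric(n)
  for (i in 1:n) {
    j <- i %% n + 1
    side[i] <- (vr[j] - vr[i]) * (pc - vc[i]) - (vc[j] - vc[i]) * (pr - vr[i])
  }
  all(side >= 0) || all(side <= 0)
}

random_mask <- function(h = 32, w = 32, p = 0.4) {
  matrix(runif(h * w) < p, h, w)
}

random_convex_polygon <- function(grid = 32, n_pts = 8) {
  pts <- cbind(runif(n_pts, 1, grid - 2), runif(n_pts, 1, grid - 2))
  hull <- chull(pts)   # returned clockwise; order is fine for both tests
  pts[hull, , drop = FALSE]
}
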