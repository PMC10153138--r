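# Independent brute-force oracles used to check the fast implementations.
# Each is written directly from the mathematical definition, not from the
# package code paths it validates.

# full 2D convolution with symmetric (mirror) boundary, explicit loops
oracle_conv2_sep <- function(px, ky, kx) {
  nr <- nrow(px); nc <- ncol(px)
  hy <- (length(ky) - 1) / 2; hx <- (length(kx) - 1) / 2
  reflect <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 1 - i, i)
      i <- ifelse(i > n, 2 * n + 1 - i, i)
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (j in seq_along(ky)) for (i in seq_along(kx)) {
      rr <- reflect(r + j - 1 - hy, nr)
      cc <- reflect(c + i - 1 - hx, nc)
      acc <- acc + ky[j] * kx[i] * px[rr, cc]
    }
    out[r, c] <- acc
  }
  out
}

# bilinear interpolation at a single (x = col, y = row) point
oracle_bilinear <- function(px, x, y) {
  nr <- nrow(px); nc <- ncol(px)
  x0 <- min(max(floor(x), 1), nc - 1); y0 <- min(max(floor(y), 1), nr - 1)
  fx <- x - x0; fy <- y - y0
  (1 - fy) * (1 - fx) * px[y0, x0] + (1 - fy) * fx * px[y0, x0 + 1] +
    fy * (1 - fx) * px[y0 + 1, x0] + fy * fx * px[y0 + 1, x0 + 1]
}

# exhaustive regional-minima search: flood every equal-value plateau and
# check all outside 8-neighbours are strictly greater
oracle_regional_minima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  seen <- matrix(FALSE, nr, nc)
  nextl <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (seen[r, c]) next
    v <- m[r, c]
    plateau <- matrix(c(r, c), 1)
    seen[r, c] <- TRUE
    frontier <- plateau
    is_min <- TRUE
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (i in seq_len(nrow(frontier))) {
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- frontier[i, 1] + dr; cc <- frontier[i, 2] + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (m[rr, cc] < v) is_min <- FALSE
          if (m[rr, cc] == v && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            nxt <- rbind(nxt, c(rr, cc))
            plateau <- rbind(plateau, c(rr, cc))
          }
        }
      }
      frontier <- if (is.null(nxt)) matrix(numeric(0), 0, 2) else nxt
    }
    if (is_min) {
      nextl <- nextl + 1L
      lab[plateau] <- nextl
    }
  }
  lab
}

# plain-R Meyer flooding with the same contract as the compiled watershed:
# 8-connected, queue ordered by (value, discovery order), lines where two
# labels meet, lines do not extend the flood
oracle_watershed <- function(m, seeds) {
  nr <- nrow(m); nc <- ncol(m); n <- nr * nc
  lab <- as.integer(seeds)
  queued <- lab > 0L
  qval <- numeric(0); qord <- numeric(0); qidx <- integer(0)
  ord <- 0
  nbrs <- function(idx) {
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    out <- integer(0)
    for (dc in -1:1) for (dr in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      out <- c(out, rr + (cc - 1L) * nr)
    }
    out
  }
  push <- function(u) {
    ord <<- ord + 1
    qval <<- c(qval, m[u]); qord <<- c(qord, ord); qidx <<- c(qidx, u)
  }
  for (i in seq_len(n)) {
    if (lab[i] == 0L) next
    for (u in nbrs(i)) if (!queued[u]) { queued[u] <- TRUE; push(u) }
  }
  while (length(qidx) > 0) {
    best <- order(qval, qord)[1]
    p <- qidx[best]
    qval <- qval[-best]; qord <- qord[-best]; qidx <- qidx[-best]
    ls <- unique(lab[nbrs(p)]); ls <- ls[ls > 0L]
    if (length(ls) > 1) { lab[p] <- 0L; next }
    lab[p] <- ls
    for (u in nbrs(p)) if (!queued[u]) { queued[u] <- TRUE; push(u) }
  }
  matrix(lab, nr, nc)
}

# exact Mann-Whitney p by exhaustive enumeration of group assignments
oracle_mw_exact_p <- function(x, y, alternative = "two_sided") {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    rx <- rank(pooled)[idx]
    sum(rx) - nx * (nx + 1) / 2
  }
  obs <- u_of(seq_len(nx))
  all_u <- apply(utils::combn(nx + ny, nx), 2, u_of)
  switch(alternative,
    two_sided = min(1, 2 * min(mean(all_u <= obs), mean(all_u >= obs))),
    less = mean(all_u <= obs),
    greater = mean(all_u >= obs))
}

# hand-rolled Gaussian KDE mode count on a fixed grid
oracle_kde_modes <- function(x, bw, grid_n = 512) {
  g <- seq(min(x) - 3 * bw, max(x) + 3 * bw, length.out = grid_n)
  dens <- vapply(g, function(gi) mean(dnorm((gi - x) / bw)) / bw, numeric(1))
  sum(diff(sign(diff(dens))) == -2)
}

# dense grid search over (kd, h) for the fixed-plateau Hill RSS
oracle_hill_grid_rss <- function(conc, fb, n_grid = 200) {
  kds <- exp(seq(log(min(conc) / 4), log(max(conc) * 4), length.out = n_grid))
  hs <- seq(0.2, 8, length.out = n_grid)
  best <- Inf
  for (kd in kds) {
    pred <- outer(conc, hs, function(a, h) a^h / (kd^h + a^h))
    rss <- colSums((fb - pred)^2)
    best <- min(best, min(rss))
  }
  best
}

# centroid-based 1-to-1 matching of recovered caps to ground truth
match_caps <- function(truth_table, rec_table, pixel_size_um, tol_px = 2) {
  d2 <- outer(truth_table$centroid_x_um, rec_table$centroid_x_um, "-")^2 +
    outer(truth_table$centroid_y_um, rec_table$centroid_y_um, "-")^2
  nn <- apply(d2, 1, which.min)
  dist_px <- sqrt(d2[cbind(seq_len(nrow(truth_table)), nn)]) / pixel_size_um
  matched <- dist_px <= tol_px & !duplicated(nn)
  list(matched = matched, nn = nn,
       rel_area_err = abs(rec_table$area_um2[nn] - truth_table$area_um2) /
         truth_table$area_um2)
}
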