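# Independent brute-force oracles and random-input generators used across the
# suite. These deliberately re-derive results by the most literal method
# available (exhaustive scans, BFS floods, winding numbers) so they share no
# code path with the package implementation.

# Winding-number point-in-polygon (boundary counts as inside), scalar.
oracle_point_in_polygon <- function(r, c, verts) {
  n <- nrow(verts)
  wn <- 0
  for (i in seq_len(n)) {
    a <- verts[i, ]
    b <- verts[if (i == n) 1L else i + 1L, ]
    # boundary check
    cr <- (b[1] - a[1]) * (c - a[2]) - (b[2] - a[2]) * (r - a[1])
    if (abs(cr) < 1e-9 &&
        r >= min(a[1], b[1]) - 1e-9 && r <= max(a[1], b[1]) + 1e-9 &&
        c >= min(a[2], b[2]) - 1e-9 && c <= max(a[2], b[2]) + 1e-9) {
      return(TRUE)
    }
    if (a[2] <= c) {
      if (b[2] > c && cr > 0) wn <- wn + 1
    } else {
      if (b[2] <= c && cr < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# BFS flood-fill labeling, 8-connectivity.
oracle_flood_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- p[1] + dr; c2 <- p[2] + dc
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              mask[r2, c2] && lab[r2, c2] == 0L) {
            lab[r2, c2] <- cur
            queue[[length(queue) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

# Exhaustive Otsu: try every candidate threshold, compute the between-class
# variance from first principles, return the first maximizer.
oracle_otsu <- function(v) {
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 0:(max(v) - 1L)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v)
    w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) {
      best_s <- s
      best_t <- t
    }
  }
  best_t
}

# Star-shaped random polygon around a center: always simple.
random_simple_polygon <- function(frame = 64, n_vert = sample(3:8, 1)) {
  ctr <- stats::runif(2, frame * 0.35, frame * 0.6)
  ang <- sort(stats::runif(n_vert, 0, 2 * pi))
  rad <- stats::runif(n_vert, frame * 0.1, frame * 0.3)
  v <- cbind(ctr[1] + rad * cos(ang), ctr[2] + rad * sin(ang))
  v <- pmin(pmax(v, 0), frame - 1)
  v
}

# One 8-connected random blob: union of a few overlapping disks, largest
# component kept.
random_blob <- function(frame = 48L, n_disks = sample(2:4, 1)) {
  mask <- matrix(FALSE, frame, frame)
  ctr <- c(stats::runif(1, frame * 0.3, frame * 0.7),
           stats::runif(1, frame * 0.3, frame * 0.7))
  pos <- ctr
  for (i in seq_len(n_disks)) {
    rad <- stats::runif(1, 2.5, 6)
    rr <- outer(seq_len(frame) - pos[1], rep(1, frame))
    cc <- outer(rep(1, frame), seq_len(frame) - pos[2])
    mask <- mask | (rr^2 + cc^2 <= rad^2)
    pos <- pos + stats::runif(2, -6, 6)
    pos <- pmin(pmax(pos, 8), frame - 8)
  }
  lab <- oracle_flood_label(mask)
  keep <- which.max(tabulate(lab[lab > 0L]))
  which(lab == keep, arr.ind = TRUE)
}

# k distinct random seed pixels from a pixel set.
random_seeds <- function(pixels, k) {
  pick <- sample(nrow(pixels), k)
  cbind(pixels[pick, 1], pixels[pick, 2])
}
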