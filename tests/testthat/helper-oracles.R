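# Independent oracles used across the test files. These deliberately use
# naive direct algorithms (exhaustive scans, flood fill, rasterization,
# full enumeration) so they share no code path with the implementation.

# exhaustive per-pixel min/max scan for the tight bounding box (0-based)
oracle_bbox_scan <- function(mask) {
  found <- FALSE
  x0 <- y0 <- Inf; x1 <- y1 <- -Inf
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] != 0) {
        found <- TRUE
        y0 <- min(y0, i - 1); y1 <- max(y1, i - 1)
        x0 <- min(x0, j - 1); x1 <- max(x1, j - 1)
      }
    }
  }
  if (!found) return(NULL)
  c(x_min = as.integer(x0), y_min = as.integer(y0),
    x_max = as.integer(x1), y_max = as.integer(y1))
}

# stack-based flood fill, 8-connectivity
oracle_flood_fill <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (sj in seq_len(W)) {
    for (si in seq_len(H)) {
      if (mask[si, sj] == 0 || lab[si, sj] != 0) next
      nxt <- nxt + 1L
      stack <- list(c(si, sj))
      lab[si, sj] <- nxt
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ni <- p[1] + di; nj <- p[2] + dj
          if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
              mask[ni, nj] != 0 && lab[ni, nj] == 0) {
            lab[ni, nj] <- nxt
            stack[[length(stack) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# paint two boxes on a pixel grid and count overlap / union pixels
oracle_iou_raster <- function(a, b) {
  W <- max(a$x_max, b$x_max) + 1L
  H <- max(a$y_max, b$y_max) + 1L
  ga <- matrix(FALSE, H, W); gb <- matrix(FALSE, H, W)
  ga[(a$y_min:a$y_max) + 1L, (a$x_min:a$x_max) + 1L] <- TRUE
  gb[(b$y_min:b$y_max) + 1L, (b$x_min:b$x_max) + 1L] <- TRUE
  sum(ga & gb) / sum(ga | gb)
}

# pixel-by-pixel direct evaluation of the diffusion update:
# out[p] = in[p] + lambda/4 * sum_q exp(-((Iq-Ip)/k)^2) * (Iq-Ip),
# q over N/S/E/W with replicate borders
oracle_diffusion_direct <- function(img, k, lambda) {
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- min(max(i + d[1], 1), H)
        nj <- min(max(j + d[2], 1), W)
        dd <- img[ni, nj] - img[i, j]
        acc <- acc + exp(-(dd / k)^2) * dd
      }
      out[i, j] <- img[i, j] + lambda / 4 * acc
    }
  }
  out
}

# direct global histogram equalization: map each pixel to the CDF of its bin
oracle_global_he <- function(img, n_bins) {
  bin <- pmin(floor(pmin(pmax(img, 0), 1) * n_bins) + 1L, n_bins)
  cdf <- cumsum(tabulate(bin, nbins = n_bins)) / length(img)
  matrix(cdf[bin], nrow(img), ncol(img))
}

# exhaustive enumeration of injective prediction -> ground-truth
# assignments (same class, IoU strictly above threshold) maximizing TP
oracle_max_tp <- function(preds, gts, iou_threshold) {
  np <- nrow(preds); ng <- nrow(gts)
  if (np == 0 || ng == 0) return(0L)
  feasible <- matrix(FALSE, np, ng)
  for (i in seq_len(np)) {
    for (j in seq_len(ng)) {
      feasible[i, j] <- preds$class[i] == gts$class[j] &&
        iou(preds[i, ], gts[j, ]) > iou_threshold
    }
  }
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    recurse(i + 1, used, count)                 # leave prediction i unmatched
    for (j in seq_len(ng)) {
      if (!used[j] && feasible[i, j]) {
        used[j] <- TRUE
        recurse(i + 1, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, ng), 0L)
  best
}

# random sparse binary mask
random_mask <- function(H = 16, W = 16, density = 0.1) {
  matrix(as.integer(runif(H * W) < density), H, W)
}

# random integer box within a frame, as a one-row tibble
random_box <- function(size = 30, max_wh = 12) {
  x0 <- sample(0:(size - 2), 1); y0 <- sample(0:(size - 2), 1)
  x1 <- as.integer(min(size - 1, x0 + sample(0:max_wh, 1)))
  y1 <- as.integer(min(size - 1, y0 + sample(0:max_wh, 1)))
  tibble::tibble(x_min = x0, y_min = y0, x_max = x1, y_max = y1)
}

# tiny phantom set reused by the training tests
phantom_batch <- function(n, size = 64, seed_offset = 0) {
  lapply(seq_len(n), function(i) {
    generate_phantom(phantom_spec(
      height = size, width = size,
      lesion_class = if (i %% 2 == 0) "malignant" else "benign",
      seed = i + seed_offset))
  })
}

# n-fold 8-neighbourhood dilation (logical matrix), pure R
dilate_test <- function(m, times = 1) {
  m <- m > 0
  H <- nrow(m); W <- ncol(m)
  for (t in seq_len(times)) {
    out <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      src_r <- seq_len(H) - dr
      src_c <- seq_len(W) - dc
      ok_r <- src_r >= 1 & src_r <= H
      ok_c <- src_c >= 1 & src_c <= W
      shifted <- matrix(FALSE, H, W)
      shifted[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
      out <- out | shifted
    }
    m <- out
  }
  m
}

erode_test <- function(m, times = 1) !dilate_test(!(m > 0), times)
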