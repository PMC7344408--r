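# Independent brute-force oracles used to check the implementation.
# These deliberately share no code with the package internals.

# mirror an out-of-range index back into 1..n (edge-inclusive reflection)
refl_index <- function(i, n) {
  if (i < 1L) return(1L - i)
  if (i > n) return(2L * n + 1L - i)
  i
}

# per-pixel nested-loop 2D correlation with mirror padding
brute_conv_reflect <- function(x, kernel) {
  k <- nrow(kernel)
  pad <- (k - 1L) %/% 2L
  h <- nrow(x)
  w <- ncol(x)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      acc <- 0
      for (i in seq_len(k)) {
        for (j in seq_len(k)) {
          rr <- refl_index(r + i - 1L - pad, h)
          cc <- refl_index(c + j - 1L - pad, w)
          acc <- acc + kernel[i, j] * x[rr, cc]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# mask pixels with at least one 4-neighbor of 0 (outside the image counts as 0)
boundary4_set <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (mask[r, c] != 1L) next
      nb <- c(
        if (r > 1L) mask[r - 1L, c] else 0L,
        if (r < h) mask[r + 1L, c] else 0L,
        if (c > 1L) mask[r, c - 1L] else 0L,
        if (c < w) mask[r, c + 1L] else 0L
      )
      if (any(nb == 0L)) out[r, c] <- TRUE
    }
  }
  out
}

# queue-based flood fill component labelling (8- or 4-connected)
flood_fill_label <- function(mask, connectivity = 8L) {
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  for (start in which(mask == 1L & lab == 0L)) {
    if (lab[start] != 0L || mask[start] != 1L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[1L]
      queue <- queue[-1L]
      r <- (p - 1L) %% h + 1L
      c <- (p - 1L) %/% h + 1L
      for (k in seq_along(dr)) {
        rr <- r + dr[k]
        cc <- c + dc[k]
        if (rr < 1L || rr > h || cc < 1L || cc > w) next
        q <- (cc - 1L) * h + rr
        if (mask[q] == 1L && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# random 8-bit RGB image of side n
random_rgb <- function(n, seed) {
  set.seed(seed)
  rgb_image(array(sample(0:255, n * n * 3L, replace = TRUE), dim = c(n, n, 3L)))
}

# random 0/1 plane with given foreground probability
random_plane <- function(h, w, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(as.integer(runif(h * w) < p), h, w)
}

# shoelace signed area of a closed pixel path (x = col, y = row);
# negative = counterclockwise as displayed with row 1 at the top
contour_signed_area <- function(contour) {
  x <- contour$col
  y <- contour$row
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}
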