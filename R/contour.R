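#' Trace the ordered border contour of a lesion mask
#'
#' Walks the crack boundary (the polyline of pixel edges separating foreground
#' from background) of the mask's 1-region and records the foreground pixel
#' adjacent to each traversed edge, collapsing consecutive duplicates. The
#' result is the outer border of the component containing the
#' topmost-then-leftmost foreground pixel, as a closed 8-connected path that
#' starts at that pixel and runs counterclockwise as the image is displayed
#' (row 1 at the top). Every contour pixel is a mask pixel with at least one
#' 4-neighbor outside the mask, and for a hole-free connected mask the contour
#' visits exactly that set.
#'
#' Diagonal saddle configurations are resolved toward 8-connectivity, so a
#' region that is 8-connected but not 4-connected still yields a single closed
#' path (pixels on one-pixel-wide necks may appear more than once).
#'
#' @param mask Integer 0/1 matrix.
#' @return A tibble with integer columns `row` and `col`, one row per contour
#'   step; zero rows for an empty mask.
#' @export
trace_border <- function(mask) {
  assert_binary_matrix(mask, "mask")
  fgpix <- which(mask == 1L)
  if (!length(fgpix)) {
    return(tibble::tibble(row = integer(), col = integer()))
  }
  h <- nrow(mask)
  w <- ncol(mask)
  fg <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && mask[r, c] == 1L

  # topmost-then-leftmost foreground pixel
  cand <- arrayInd(fgpix, dim(mask))
  ord <- order(cand[, 1L], cand[, 2L])
  r0 <- cand[ord[1L], 1L]
  c0 <- cand[ord[1L], 2L]

  # vertex (i, j) = bottom-right corner of pixel (i, j); directions 1=E 2=S 3=W 4=N
  # walk with foreground on the right-hand side (visually clockwise)
  valid_move <- function(i, j, d) {
    switch(d,
      fg(i + 1L, j + 1L) && !fg(i, j + 1L),     # E
      fg(i + 1L, j)      && !fg(i + 1L, j + 1L), # S
      fg(i, j)           && !fg(i + 1L, j),      # W
      fg(i, j + 1L)      && !fg(i, j)            # N
    )
  }
  step_delta <- list(c(0L, 1L), c(1L, 0L), c(0L, -1L), c(-1L, 0L))
  pixel_of_move <- function(i, j, d) {
    switch(d,
      c(i + 1L, j + 1L), # E
      c(i + 1L, j),      # S
      c(i, j),           # W
      c(i, j + 1L)       # N
    )
  }
  turn_left <- c(4L, 1L, 2L, 3L)
  turn_right <- c(2L, 3L, 4L, 1L)

  vi <- r0 - 1L
  vj <- c0 - 1L
  d0 <- 1L # east along the top edge of the start pixel
  stopifnot(valid_move(vi, vj, d0))

  rows <- integer(0)
  cols <- integer(0)
  i <- vi
  j <- vj
  d <- d0
  maxit <- 8L * (h + 1L) * (w + 1L)
  for (it in seq_len(maxit)) {
    px <- pixel_of_move(i, j, d)
    n <- length(rows)
    if (n == 0L || rows[n] != px[1L] || cols[n] != px[2L]) {
      rows <- c(rows, px[1L])
      cols <- c(cols, px[2L])
    }
    i <- i + step_delta[[d]][1L]
    j <- j + step_delta[[d]][2L]
    # prefer the left turn: hugs the region and crosses diagonal saddles
    nd <- NA_integer_
    for (try in c(turn_left[d], d, turn_right[d], turn_right[turn_right[d]])) {
      if (valid_move(i, j, try)) {
        nd <- try
        break
      }
    }
    if (is.na(nd)) stop("contour walk failed (internal error)", call. = FALSE)
    if (i == vi && j == vj && nd == d0) break
    d <- nd
  }
  n <- length(rows)
  if (n > 1L && rows[n] == rows[1L] && cols[n] == cols[1L]) {
    rows <- rows[-n]
    cols <- cols[-n]
  }
  # reverse to counterclockwise (as displayed), keeping the start pixel first
  if (length(rows) > 1L) {
    idx <- c(1L, rev(seq_along(rows)[-1L]))
    rows <- rows[idx]
    cols <- cols[idx]
  }
  tibble::tibble(row = as.integer(rows), col = as.integer(cols))
}
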