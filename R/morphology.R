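#' Label connected components of a binary matrix
#'
#' Foreground components are found by building the pixel-adjacency graph
#' (8- or 4-connected) and extracting its connected components. Labels are
#' renumbered deterministically: component 1 contains the foreground pixel
#' with the smallest linear index.
#'
#' @param mask Integer 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix; 0 = background, 1..k = component label.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_binary_matrix(mask, "mask")
  if (!connectivity %in% c(4L, 8L)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  h <- nrow(mask)
  w <- ncol(mask)
  fg <- which(mask == 1L)
  lab <- matrix(0L, h, w)
  if (!length(fg)) return(lab)

  fg_index <- integer(h * w) # linear pixel index -> foreground vertex id
  fg_index[fg] <- seq_along(fg)

  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- vector("list", length(offsets))
  for (oi in seq_along(offsets)) {
    dr <- offsets[[oi]][1L]
    dc <- offsets[[oi]][2L]
    r1 <- seq_len(h - dr)
    c1 <- if (dc >= 0L) seq_len(w - dc) else seq(1L - dc, w)
    a <- mask[r1, c1, drop = FALSE] == 1L
    b <- mask[r1 + dr, c1 + dc, drop = FALSE] == 1L
    both <- which(a & b)
    if (!length(both)) next
    rr <- r1[(both - 1L) %% length(r1) + 1L]
    cc <- c1[(both - 1L) %/% length(r1) + 1L]
    ia <- (cc - 1L) * h + rr
    ib <- (cc + dc - 1L) * h + rr + dr
    edges[[oi]] <- rbind(fg_index[ia], fg_index[ib])
  }
  el <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(el) && ncol(el)) g <- igraph::add_edges(g, as.vector(el))
  memb <- igraph::components(g)$membership
  # renumber by first occurrence in linear-index order
  relab <- integer(max(memb))
  nxt <- 0L
  for (v in seq_along(fg)) {
    m <- memb[v]
    if (relab[m] == 0L) {
      nxt <- nxt + 1L
      relab[m] <- nxt
    }
  }
  lab[fg] <- relab[memb]
  lab
}

#' Fill interior holes of a binary mask
#'
#' A hole is a 4-connected background component that does not touch the image
#' border (the standard complement-connectivity dual of 8-connected
#' foreground).
#'
#' @param mask Integer 0/1 matrix.
#' @return Integer 0/1 matrix with holes set to 1.
#' @export
fill_holes <- function(mask) {
  assert_binary_matrix(mask, "mask")
  bg <- 1L - mask
  if (!any(bg == 1L)) return(mask)
  lab <- label_components(bg, connectivity = 4L)
  h <- nrow(mask)
  w <- ncol(mask)
  border_labels <- unique(c(lab[1L, ], lab[h, ], lab[, 1L], lab[, w]))
  border_labels <- border_labels[border_labels > 0L]
  hole <- lab > 0L & !(lab %in% border_labels)
  out <- mask
  out[hole] <- 1L
  out
}
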