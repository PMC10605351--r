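#' Label connected components of a binary grid
#'
#' Foreground pixels (`TRUE`/nonzero) are grouped into connected
#' components under 4- or 8-connectivity by building the pixel
#' adjacency graph and extracting its connected components. Labels are
#' consecutive integers `1..N`, assigned in column-major scan order of
#' each component's first pixel, so labeling is deterministic.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal
#'   neighbours; the common particle-analysis default).
#' @return Integer matrix of the same dimensions; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(out)

  # vertex id = rank of the pixel's linear index within `idx`
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)

  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))

  edges <- vector("list", length(shifts))
  for (s in seq_along(shifts)) {
    dr <- shifts[[s]][1]; dc <- shifts[[s]][2]
    rows <- seq_len(nr - dr)
    cols <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    a <- mask[rows, cols, drop = FALSE]
    b <- mask[rows + dr, cols + dc, drop = FALSE]
    hit <- which(a & b)
    if (!length(hit)) next
    # linear indices in the full matrix for both endpoints
    r0 <- (hit - 1L) %% length(rows) + rows[1]
    c0 <- (hit - 1L) %/% length(rows) + cols[1]
    p <- (c0 - 1L) * nr + r0
    q <- (c0 + dc - 1L) * nr + (r0 + dr)
    edges[[s]] <- rbind(vid[p], vid[q])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(em) && length(em)) g <- igraph::add_edges(g, as.vector(em))
  memb <- igraph::components(g)$membership

  # relabel components 1..N by first occurrence in scan order
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  out[idx] <- relab[memb]
  out
}

#' Per-label summaries of a label map
#'
#' @param label_map Integer matrix as returned by [label_components()].
#' @return Data frame with one row per label: `label`, `pixel_count`,
#'   bounding box (`row_min`, `col_min`, `row_max`, `col_max`; 1-based,
#'   inclusive) and `touches_border`.
#' @keywords internal
component_records <- function(label_map) {
  nr <- nrow(label_map); nc <- ncol(label_map)
  idx <- which(label_map > 0)
  if (!length(idx)) {
    return(data.frame(label = integer(0), pixel_count = integer(0),
                      row_min = integer(0), col_min = integer(0),
                      row_max = integer(0), col_max = integer(0),
                      touches_border = logical(0)))
  }
  lab <- label_map[idx]
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  f <- factor(lab, levels = sort(unique(lab)))
  data.frame(
    label = as.integer(levels(f)),
    pixel_count = as.integer(tabulate(f)),
    row_min = as.integer(tapply(r, f, min)),
    col_min = as.integer(tapply(c, f, min)),
    row_max = as.integer(tapply(r, f, max)),
    col_max = as.integer(tapply(c, f, max)),
    touches_border = as.logical(
      tapply(r == 1L | r == nr | c == 1L | c == nc, f, any)),
    row.names = NULL
  )
}
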