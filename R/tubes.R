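#' Morphological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' Iterative thinning to a 1-pixel-wide, 8-connected skeleton. Each
#' iteration is fully vectorized over the grid; iteration stops at a fixed
#' point.
#'
#' @param g logical matrix
#' @return logical matrix of skeleton pixels
#' @export
skeletonize <- function(g) {
  stopifnot(is.matrix(g), is.logical(g))
  nr <- nrow(g); nc <- ncol(g)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- g
  g <- pad
  shift <- function(m, di, dj) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    ri <- (1 + max(di, 0)):(nrow(m) + min(di, 0))
    rj <- (1 + max(dj, 0)):(ncol(m) + min(dj, 0))
    out[ri, rj] <- m[ri - di, rj - dj]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbours P2..P9 clockwise from north (di = -1 is up/north)
      p2 <- shift(g, -1,  0); p3 <- shift(g, -1,  1); p4 <- shift(g, 0,  1)
      p5 <- shift(g,  1,  1); p6 <- shift(g,  1,  0); p7 <- shift(g, 1, -1)
      p8 <- shift(g,  0, -1); p9 <- shift(g, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1) {
        cond <- g & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- g & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        g[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  g[2:(nr + 1), 2:(nc + 1)]
}

# Trace the skeleton into segments between nodes (endpoints, junctions).
# Returns a list of segment geodesic lengths in pixels-units (step 1 for
# axial moves, sqrt(2) for diagonal moves). Isolated cycles count as one
# segment each.
skeleton_segments <- function(sk) {
  idx <- which(sk, arr.ind = TRUE)
  if (nrow(idx) == 0) return(numeric(0))
  nr <- nrow(sk); nc <- ncol(sk)
  key <- function(i, j) (j - 1L) * nr + i
  offs <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  neighbors <- function(i, j) {
    ii <- i + offs[, 1]; jj <- j + offs[, 2]
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    ii <- ii[ok]; jj <- jj[ok]
    keep <- sk[cbind(ii, jj)]
    cbind(ii[keep], jj[keep])
  }
  deg <- integer(nrow(idx))
  for (r in seq_len(nrow(idx)))
    deg[r] <- nrow(neighbors(idx[r, 1], idx[r, 2]))
  degmap <- matrix(0L, nr, nc)
  degmap[idx] <- deg
  is_node <- degmap != 2 & sk   # endpoints (1) and junctions (>= 3)
  step_len <- function(a, b) if (abs(a[1] - b[1]) + abs(a[2] - b[2]) == 2) sqrt(2) else 1

  visited_edge <- new.env(hash = TRUE, parent = emptyenv())
  edge_key <- function(a, b) {
    ka <- key(a[1], a[2]); kb <- key(b[1], b[2])
    paste0(min(ka, kb), "_", max(ka, kb))
  }
  lengths <- numeric(0)
  node_idx <- which(is_node, arr.ind = TRUE)
  for (r in seq_len(nrow(node_idx))) {
    start <- node_idx[r, ]
    nbs <- neighbors(start[1], start[2])
    for (q in seq_len(nrow(nbs))) {
      first <- nbs[q, ]
      ek <- edge_key(start, first)
      if (!is.null(visited_edge[[ek]])) next
      assign(ek, TRUE, visited_edge)
      len <- step_len(start, first)
      prev <- start; cur <- first
      while (!is_node[cur[1], cur[2]]) {
        nb2 <- neighbors(cur[1], cur[2])
        nxt <- nb2[!(nb2[, 1] == prev[1] & nb2[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nxt) == 0) break
        nxt <- nxt[1, ]
        assign(edge_key(cur, nxt), TRUE, visited_edge)
        len <- len + step_len(cur, nxt)
        prev <- cur; cur <- nxt
      }
      lengths <- c(lengths, len)
    }
  }
  # isolated cycles: all-degree-2 components never touched above
  if (nrow(idx) > 0) {
    touched <- vapply(seq_len(nrow(idx)), function(r) {
      nbs <- neighbors(idx[r, 1], idx[r, 2])
      any(vapply(seq_len(nrow(nbs)), function(q)
        !is.null(visited_edge[[edge_key(idx[r, ], nbs[q, ])]]), logical(1)))
    }, logical(1))
    loop_px <- idx[!touched & deg == 2, , drop = FALSE]
    if (nrow(loop_px) > 0) {
      loop_mask <- matrix(FALSE, nr, nc)
      loop_mask[loop_px] <- TRUE
      lab <- label_components(loop_mask)
      # closed loop: one segment; length approximated by its pixel count
      for (k in seq_len(attr(lab, "n_components")))
        lengths <- c(lengths, sum(lab == k))
    }
  }
  lengths
}

#' Tube-network metrics from a binarized tube image
#'
#' Skeletonizes the mask, splits the skeleton into segments between
#' endpoint/junction nodes, discards segments shorter than `min_length`
#' (default 10 um), and reports the tube count, the count normalized to
#' the ROI area (per mm^2), and the mean geodesic segment length. When a
#' control is supplied, relative metrics (`value / control value`) are
#' added; a control with zero tubes leaves them `NA` with a warning. The
#' control's own relative metrics are 1 by construction.
#'
#' @param mask a [vessel_mask()] of the binarized tube network
#' @param roi an [roi()] (or `NULL` = whole grid) defining the analyzed
#'   area
#' @param control optional `tube_network_metrics` of the matched scramble
#'   control
#' @param min_length minimum segment length to count as a tube (um)
#' @return a `tube_network_metrics`: list(tube_count, roi_area mm^2,
#'   normalized_count per mm^2, mean_tube_length um, relative_count,
#'   relative_length)
#' @export
tube_network_metrics <- function(mask, roi = NULL, control = NULL,
                                 min_length = 10) {
  stopifnot(inherits(mask, "vessel_mask"))
  s <- mask$calibration$pixel_size
  roi_grid <- resolve_roi(roi, mask)
  roi_area_mm2 <- sum(roi_grid) * s^2 / 1e6
  v <- mask$grid & roi_grid
  if (!any(v)) {
    seg_um <- numeric(0)
  } else {
    sk <- skeletonize(v)
    seg_um <- skeleton_segments(sk) * s
    seg_um <- seg_um[seg_um >= min_length]
  }
  out <- list(
    tube_count = length(seg_um),
    roi_area = roi_area_mm2,
    normalized_count = length(seg_um) / roi_area_mm2,
    mean_tube_length = if (length(seg_um)) mean(seg_um) else NA_real_,
    relative_count = NA_real_,
    relative_length = NA_real_
  )
  if (!is.null(control)) {
    stopifnot(inherits(control, "tube_network_metrics"))
    if (control$tube_count == 0) {
      vp_log("control has zero tubes; relative metrics undefined",
             level = "WARN")
    } else {
      out$relative_count <- out$normalized_count / control$normalized_count
      out$relative_length <- out$mean_tube_length / control$mean_tube_length
    }
  }
  structure(out, class = "tube_network_metrics")
}
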