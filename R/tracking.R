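# Single-organoid tracking: LAP-style frame-to-frame centroid linking with
# a second gap-closing assignment pass over track ends and starts.

#' Tracking parameters
#'
#' Defaults: 200 px maximum frame-to-frame linking distance, 200 px maximum
#' gap-closing distance, and at most 2 consecutive missed frames bridged by
#' gap closing.
#'
#' @param max_link_dist maximum frame-to-frame link distance (px).
#' @param max_gap_dist maximum gap-closing distance (px).
#' @param max_gap_frames maximum number of consecutive skipped frames.
#' @return list of class `tracking_params`.
#' @export
tracking_params <- function(max_link_dist = 200, max_gap_dist = 200,
                            max_gap_frames = 2) {
  if (max_link_dist <= 0 || max_gap_dist <= 0 || max_gap_frames <= 0)
    stop_orx("tracking parameters must be positive",
             class = "orx_validation_error")
  structure(list(max_link_dist = max_link_dist, max_gap_dist = max_gap_dist,
                 max_gap_frames = as.integer(max_gap_frames)),
            class = "tracking_params")
}

#' Extract region centroids from a label mask
#'
#' Centroid = unweighted mean of the pixel coordinates of each labeled
#' region.
#'
#' @param mask integer label matrix (0 = background).
#' @return data frame with columns `label`, `y`, `x` (one row per label).
#' @export
extract_centroids <- function(mask) {
  n <- max(mask)
  if (n == 0) return(data.frame(label = integer(0), y = numeric(0),
                                x = numeric(0)))
  H <- nrow(mask)
  idx <- which(mask > 0)
  lab <- mask[idx]
  ys <- ((idx - 1) %% H) + 1
  xs <- ((idx - 1) %/% H) + 1
  out <- data.frame(label = sort(unique(lab)))
  out$y <- as.numeric(tapply(ys, lab, mean)[as.character(out$label)])
  out$x <- as.numeric(tapply(xs, lab, mean)[as.character(out$label)])
  rownames(out) <- NULL
  out
}

# Hungarian algorithm (shortest augmenting path / Jonker-Volgenant style)
# for a square cost matrix; returns, for each row, the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  BIG <- 1e12
  cost[!is.finite(cost)] <- BIG
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1                     # columns are offset by 1 (j0=1 is virtual)
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  assign <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) assign[p[j]] <- j - 1
  assign
}

# Optimal partial matching between two point sets: minimizes
# sum of squared link distances + b * (number of unmatched points),
# with links beyond max_dist forbidden. Implemented as an augmented
# square assignment problem (real-to-dummy cost b on the diagonal).
match_points <- function(a, b_pts, max_dist) {
  na <- nrow(a); nb <- nrow(b_pts)
  if (na == 0 || nb == 0)
    return(data.frame(from = integer(0), to = integer(0)))
  bcost <- max_dist^2
  N <- na + nb
  C <- matrix(Inf, N, N)
  d2 <- outer(a[, 1], b_pts[, 1], "-")^2 + outer(a[, 2], b_pts[, 2], "-")^2
  d2[d2 > max_dist^2] <- Inf
  C[1:na, 1:nb] <- d2
  for (i in 1:na) C[i, nb + i] <- bcost          # death of a_i
  for (j in 1:nb) C[na + j, j] <- bcost          # birth of b_j
  C[(na + 1):N, (nb + 1):N] <- 0                 # dummy-dummy
  as_ <- solve_assignment(C)
  links <- data.frame(from = 1:na, to = as_[1:na])
  links <- links[links$to <= nb, , drop = FALSE]
  links <- links[is.finite(d2[cbind(links$from, links$to)]), , drop = FALSE]
  links
}

#' Link per-frame centroids into organoid tracks
#'
#' Two-pass linear-assignment tracking. Pass 1 links detections
#' frame-to-frame, minimizing total squared displacement subject to the
#' maximum linking distance; unmatched detections start new tracks. Pass 2
#' closes gaps by optimally matching track ends to later track starts
#' within the gap-closing distance and frame caps. Every detection belongs
#' to at most one track; tie-breaking is deterministic (stable label
#' order).
#'
#' @param centroid_sets list (one element per frame) of data frames with
#'   columns `label`, `y`, `x` as from [extract_centroids]. Empty frames
#'   are allowed.
#' @param params a [tracking_params].
#' @param times_h optional acquisition times recorded in the output.
#' @return data frame with columns `track_id`, `frame`, `time_h`, `label`,
#'   `y`, `x`, ordered by track then frame. Gap frames have no row.
#' @export
link_tracks <- function(centroid_sets, params = tracking_params(),
                        times_h = NULL) {
  nf <- length(centroid_sets)
  if (nf < 2)
    stop_orx("need >= 2 frames to track", class = "orx_validation_error")
  if (is.null(times_h)) times_h <- seq_len(nf)
  # detection table
  det <- list()
  for (f in seq_len(nf)) {
    cs <- centroid_sets[[f]]
    if (is.null(cs) || !nrow(cs)) next
    cs <- cs[order(cs$label), , drop = FALSE]
    det[[length(det) + 1L]] <- data.frame(frame = f, label = cs$label,
                                          y = cs$y, x = cs$x)
  }
  if (!length(det))
    return(data.frame(track_id = integer(0), frame = integer(0),
                      time_h = numeric(0), label = integer(0),
                      y = numeric(0), x = numeric(0)))
  det <- do.call(rbind, det)
  det$id <- seq_len(nrow(det))
  det$track <- NA_integer_
  next_track <- 1L
  # pass 1: frame-to-frame links
  succ <- rep(NA_integer_, nrow(det))
  for (f in 1:(nf - 1)) {
    ia <- det$id[det$frame == f]
    ib <- det$id[det$frame == f + 1]
    if (!length(ia) || !length(ib)) next
    links <- match_points(cbind(det$y[ia], det$x[ia]),
                          cbind(det$y[ib], det$x[ib]),
                          params$max_link_dist)
    succ[ia[links$from]] <- ib[links$to]
  }
  # walk segments
  has_pred <- rep(FALSE, nrow(det))
  has_pred[succ[!is.na(succ)]] <- TRUE
  seg_of <- rep(NA_integer_, nrow(det))
  seg_id <- 0L
  for (i in det$id[!has_pred]) {
    seg_id <- seg_id + 1L
    j <- i
    while (!is.na(j)) { seg_of[j] <- seg_id; j <- succ[j] }
  }
  # pass 2: gap closing between segment ends and starts
  segs <- data.frame(seg = seq_len(seg_id))
  segs$start_id <- vapply(segs$seg, function(s) min(det$id[seg_of == s]),
                          integer(1))
  segs$end_id <- vapply(segs$seg, function(s) max(det$id[seg_of == s]),
                        integer(1))
  # (det ids are frame-ordered so min/max id = first/last detection)
  ends <- det[segs$end_id, ]
  starts <- det[segs$start_id, ]
  cand_ends <- seq_len(seg_id)
  cand_starts <- seq_len(seg_id)
  gap_links <- data.frame(from_seg = integer(0), to_seg = integer(0))
  if (seg_id > 1) {
    dt <- outer(rep(1, seg_id), starts$frame) - outer(ends$frame, rep(1, seg_id))
    d2 <- outer(ends$y, starts$y, "-")^2 + outer(ends$x, starts$x, "-")^2
    feasible <- dt >= 2 & dt <= params$max_gap_frames + 1 &
      d2 <= params$max_gap_dist^2
    if (any(feasible)) {
      ge <- which(rowSums(feasible) > 0)
      gs <- which(colSums(feasible) > 0)
      C <- matrix(Inf, length(ge) + length(gs), length(ge) + length(gs))
      sub <- d2[ge, gs, drop = FALSE]
      sub[!feasible[ge, gs, drop = FALSE]] <- Inf
      C[seq_along(ge), seq_along(gs)] <- sub
      bcost <- params$max_gap_dist^2
      for (i in seq_along(ge)) C[i, length(gs) + i] <- bcost
      for (j in seq_along(gs)) C[length(ge) + j, j] <- bcost
      C[(length(ge) + 1):nrow(C), (length(gs) + 1):ncol(C)] <- 0
      as_ <- solve_assignment(C)
      for (i in seq_along(ge)) {
        j <- as_[i]
        if (j <= length(gs) && is.finite(sub[i, j]))
          gap_links <- rbind(gap_links,
                             data.frame(from_seg = ge[i], to_seg = gs[j]))
      }
    }
  }
  # merge segments through gap links
  seg_root <- seq_len(seg_id)
  if (nrow(gap_links)) {
    # follow chains deterministically (each seg has <=1 incoming/outgoing)
    nxt <- rep(NA_integer_, seg_id)
    nxt[gap_links$from_seg] <- gap_links$to_seg
    has_in <- rep(FALSE, seg_id); has_in[gap_links$to_seg] <- TRUE
    for (s in which(!has_in)) {
      j <- nxt[s]
      while (!is.na(j)) { seg_root[j] <- seg_root[s]; j <- nxt[j] }
    }
  }
  track_of_seg <- match(seg_root, unique(seg_root[order(segs$start_id)]))
  det$track <- track_of_seg[seg_of]
  out <- det[order(det$track, det$frame),
             c("track", "frame", "label", "y", "x")]
  names(out)[1] <- "track_id"
  out$time_h <- times_h[out$frame]
  rownames(out) <- NULL
  out[, c("track_id", "frame", "time_h", "label", "y", "x")]
}

#' Identity accuracy of tracks against phantom truth
#'
#' Each detection is matched to the nearest ground-truth organoid position
#' in its frame (within `match_dist`). A track's identity is the majority
#' truth id over its detections; accuracy is the fraction of matched
#' detections whose truth id equals their track's majority identity.
#'
#' @param tracks data frame from [link_tracks].
#' @param truth_tracks data frame with `track_id`, `frame`, `y`, `x`
#'   (ground truth).
#' @param match_dist maximum detection-to-truth distance (px).
#' @return fraction in `[0, 1]`.
#' @export
match_tracks_to_truth <- function(tracks, truth_tracks, match_dist = 25) {
  if (!nrow(tracks)) {
    warning("no tracks to evaluate")
    return(0)
  }
  truth_id <- rep(NA_integer_, nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    tt <- truth_tracks[truth_tracks$frame == tracks$frame[i], ]
    if (!nrow(tt)) next
    d <- sqrt((tt$y - tracks$y[i])^2 + (tt$x - tracks$x[i])^2)
    k <- which.min(d)
    if (d[k] <= match_dist) truth_id[i] <- tt$track_id[k]
  }
  ok <- !is.na(truth_id)
  if (!any(ok)) {
    warning("no detection matched truth")
    return(0)
  }
  correct <- 0L
  for (tr in unique(tracks$track_id)) {
    sel <- tracks$track_id == tr & ok
    if (!any(sel)) next
    ids <- truth_id[sel]
    maj <- as.integer(names(which.max(table(ids))))
    correct <- correct + sum(ids == maj)
  }
  correct / sum(ok)
}
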