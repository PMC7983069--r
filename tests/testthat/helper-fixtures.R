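# Shared fixtures and independent oracles, built in code at test time.

# small working-scale phantom (cached per seed within a test run)
.phantom_cache <- new.env(parent = emptyenv())

small_phantom_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(image_size = c(256, 256), n_organoids = 4,
         radius_range = c(20, 32), drift_px = c(1, 1), seed = seed),
    list(...))
  do.call(phantom_config, args)
}

small_phantom <- function(seed) {
  key <- as.character(seed)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom_series(small_phantom_config(seed))
  .phantom_cache[[key]]
}

disk_mask <- function(size, cy, cx, r) {
  yy <- matrix(seq_len(size[1]), size[1], size[2])
  xx <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# Independent brute-force NCC shift search (direct overlap sums).
brute_force_shift <- function(ref, mov, max_shift, min_overlap = 0.5) {
  H <- nrow(ref); W <- ncol(ref)
  best <- -Inf; best_sh <- c(0L, 0L)
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      ys <- max(1, 1 + dy):min(H, H + dy)
      xs <- max(1, 1 + dx):min(W, W + dx)
      if (length(ys) * length(xs) < min_overlap * H * W) next
      a <- ref[ys, xs]; b <- mov[ys - dy, xs - dx]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      v <- stats::cor(as.vector(a), as.vector(b))
      better <- v > best + 1e-12 ||
        (abs(v - best) <= 1e-12 &&
           (dy^2 + dx^2 < sum(best_sh^2) ||
              (dy^2 + dx^2 == sum(best_sh^2) &&
                 (dy < best_sh[1] || (dy == best_sh[1] && dx < best_sh[2])))))
      if (better) { best <- v; best_sh <- c(dy, dx) }
    }
  }
  list(dy = best_sh[1], dx = best_sh[2], ncc = best)
}

# Exhaustive minimum-cost partial matching between two point sets under the
# squared-distance + birth/death-cost objective used by the tracker.
brute_force_match <- function(a, b, max_dist) {
  na <- nrow(a); nb <- nrow(b); bc <- max_dist^2
  best <- Inf; best_links <- data.frame(from = integer(0), to = integer(0))
  rec <- function(i, used, links, cost) {
    if (i > na) {
      nlink <- nrow(links)
      tot <- cost + bc * (na - nlink) + bc * (nb - nlink)
      if (tot < best - 1e-9) { best <<- tot; best_links <<- links }
      return()
    }
    rec(i + 1, used, links, cost)        # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (!used[j]) {
        d2 <- sum((a[i, ] - b[j, ])^2)
        if (d2 <= bc)
          rec(i + 1, replace(used, j, TRUE),
              rbind(links, data.frame(from = i, to = j)), cost + d2)
      }
    }
  }
  rec(1, logical(nb), data.frame(from = integer(0), to = integer(0)), 0)
  list(cost = best, links = best_links)
}

# Independent tracker: sequential exhaustive frame-pair matching plus
# exhaustive gap closing, returning the partition of detections into tracks.
brute_force_tracks <- function(centroid_sets, params) {
  nf <- length(centroid_sets)
  det <- list()
  for (f in seq_len(nf)) {
    cs <- centroid_sets[[f]]
    if (is.null(cs) || !nrow(cs)) next
    cs <- cs[order(cs$label), , drop = FALSE]
    det[[length(det) + 1]] <- data.frame(frame = f, label = cs$label,
                                         y = cs$y, x = cs$x)
  }
  det <- do.call(rbind, det)
  det$id <- seq_len(nrow(det))
  succ <- rep(NA_integer_, nrow(det))
  for (f in seq_len(nf - 1)) {
    ia <- det$id[det$frame == f]; ib <- det$id[det$frame == f + 1]
    if (!length(ia) || !length(ib)) next
    bm <- brute_force_match(cbind(det$y[ia], det$x[ia]),
                            cbind(det$y[ib], det$x[ib]),
                            params$max_link_dist)
    if (nrow(bm$links)) succ[ia[bm$links$from]] <- ib[bm$links$to]
  }
  has_pred <- rep(FALSE, nrow(det)); has_pred[succ[!is.na(succ)]] <- TRUE
  seg <- rep(NA_integer_, nrow(det)); sid <- 0
  for (i in det$id[!has_pred]) {
    sid <- sid + 1; j <- i
    while (!is.na(j)) { seg[j] <- sid; j <- succ[j] }
  }
  # gap closing between segment ends and starts (exhaustive)
  ends <- vapply(seq_len(sid), function(s) max(det$id[seg == s]), integer(1))
  starts <- vapply(seq_len(sid), function(s) min(det$id[seg == s]), integer(1))
  dt <- outer(det$frame[ends], det$frame[starts],
              function(a, b) b - a)
  d2 <- outer(det$y[ends], det$y[starts], "-")^2 +
    outer(det$x[ends], det$x[starts], "-")^2
  feas <- dt >= 2 & dt <= params$max_gap_frames + 1 &
    d2 <= params$max_gap_dist^2
  ge <- which(rowSums(feas) > 0); gs <- which(colSums(feas) > 0)
  merged <- seq_len(sid)
  if (length(ge) && length(gs)) {
    a <- cbind(det$y[ends[ge]], det$x[ends[ge]])
    b <- cbind(det$y[starts[gs]], det$x[starts[gs]])
    bm <- brute_force_match(a, b, params$max_gap_dist)
    if (nrow(bm$links)) {
      keep <- feas[cbind(ge[bm$links$from], gs[bm$links$to])]
      links <- bm$links[keep, , drop = FALSE]
      for (k in seq_len(nrow(links))) {
        from <- ge[links$from[k]]; to <- gs[links$to[k]]
        merged[merged == merged[to]] <- merged[from]
      }
    }
  }
  split(det$id, merged[seg])
}

track_partition <- function(tracks) {
  key <- paste(tracks$frame, round(tracks$y, 6), round(tracks$x, 6))
  unname(lapply(split(key, tracks$track_id), sort))
}

# mean silhouette of a 2-group labelling in a score space
silhouette_mean <- function(scores, groups) {
  d <- as.matrix(stats::dist(scores))
  s <- numeric(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    own <- groups == groups[i]
    a <- mean(d[i, own & seq_len(nrow(scores)) != i])
    b <- mean(d[i, !own])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# translate image content by (ty, tx), filling vacated areas with fresh
# uniform noise (wrap-free padding)
shiftfix <- function(m, ty, tx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(stats::runif(H * W, min(m), max(m)), H, W)
  ys <- max(1, 1 + ty):min(H, H + ty)
  xs <- max(1, 1 + tx):min(W, W + tx)
  out[ys, xs] <- m[ys - ty, xs - tx]
  out
}
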