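# Region geometry: 8-connected labeling, boundary tracing, shape descriptors.

#' Label connected foreground regions (8-connectivity)
#'
#' @param mask logical or 0/1 numeric matrix.
#' @return integer matrix; 0 = background, regions numbered consecutively
#'   in order of their first pixel (column-major).
#' @export
label_regions <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)  # 4-connected components
  n <- max(lab)
  if (n == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  # merge components that touch diagonally (union-find over label ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # renumber consecutively by first occurrence in column-major order
  lab_v <- as.integer(lab)
  fg <- lab_v > 0
  lab_v[fg] <- root[lab_v[fg]]
  first <- !duplicated(lab_v[fg])
  newid <- integer(n)
  newid[lab_v[fg][first]] <- seq_len(sum(first))
  lab_v[fg] <- newid[lab_v[fg]]
  matrix(lab_v, H, W)
}

# Moore-neighbour boundary tracing (8-connected, Jacob's stopping rule).
# Returns an n x 2 matrix of boundary pixel (y, x) coordinates in traversal
# order, or a single row for an isolated pixel.
trace_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  m <- matrix(FALSE, H + 2, W + 2)
  m[2:(H + 1), 2:(W + 1)] <- mask != 0
  idx <- which(m)
  if (!length(idx)) return(matrix(numeric(0), 0, 2))
  start <- idx[1]                       # column-major first pixel
  sy <- ((start - 1) %% (H + 2)) + 1
  sx <- ((start - 1) %/% (H + 2)) + 1
  # clockwise neighbour order starting west
  off <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                ncol = 2, byrow = TRUE)  # W NW N NE E SE S SW
  pts <- matrix(NA_real_, 4 * sum(m) + 8, 2)
  np <- 0L
  cy <- sy; cx <- sx; bdir <- 1L  # backtrack direction index (pointing W)
  first_dir <- NA_integer_
  repeat {
    np <- np + 1L
    pts[np, ] <- c(cy, cx)
    found <- FALSE
    for (k in 0:7) {
      d <- ((bdir - 1L + k) %% 8L) + 1L
      ny <- cy + off[d, 1]; nx <- cx + off[d, 2]
      if (m[ny, nx]) {
        if (np == 1L) first_dir <- d
        # new backtrack: direction from new pixel to previous pixel, +1 cw
        rev_d <- ((d - 1L + 4L) %% 8L) + 1L
        bdir <- (rev_d %% 8L) + 1L
        cy <- ny; cx <- nx
        found <- TRUE
        break
      }
    }
    if (!found) break                   # isolated pixel
    if (cy == sy && cx == sx && np > 1L) break
    if (np > nrow(pts) - 2L) break      # safety
  }
  pts <- pts[seq_len(np), , drop = FALSE]
  pts[, 1] <- pts[, 1] - 1; pts[, 2] <- pts[, 2] - 1
  pts
}

# Douglas-Peucker simplification of an open polyline (keeps endpoints).
dp_simplify <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  keep <- logical(n); keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a; L2 <- sum(ab^2)
    seg <- (i + 1):(j - 1)
    if (L2 < 1e-12) {
      d <- sqrt((pts[seg, 1] - a[1])^2 + (pts[seg, 2] - a[2])^2)
    } else {
      d <- abs(ab[2] * (pts[seg, 1] - a[1]) - ab[1] * (pts[seg, 2] - a[2])) /
        sqrt(L2)
    }
    k <- which.max(d)
    if (d[k] > eps) {
      m <- seg[k]
      keep[m] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, m)
      stack[[length(stack) + 1L]] <- c(m, j)
    }
  }
  pts[keep, , drop = FALSE]
}

# Perimeter of a digital region: trace the outer boundary through pixel
# centers, simplify the staircase with Douglas-Peucker (tolerance sqrt(2)/2),
# then add the half-pixel outward-offset correction (miter joins at corners
# up to 90 degrees, round joins beyond). Exact for axis-aligned rectangles
# (a 10x10-pixel square gives 40) and asymptotically exact for disks.
perimeter_region <- function(mask) {
  bpts <- trace_boundary(mask)
  n <- nrow(bpts)
  if (n == 0) return(0)
  if (n <= 2) {  # 1-2 pixel blobs: crack-edge count
    return(crack_perimeter(mask))
  }
  closed <- bpts[n, 1] == bpts[1, 1] && bpts[n, 2] == bpts[1, 2]
  if (closed) bpts <- bpts[-n, , drop = FALSE]
  n <- nrow(bpts)
  if (n <= 2) return(crack_perimeter(mask))
  # split the closed curve at two far-apart anchors and simplify each arc
  d0 <- (bpts[, 1] - bpts[1, 1])^2 + (bpts[, 2] - bpts[1, 2])^2
  k <- which.max(d0)
  eps <- sqrt(2) / 2
  arc1 <- dp_simplify(bpts[1:k, , drop = FALSE], eps)
  arc2 <- dp_simplify(bpts[c(k:n, 1), , drop = FALSE], eps)
  poly <- rbind(arc1, arc2[-1, , drop = FALSE])
  poly <- poly[-nrow(poly), , drop = FALSE]      # closed; drop repeat of start
  m <- nrow(poly)
  if (m < 3) return(crack_perimeter(mask))
  nxt <- c(2:m, 1)
  e <- poly[nxt, ] - poly
  len <- sqrt(rowSums(e^2))
  good <- len > 1e-9
  poly <- poly[good, , drop = FALSE]
  m <- nrow(poly)
  if (m < 3) return(crack_perimeter(mask))
  nxt <- c(2:m, 1); prv <- c(m, 1:(m - 1))
  e <- poly[nxt, ] - poly
  len <- sqrt(rowSums(e^2))
  L <- sum(len)
  # signed turning angle at each vertex; positive when turning with the
  # polygon orientation (convex for the outer boundary)
  a_in <- atan2(e[prv, 1], e[prv, 2])
  a_out <- atan2(e[, 1], e[, 2])
  phi <- a_out - a_in
  phi <- (phi + pi) %% (2 * pi) - pi
  orient <- sign(sum(phi))               # total turning = +-2*pi
  s <- phi * orient                      # >0 convex, <0 concave
  d <- 0.5
  corr <- ifelse(abs(s) <= pi / 2 + 1e-9,
                 sign(s) * 2 * d * tan(abs(s) / 2),
                 sign(s) * d * abs(s))
  L + sum(corr)
}

crack_perimeter <- function(mask) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  p <- matrix(FALSE, H + 2, W + 2); p[2:(H + 1), 2:(W + 1)] <- m
  core <- p[2:(H + 1), 2:(W + 1)]
  sum(core & !p[1:H, 2:(W + 1)]) + sum(core & !p[3:(H + 2), 2:(W + 1)]) +
    sum(core & !p[2:(H + 1), 1:W]) + sum(core & !p[2:(H + 1), 3:(W + 2)])
}

#' Circularity of a binary region
#'
#' `4 * pi * area / perimeter^2`, clipped to at most 1 to absorb
#' discretization overshoot on small round regions. The perimeter is the
#' package's contour-length estimator (see [region_properties]).
#'
#' @param mask logical/numeric matrix containing a single region.
#' @return unitless circularity in `(0, 1]`.
#' @export
circularity <- function(mask) {
  a <- sum(mask != 0)
  if (a == 0) stop_orx("empty region", class = "orx_validation_error")
  p <- perimeter_region(mask)
  if (p <= 0) return(1)
  min(1, 4 * pi * a / p^2)
}

#' Sorensen-Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two binary masks; defined as 1 when
#' both masks are empty.
#'
#' @param a,b logical/numeric matrices of identical dimension.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop_orx("mask dimensions differ", class = "orx_validation_error")
  a <- a != 0; b <- b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# Convex hull of the pixel *corners* of a set of pixels (y, x centers).
pixel_corner_hull <- function(ys, xs) {
  cy <- c(ys - 0.5, ys - 0.5, ys + 0.5, ys + 0.5)
  cx <- c(xs - 0.5, xs + 0.5, xs - 0.5, xs + 0.5)
  h <- grDevices::chull(cx, cy)
  cbind(y = cy[h], x = cx[h])   # chull returns clockwise in (x, y)
}

feret_diameters <- function(hull) {
  n <- nrow(hull)
  if (n == 1) return(c(min = sqrt(2) / 2, max = sqrt(2)))
  dmax <- 0
  for (i in 1:(n - 1)) {
    d <- sqrt((hull[(i + 1):n, 1] - hull[i, 1])^2 +
              (hull[(i + 1):n, 2] - hull[i, 2])^2)
    dmax <- max(dmax, d)
  }
  if (n == 2) return(c(min = 0, max = dmax))
  # rotating calipers: min width over hull edges
  wmin <- Inf
  for (i in 1:n) {
    j <- if (i == n) 1 else i + 1
    ey <- hull[j, 1] - hull[i, 1]; ex <- hull[j, 2] - hull[i, 2]
    L <- sqrt(ey^2 + ex^2)
    if (L < 1e-12) next
    w <- max(abs(ey * (hull[, 2] - hull[i, 2]) -
                 ex * (hull[, 1] - hull[i, 1])) / L)
    wmin <- min(wmin, w)
  }
  c(min = wmin, max = dmax)
}

convex_pixel_area <- function(hull, ylim, xlim) {
  ys <- ylim[1]:ylim[2]; xs <- xlim[1]:xlim[2]
  gy <- rep(ys, times = length(xs))
  gx <- rep(xs, each = length(ys))
  inside <- rep(TRUE, length(gy))
  n <- nrow(hull)
  # hull is clockwise in (x,y) from chull => test all points on one side
  for (i in 1:n) {
    j <- if (i == n) 1 else i + 1
    cr <- (hull[j, 2] - hull[i, 2]) * (gy - hull[i, 1]) -
          (hull[j, 1] - hull[i, 1]) * (gx - hull[i, 2])
    inside <- inside & (cr <= 1e-9)
    if (!any(inside)) break
  }
  sum(inside)
}

#' Morphological descriptors of every labeled region
#'
#' Computes, per label: pixel area, perimeter (contour-length estimator:
#' Moore-traced boundary polygon simplified by Douglas-Peucker at tolerance
#' `sqrt(2)/2` px plus a half-pixel offset correction), circularity
#' (`4*pi*A/P^2`, clipped at 1), solidity (area / convex area, convex area
#' counted as pixels whose centers fall in the convex hull of pixel
#' corners), extent (area / bounding-box area), eccentricity and axis
#' lengths from the same-second-moment ellipse (with the 1/12 px
#' self-variance term), minimum and maximum Feret diameters (rotating
#' calipers on the corner hull), equivalent diameter `sqrt(4A/pi)`, the
#' centroid, and whether the region touches the image border.
#'
#' @param labels integer label matrix (0 = background).
#' @return data frame with one row per label.
#' @export
region_properties <- function(labels) {
  n <- max(labels)
  cols <- c("label", "area", "centroid_y", "centroid_x", "perimeter",
            "circularity", "solidity", "extent", "eccentricity",
            "feret_min", "feret_max", "axis_minor", "axis_major",
            "convex_area", "equiv_diameter", "border_touching")
  if (n == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    out$border_touching <- logical(0)
    return(out)
  }
  H <- nrow(labels); W <- ncol(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  ys <- ((idx - 1) %% H) + 1
  xs <- ((idx - 1) %/% H) + 1
  out <- vector("list", n)
  for (k in seq_len(n)) {
    sel <- lab == k
    y <- ys[sel]; x <- xs[sel]
    a <- length(y)
    y0 <- min(y); y1 <- max(y); x0 <- min(x); x1 <- max(x)
    sub <- matrix(FALSE, y1 - y0 + 1, x1 - x0 + 1)
    sub[cbind(y - y0 + 1, x - x0 + 1)] <- TRUE
    per <- perimeter_region(sub)
    hull <- pixel_corner_hull(y, x)
    fer <- feret_diameters(hull)
    carea <- convex_pixel_area(hull, c(y0, y1), c(x0, x1))
    # second moments with the pixel self-variance term (1/12)
    myy <- stats::var(y) * (a - 1) / a + 1 / 12
    mxx <- stats::var(x) * (a - 1) / a + 1 / 12
    mxy <- if (a > 1) sum((y - mean(y)) * (x - mean(x))) / a else 0
    common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
    major <- 2 * sqrt(2) * sqrt(mxx + myy + common)
    minor <- 2 * sqrt(2) * sqrt(max(mxx + myy - common, 0))
    ecc <- if (major > 0) sqrt(max(0, 1 - (minor / major)^2)) else 0
    out[[k]] <- data.frame(
      label = k, area = a, centroid_y = mean(y), centroid_x = mean(x),
      perimeter = per,
      circularity = if (per > 0) min(1, 4 * pi * a / per^2) else 1,
      solidity = a / max(carea, a),
      extent = a / ((y1 - y0 + 1) * (x1 - x0 + 1)),
      eccentricity = ecc,
      feret_min = fer["min"], feret_max = fer["max"],
      axis_minor = minor, axis_major = major,
      convex_area = max(carea, a),
      equiv_diameter = sqrt(4 * a / pi),
      border_touching = y0 == 1 || x0 == 1 || y1 == H || x1 == W)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
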