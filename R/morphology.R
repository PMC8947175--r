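# Internal image-morphology helpers shared by calibration, detection and
# cell counting.

# Otsu threshold of a numeric vector/matrix: the bin boundary maximising
# the between-class variance of a `levels`-bin histogram over the data
# range. With ignore_zero the histogram is built from strictly positive
# values only -- subtracted images are mostly exact zeros after clipping,
# which would otherwise dominate the background class. Returns NA when no
# usable values remain. (Histogram arithmetic is done directly; a
# dispatch-free implementation is worthwhile because thresholding runs
# three times per field in batch mode.)
otsu_threshold <- function(x, ignore_zero = FALSE, levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (ignore_zero) v <- v[v > 0]
  if (length(v) == 0L) return(NA_real_)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  h <- tabulate(bin, levels)
  mids <- (edges[-1] + edges[-(levels + 1L)]) / 2
  w0 <- cumsum(h)[-levels]
  w1 <- sum(h) - w0
  s0 <- cumsum(h * mids)[-levels]
  mu0 <- s0 / w0
  mu1 <- (sum(h * mids) - s0) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[!is.finite(between)] <- -Inf
  # empty histogram gaps between classes tie exactly; centre the
  # threshold in the tied plateau rather than hugging the lower mode
  best <- which(between >= max(between) * (1 - 1e-9))
  gap <- which(diff(best) != 1L)
  if (length(gap)) best <- best[seq_len(gap[1])]  # leading contiguous run
  edges[best[ceiling(length(best) / 2)] + 1L]
}

# pad a logical/integer matrix with `k` rows/cols of `value`
pad_matrix <- function(m, k = 1L, value = 0L) {
  out <- matrix(value, nrow(m) + 2L * k, ncol(m) + 2L * k)
  out[k + seq_len(nrow(m)), k + seq_len(ncol(m))] <- m
  out
}

shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# connected-component labelling. EBImage::bwlabel is 4-connected; the
# 8-connectivity used by particle counting is obtained by merging
# 4-components that touch diagonally (union-find over the few label
# pairs). Plain 4-connectivity falls back to iterative minimum-label
# propagation for the small masks it is used on.
label_components <- function(mask, connectivity = 8L) {
  mask <- mask != 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (connectivity == 8L) {
    lab <- matrix(as.integer(EBImage::bwlabel(mask)),
                  nrow(mask), ncol(mask))
    n <- max(lab)
    if (n > 1L) {
      nr <- nrow(lab); nc <- ncol(lab)
      a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]     # down-right contacts
      a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]     # down-left contacts
      s1 <- a1 > 0L & b1 > 0L & a1 != b1
      s2 <- a2 > 0L & b2 > 0L & a2 != b2
      pairs <- unique(rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2])))
      if (nrow(pairs)) {
        parent <- seq_len(n)
        find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
        for (k in seq_len(nrow(pairs))) {
          ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
        root <- vapply(seq_len(n), find, integer(1))
        relab <- match(root, sort(unique(root)))
        pos <- lab > 0L
        lab[pos] <- relab[lab[pos]]
      }
    }
    return(lab)
  }
  lab <- matrix(0, nrow(mask), ncol(mask))
  lab[mask] <- which(mask)          # unique provisional labels
  repeat {
    new <- lab
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      nb <- shift_mat(lab, d[1], d[2], fill = 0)
      upd <- mask & nb > 0 & (nb < new | new == 0)
      new[upd] <- nb[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[mask] <- as.integer(factor(lab[mask]))
  out
}

# Perimeter of a binary object by weighted boundary-pixel configurations
# (Benkrid-style): each boundary pixel contributes a weight determined by
# how many of its 4- and 8-neighbours are also boundary pixels. Far more
# accurate for small objects than counting boundary pixels, and the basis
# of the circularity filter. `m` is a logical matrix containing one object
# (context-free: other objects must be masked out first).
config_perimeter <- function(m) {
  m <- pad_matrix(m != 0, 1L, FALSE)
  er <- m &
    shift_mat(m, 1L, 0L, FALSE) & shift_mat(m, -1L, 0L, FALSE) &
    shift_mat(m, 0L, 1L, FALSE) & shift_mat(m, 0L, -1L, FALSE)
  b <- (m & !er) + 0L              # boundary pixels (4-connected erosion)
  n4 <- shift_mat(b, 1L, 0L) + shift_mat(b, -1L, 0L) +
        shift_mat(b, 0L, 1L) + shift_mat(b, 0L, -1L)
  n8 <- shift_mat(b, 1L, 1L) + shift_mat(b, 1L, -1L) +
        shift_mat(b, -1L, 1L) + shift_mat(b, -1L, -1L)
  idx <- 1L + 2L * n4 + 10L * n8     # configuration code of each pixel
  w <- numeric(50)                   # w[code + 1] = weight of that code
  w[c(5, 7, 15, 17, 25, 27) + 1L] <- 1
  w[c(21, 33) + 1L] <- sqrt(2)
  w[c(13, 23) + 1L] <- (1 + sqrt(2)) / 2
  sum(w[idx[b == 1L] + 1L])
}

# Number of holes of a binary object: background regions of the padded
# bounding box not reachable from the border, using the connectivity
# complementary to the foreground's. Holes smaller than min_area pixels
# are ignored -- they are single-pixel noise dropouts, not the lumen of a
# ring. Reachability is a multi-source flood from the border (converges
# in O(patch radius) vectorised steps); only genuine hole pixels, which
# are rare, ever get labelled.
count_holes <- function(m, fg_connectivity = 8L, min_area = 1L) {
  p <- pad_matrix(m != 0, 1L, FALSE)
  bg <- !p
  bg_conn <- if (fg_connectivity == 8L) 4L else 8L
  reach <- bg
  reach[2:(nrow(bg) - 1L), 2:(ncol(bg) - 1L)] <- FALSE
  repeat {
    grow <- shift_mat(reach, 1L, 0L, FALSE) | shift_mat(reach, -1L, 0L, FALSE) |
      shift_mat(reach, 0L, 1L, FALSE) | shift_mat(reach, 0L, -1L, FALSE)
    if (bg_conn == 8L)
      grow <- grow | shift_mat(reach, 1L, 1L, FALSE) |
        shift_mat(reach, 1L, -1L, FALSE) | shift_mat(reach, -1L, 1L, FALSE) |
        shift_mat(reach, -1L, -1L, FALSE)
    new <- reach | (bg & grow)
    if (identical(new, reach)) break
    reach <- new
  }
  holes <- bg & !reach
  if (!any(holes)) return(0L)
  lab <- label_components(holes, bg_conn)
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= min_area)
}

# binary erosion / dilation by a (2k+1) box; separable shift composition,
# cheaper than a generic morphology call for the small k used here
box_erode <- function(mask, k) {
  if (k <= 0) return(mask)
  m <- mask != 0
  for (i in seq_len(k)) {
    m <- m & shift_mat(m, 1L, 0L, FALSE) & shift_mat(m, -1L, 0L, FALSE)
    m <- m & shift_mat(m, 0L, 1L, FALSE) & shift_mat(m, 0L, -1L, FALSE)
  }
  m
}

box_dilate <- function(mask, k) {
  if (k <= 0) return(mask)
  m <- mask != 0
  for (i in seq_len(k)) {
    m <- m | shift_mat(m, 1L, 0L, FALSE) | shift_mat(m, -1L, 0L, FALSE)
    m <- m | shift_mat(m, 0L, 1L, FALSE) | shift_mat(m, 0L, -1L, FALSE)
  }
  m
}
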