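# Independent brute-force oracles. These re-derive every measurement by
# direct pixel enumeration (explicit queues and loops, no shared helper
# code with the package) so they can stand as a second route against the
# vectorised implementation.

# connected-component labelling by breadth-first search
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] > 0L) next
    cur <- cur + 1L
    queue <- list(c(r, c)); lab[r, c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# weighted boundary-configuration perimeter of one object, by per-pixel
# neighbourhood inspection
oracle_perimeter <- function(pix) {
  # pix: 2-column matrix of (row, col) of the object's pixels
  inset <- function(r, c) any(pix[, 1] == r & pix[, 2] == c)
  isborder <- matrix(FALSE, nrow(pix), 1)
  for (i in seq_len(nrow(pix))) {
    r <- pix[i, 1]; c <- pix[i, 2]
    isborder[i] <- !(inset(r - 1, c) && inset(r + 1, c) &&
                       inset(r, c - 1) && inset(r, c + 1))
  }
  bset <- pix[isborder, , drop = FALSE]
  inb <- function(r, c) any(bset[, 1] == r & bset[, 2] == c)
  total <- 0
  for (i in seq_len(nrow(bset))) {
    r <- bset[i, 1]; c <- bset[i, 2]
    a <- sum(inb(r - 1, c), inb(r + 1, c), inb(r, c - 1), inb(r, c + 1))
    b <- sum(inb(r - 1, c - 1), inb(r - 1, c + 1),
             inb(r + 1, c - 1), inb(r + 1, c + 1))
    idx <- 1 + 2 * a + 10 * b
    w <- 0
    if (idx %in% c(5, 7, 15, 17, 25, 27)) w <- 1
    if (idx %in% c(21, 33)) w <- sqrt(2)
    if (idx %in% c(13, 23)) w <- (1 + sqrt(2)) / 2
    total <- total + w
  }
  total
}

# holes of one object: flood the padded background from the border with
# the complementary connectivity; unreached background regions of at
# least min_area pixels are holes
oracle_holes <- function(pix, fg_connectivity = 8, min_area = 4) {
  r0 <- min(pix[, 1]) - 1L; c0 <- min(pix[, 2]) - 1L
  h <- max(pix[, 1]) - r0 + 2L; w <- max(pix[, 2]) - c0 + 2L
  m <- matrix(FALSE, h, w)
  m[cbind(pix[, 1] - r0, pix[, 2] - c0)] <- TRUE
  conn <- if (fg_connectivity == 8) 4 else 8
  reach <- matrix(FALSE, h, w)
  queue <- list()
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if ((r == 1 || r == h || c == 1 || c == w) && !m[r, c]) {
      reach[r, c] <- TRUE; queue[[length(queue) + 1L]] <- c(r, c)
    }
  }
  nb <- if (conn == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(nrow(nb))) {
      rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
          !m[rr, cc] && !reach[rr, cc]) {
        reach[rr, cc] <- TRUE
        queue[[length(queue) + 1L]] <- c(rr, cc)
      }
    }
  }
  holes <- !m & !reach
  if (!any(holes)) return(0L)
  hl <- oracle_label(holes, conn)
  sum(tabulate(hl[hl > 0]) >= min_area)
}

# full per-pixel classification map, first-failing-rule precedence
oracle_class_map <- function(mask, nuc_mask, pixel_size_um,
                             min_area = 2, max_area = 20,
                             min_circ = 0.1, max_circ = 1,
                             connectivity = 8, overlap_max = 0.3,
                             min_hole = 4) {
  lab <- oracle_label(mask, connectivity)
  out <- matrix("", nrow(mask), ncol(mask))
  for (l in seq_len(max(lab))) {
    pixidx <- which(lab == l)
    pix <- cbind((pixidx - 1) %% nrow(mask) + 1,
                 (pixidx - 1) %/% nrow(mask) + 1)
    area <- nrow(pix) * pixel_size_um^2
    per <- oracle_perimeter(pix)
    circ <- if (per > 0) min(1, 4 * pi * nrow(pix) / per^2) else 1
    euler <- 1 - oracle_holes(pix, connectivity, min_hole)
    ovl <- mean(nuc_mask[pixidx])
    cls <- if (area < min_area || area > max_area) "rejected_size"
    else if (circ < min_circ || circ > max_circ) "rejected_shape"
    else if (euler < 1) "nuclear_origin_donut"
    else if (ovl > overlap_max) "nuclear_origin_overlap"
    else "ectopic_mito"
    out[pixidx] <- cls
  }
  out
}

# exhaustive Otsu: maximise the between-class variance over every split
# of a 256-bin histogram, evaluated from first principles
oracle_otsu <- function(v, levels = 256) {
  v <- v[v > 0]
  edges <- seq(min(v), max(v), length.out = levels + 1)
  mids <- (edges[-1] + edges[-(levels + 1)]) / 2
  counts <- sapply(seq_len(levels), function(k) {
    if (k == levels) sum(v >= edges[k] & v <= edges[k + 1])
    else sum(v >= edges[k] & v < edges[k + 1])
  })
  bc <- rep(-Inf, levels - 1)
  for (k in seq_len(levels - 1)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / w0
    mu1 <- sum(counts[(k + 1):levels] * mids[(k + 1):levels]) / w1
    bc[k] <- w0 * w1 * (mu0 - mu1)^2
  }
  # splits through an empty inter-mode gap tie exactly; take the middle
  # of the first tied run
  tied <- which(bc >= max(bc) * (1 - 1e-9))
  brk <- which(diff(tied) != 1)
  if (length(brk)) tied <- tied[1:brk[1]]
  edges[tied[ceiling(length(tied) / 2)] + 1]
}

# textbook pooled-variance two-sample t-test
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# random blob mask: scattered discs, annuli and speckle on a small grid
random_blob_mask <- function(size = 28) {
  m <- matrix(FALSE, size, size)
  for (i in seq_len(sample(1:4, 1))) {
    r <- runif(1, 1, 6); cy <- runif(1, 3, size - 2); cx <- runif(1, 3, size - 2)
    rin <- if (runif(1) < 0.3) r * runif(1, 0.35, 0.6) else 0
    d2 <- outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, `+`)
    m <- m | (d2 <= r^2 & d2 >= rin^2)
  }
  speck <- matrix(runif(size^2) < 0.04, size, size)
  m | speck
}
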