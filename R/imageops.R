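# Minimal raster utilities for the morphometry pipeline, written against
# base R matrices (row = y increasing downward, column = x; 0-based pixel
# centers at integer coordinates for all exported geometry). Kept internal:
# the package needs only Gaussian smoothing, Otsu thresholding, binary
# morphology with a disk, connected components, hole filling, bilinear
# sampling and a distance-to-background transform, all at the ~100 x 100 px
# scale of the line-scan field of view.

# 1D Gaussian convolution matrix with replicate padding
gauss_conv_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  K <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    j <- pmin(pmax(seq_len(n) + o, 1L), n)   # replicate boundary
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + kern[o + r + 1]
  }
  K
}

# separable Gaussian blur of a matrix
gaussian_blur <- function(img, sigma = 1) {
  if (sigma <= 0) return(img)
  Ky <- gauss_conv_matrix(nrow(img), sigma)
  Kx <- gauss_conv_matrix(ncol(img), sigma)
  Ky %*% img %*% t(Kx)
}

# Otsu threshold on finite values
otsu_threshold <- function(img, n_bins = 256L) {
  v <- img[is.finite(img)]
  if (!length(v)) stop("no finite pixels", call. = FALSE)
  rng <- range(v)
  if (rng[2] <= rng[1]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (utils::head(br, -1) + utils::tail(br, -1)) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

disk_offsets <- function(r) {
  d <- expand.grid(dy = -r:r, dx = -r:r)
  d[d$dy^2 + d$dx^2 <= r^2 + 1e-9, ]
}

shift_mat <- function(m, dy, dx, fill = FALSE) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

binary_dilate <- function(mask, r = 2) {
  off <- disk_offsets(r)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mat(mask, off$dy[i], off$dx[i], FALSE)
  }
  out
}

binary_erode <- function(mask, r = 2) {
  !binary_dilate(!mask, r)
}

binary_close <- function(mask, r = 2) binary_erode(binary_dilate(mask, r), r)

# connected components by iterative minimum-label propagation
# (4-connectivity); returns an integer label matrix, 0 = background.
connected_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  lab[mask] <- seq_len(sum(mask))
  labf <- matrix(Inf, ny, nx)
  labf[mask] <- lab[mask]
  repeat {
    nb <- pmin(shift_mat(labf, 1, 0, Inf), shift_mat(labf, -1, 0, Inf),
               shift_mat(labf, 0, 1, Inf), shift_mat(labf, 0, -1, Inf))
    new <- pmin(labf, nb)
    new[!mask] <- Inf
    if (all(new[mask] == labf[mask])) break
    labf <- new
  }
  out <- matrix(0L, ny, nx)
  if (any(mask)) {
    ids <- sort(unique(labf[mask]))
    out[mask] <- match(labf[mask], ids)
  }
  out
}

largest_component <- function(mask) {
  lab <- connected_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# fill holes: background regions not connected to the frame border
fill_holes <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, ny, nx)
  reach[1, ] <- bg[1, ]; reach[ny, ] <- bg[ny, ]
  reach[, 1] <- bg[, 1]; reach[, nx] <- bg[, nx]
  repeat {
    grown <- reach | (bg & (shift_mat(reach, 1, 0) | shift_mat(reach, -1, 0) |
                              shift_mat(reach, 0, 1) | shift_mat(reach, 0, -1)))
    if (all(grown == reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

# Bilinear interpolation of matrix img at 0-based (x, y) coordinates
# (x = column, y = row). Returns NA outside the frame or when any of the
# four neighbours is NA.
bilinear_sample <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1 & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  x <- pmin(x[ok], nx - 1 - 1e-9); y <- pmin(y[ok], ny - 1 - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1; j <- x0 + 1
  v00 <- img[cbind(i, j)]; v01 <- img[cbind(i, j + 1)]
  v10 <- img[cbind(i + 1, j)]; v11 <- img[cbind(i + 1, j + 1)]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  out
}

# Euclidean distance (in pixels) from every TRUE pixel of `mask` to the
# nearest background pixel adjacent to the mask; Inf for background pixels.
# Exact brute force against the inner boundary ring, adequate at this scale.
distance_to_edge <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(Inf, ny, nx)
  if (!any(mask)) return(out)
  inner <- mask & !binary_erode(mask, 1)
  # boundary reference: background pixels 4-adjacent to the mask; if the mask
  # touches the frame border, the border itself acts as boundary
  bg_adj <- !mask & (shift_mat(mask, 1, 0) | shift_mat(mask, -1, 0) |
                       shift_mat(mask, 0, 1) | shift_mat(mask, 0, -1))
  ref <- which(bg_adj, arr.ind = TRUE)
  mk <- which(mask, arr.ind = TRUE)
  if (nrow(ref) == 0) {                       # full-frame mask
    out[mask] <- Inf
    return(out)
  }
  d2 <- outer(mk[, 1], ref[, 1], "-")^2 + outer(mk[, 2], ref[, 2], "-")^2
  out[mask] <- sqrt(apply(d2, 1, min)) - 0.5  # center-to-edge convention
  out[mask] <- pmax(out[mask], 0)
  out
}
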