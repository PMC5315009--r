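# Decimated orthogonal discrete wavelet transform with periodic boundary
# handling, as needed by the wavelet-Fourier stripe filter. Only the small
# filter bank below is required; synthesis is the exact inverse of analysis
# for even-length inputs (orthonormal perfect-reconstruction pairs).

wavelet_filters <- function(name) {
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.23037781330885523, 0.71484657055254153,
            0.63088076792959036, -0.02798376941698385,
            -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728),
    db8 = c(0.054415842243104008, 0.31287159091429995,
            0.67563073629728976, 0.58535468365420673,
            -0.015829105256349306, -0.28401554296154691,
            0.00047248457391328279, 0.12874742662047847,
            -0.017369301001807547, -0.044088253930794755,
            0.013981027917398282, 0.0087460940474057766,
            -0.0048703529934515741, -0.00039174037337694705,
            0.00067544940645056933, -0.00011747678412476953),
    sym8 = c(0.0018899503327594609, -0.0003029205147213668,
             -0.014952258337048231, 0.0038087520138906151,
             0.049137179673607506, -0.027219029917056003,
             -0.051945838107709037, 0.3644418948353314,
             0.77718575170052351, 0.48135965125837221,
             -0.061273359067658524, -0.14329423835080971,
             0.0076074873249176054, 0.031695087811492981,
             -0.00054213233179114812, -0.0033824159510061256),
    stop(sprintf("unknown wavelet '%s' (supported: haar, db2, db4, db8, sym8)",
                 name)))
  g <- rev(h) * (-1)^(seq_along(h) - 1)   # quadrature mirror high-pass
  list(h = h, g = g)
}

# One analysis level along the columns of `x` (periodic, decimating):
# returns list(a, d), each with half the rows.
dwt_cols <- function(x, flt) {
  n <- nrow(x)
  stopifnot(n %% 2L == 0L)
  half <- n / 2L
  a <- matrix(0, half, ncol(x))
  d <- matrix(0, half, ncol(x))
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(flt$h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    a <- a + flt$h[k] * x[idx, , drop = FALSE]
    d <- d + flt$g[k] * x[idx, , drop = FALSE]
  }
  list(a = a, d = d)
}

# Inverse of dwt_cols.
idwt_cols <- function(a, d, flt) {
  half <- nrow(a)
  n <- 2L * half
  x <- matrix(0, n, ncol(a))
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(flt$h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    # idx has no duplicates for fixed k (stride-2 base plus constant shift)
    x[idx, ] <- x[idx, ] + flt$h[k] * a + flt$g[k] * d
  }
  x
}

# Separable 2-D analysis step: returns the four subbands of `x`.
# Naming: first letter = filter along rows-axis (dimension 1),
# second = along columns-axis (dimension 2); "a" approximation, "d" detail.
dwt2 <- function(x, flt) {
  cdec <- dwt_cols(x, flt)                   # along dimension 1
  aa_ad <- list(t(dwt_cols(t(cdec$a), flt)$a), t(dwt_cols(t(cdec$a), flt)$d))
  da_dd <- list(t(dwt_cols(t(cdec$d), flt)$a), t(dwt_cols(t(cdec$d), flt)$d))
  list(aa = aa_ad[[1]], ad = aa_ad[[2]], da = da_dd[[1]], dd = da_dd[[2]])
}

idwt2 <- function(bands, flt) {
  lo <- t(idwt_cols(t(bands$aa), t(bands$ad), flt))
  hi <- t(idwt_cols(t(bands$da), t(bands$dd), flt))
  idwt_cols(lo, hi, flt)
}
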