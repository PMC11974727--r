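# Independent oracles and small scene builders shared across the tests.

# Brute-force spatial cross-correlation PIV oracle: direct nested-shift
# correlation of zero-mean windows with the same 3-point Gaussian sub-pixel
# refinement, computed without any FFT. Independent of the implementation
# path in piv_field().
brute_piv_window <- function(wa, wb, max_shift) {
  wa <- wa - mean(wa); wb <- wb - mean(wb)
  n <- nrow(wa)
  shifts <- -max_shift:max_shift
  C <- matrix(NA_real_, length(shifts), length(shifts),
              dimnames = list(shifts, shifts))
  for (iy in seq_along(shifts)) for (ix in seq_along(shifts)) {
    dy <- shifts[iy]; dx <- shifts[ix]
    # correlate wb against wa displaced by (dy, dx): overlap region only
    ya <- max(1, 1 - dy):min(n, n - dy)
    xa <- max(1, 1 - dx):min(n, n - dx)
    C[iy, ix] <- sum(wa[ya, xa] * wb[ya + dy, xa + dx])
  }
  p <- which(C == max(C), arr.ind = TRUE)[1, ]
  gauss1 <- function(cm, cc, cp) {
    if (cm > 0 && cp > 0 && cc > 0 && (cc > cm || cc > cp)) {
      d <- (log(cm) - log(cp)) / (2 * (log(cm) + log(cp) - 2 * log(cc)))
      if (is.finite(d) && abs(d) <= 1) d else 0
    } else {
      den <- cm + cp - 2 * cc
      if (den < 0) {
        d <- (cm - cp) / (2 * den)
        if (is.finite(d) && abs(d) <= 1) d else 0
      } else 0
    }
  }
  ddy <- if (p[1] > 1 && p[1] < nrow(C)) {
    gauss1(C[p[1] - 1, p[2]], C[p[1], p[2]], C[p[1] + 1, p[2]])
  } else 0
  ddx <- if (p[2] > 1 && p[2] < ncol(C)) {
    gauss1(C[p[1], p[2] - 1], C[p[1], p[2]], C[p[1], p[2] + 1])
  } else 0
  c(dx = shifts[p[2]] + ddx, dy = shifts[p[1]] + ddy)
}

# circular (torus) shift of a matrix by (dy, dx): every window keeps full
# texture, so constructed-shift scenes have exact ground truth everywhere
circ_shift <- function(m, dy, dx) {
  n <- nrow(m); p <- ncol(m)
  m[((0:(n - 1) - dy) %% n) + 1, ((0:(p - 1) - dx) %% p) + 1]
}

smooth_noise <- function(nr, nc, sigma = 1, seed = 1) {
  set.seed(seed)
  gaussian_blur(matrix(stats::runif(nr * nc), nr, nc), sigma)
}

run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  out <- suppressWarnings(system2("python", f, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  }
  out
}
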