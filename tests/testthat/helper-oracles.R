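# Independent brute-force oracles used to check the package implementations.
# These are deliberately naive (nested loops, direct definitions) and share
# no code with the package internals.

# per-pixel median filter with a given window-size map; lower median;
# windows clipped at the border
naiveMedianFilter <- function(px, win) {
  nr <- nrow(px); nc <- ncol(px)
  out <- px
  for (j in seq_len(nr)) {
    for (i in seq_len(nc)) {
      h <- (win[j, i] - 1) / 2
      vals <- px[max(1, j - h):min(nr, j + h),
                 max(1, i - h):min(nc, i + h)]
      s <- sort(as.vector(vals))
      out[j, i] <- s[(length(s) + 1) %/% 2]
    }
  }
  out
}

# 8-connected component labeling by repeated flood fill (BFS with a queue)
naiveLabel8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nr)) for (i in seq_len(nc)) {
    if (!mask[j, i] || lab[j, i] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(j, i))
    lab[j, i] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dj in -1:1) for (di in -1:1) {
        r <- p[1] + dj; c <- p[2] + di
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (mask[r, c] && lab[r, c] == 0) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# spatial energy curve straight from the definition: per level, +/-1
# indicator field, negated ordered-pair correlation plus the weighted pair
# count, pair weight (1/chebyshev)^f
naiveEnergyCurve <- function(px, R, d = 1, f = 1) {
  nr <- nrow(px); nc <- ncol(px)
  sapply(0:(R - 1), function(l) {
    B <- ifelse(px > l, 1, -1)
    e <- 0
    for (j in seq_len(nr)) for (i in seq_len(nc)) {
      for (dj in -d:d) for (di in -d:d) {
        if (dj == 0 && di == 0) next
        r <- j + dj; c <- i + di
        if (r < 1 || r > nr || c < 1 || c > nc) next
        w <- (1 / max(abs(dj), abs(di)))^f
        e <- e + w * (1 - B[j, i] * B[r, c])
      }
    }
    e
  })
}

# load a frozen DICOM fixture (hex text) into a temporary .dcm file
dicomFixture <- function(name) {
  hex <- readLines(test_path(name))
  b <- as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                               seq(2, nchar(hex), 2)), 16L))
  f <- tempfile(fileext = ".dcm")
  writeBin(b, f)
  f
}

# random phantom-free test image
randomGrayImage <- function(nr, nc, R = 256, seed = 1) {
  set.seed(seed)
  GrayImage(matrix(sample(0:(R - 1), nr * nc, replace = TRUE), nr, nc),
            levels = R)
}
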