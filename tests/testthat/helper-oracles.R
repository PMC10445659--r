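# Independent brute-force oracles shared across test files.

phansalkar_bruteforce <- function(img, radius, k = 0.25, r = 0.5, p = 2, q = 10) {
  ny <- nrow(img); nx <- ncol(img)
  rg <- range(img)
  norm <- (img - rg[1]) / diff(rg)
  ys <- c(radius:1, 1:ny, ny:(ny - radius + 1))
  xs <- c(radius:1, 1:nx, nx:(nx - radius + 1))
  padded <- norm[ys, xs]
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  out <- matrix(FALSE, ny, nx)
  for (yy in 1:ny) {
    for (xx in 1:nx) {
      vals <- padded[cbind(yy + radius + offs$dy, xx + radius + offs$dx)]
      m <- mean(vals)
      s <- sqrt(mean(vals^2) - m^2)
      thr <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
      out[yy, xx] <- norm[yy, xx] > thr
    }
  }
  out
}

random_annotation_table <- function(n, seed) {
  set.seed(seed)
  data.frame(cell_id = sample(1:40, n, replace = TRUE),
             motif = sample(c("sail", "bead", "pad", "bristle", "tube",
                              "end-foot", "hole"), n, replace = TRUE),
             axon = as.integer(runif(n) < 0.6),
             soma = as.integer(runif(n) < 0.35),
             astrocyte = as.integer(runif(n) < 0.1))
}
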