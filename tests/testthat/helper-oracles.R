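# Independent oracles, kept free of the implementation paths they check.

# dense-sampling traversal oracle: bin equally spaced points along the ray
# into voxels and convert counts to segment lengths
oracle_traverse <- function(origin, direction, grid, max_range, n = 1e4) {
  direction <- direction / sqrt(sum(direction^2))
  d <- dim(grid$values)
  hi <- grid$origin + d * grid$voxel_size
  t <- seq(0, max_range, length.out = n)
  step <- t[2] - t[1]
  px <- origin[1] + t * direction[1]
  py <- origin[2] + t * direction[2]
  pz <- origin[3] + t * direction[3]
  inside <- px >= grid$origin[1] & px < hi[1] &
    py >= grid$origin[2] & py < hi[2] &
    pz >= grid$origin[3] & pz < hi[3]
  ix <- floor((px - grid$origin[1]) / grid$voxel_size) + 1
  iy <- floor((py - grid$origin[2]) / grid$voxel_size) + 1
  iz <- floor((pz - grid$origin[3]) / grid$voxel_size) + 1
  key <- paste(ix[inside], iy[inside], iz[inside])
  counts <- table(key)
  tibble::tibble(key = names(counts), length = as.numeric(counts) * step)
}

# numeric maximiser of the weighted censored-exponential log-likelihood:
# golden-section search polished by Newton steps on the analytic score
oracle_lambda_mle <- function(intercepted, total_path, upper = 100) {
  if (intercepted == 0) return(0)
  nll <- function(lam) -(intercepted * log(lam) - lam * total_path)
  lam <- optimize(nll, c(1e-12, upper), tol = 1e-12)$minimum
  for (i in 1:6) {
    score <- intercepted / lam - total_path
    hess <- -intercepted / lam^2
    lam <- lam - score / hess
  }
  lam
}

# brute-force trailing running sum
oracle_running_sum <- function(x, window) {
  n <- length(x)
  vapply(seq_len(n), function(i) sum(x[max(1, i - window + 1):i]), numeric(1))
}
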