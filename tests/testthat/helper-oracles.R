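## Independent oracles and small fixture builders shared across tests.

## Unconstrained normal-equations solve of sample ~ alpha*m + beta*w + linear
## baseline over [lo, hi]; independent of the package's fitting code path.
oracleWaterFit <- function(wn, y, m, w, lo = 1500, hi = 1700) {
  i <- wn >= lo & wn <= hi
  X <- cbind(m[i], w[i], 1, wn[i] - mean(wn[i]))
  as.vector(solve(t(X) %*% X, t(X) %*% y[i]))
}

## Brute-force two-point linear interpolation.
oracleInterp <- function(x, y, xout) {
  vapply(xout, function(t) {
    j <- max(which(x <= t))
    if (x[j] == t) return(y[j])
    y[j] + (y[j + 1] - y[j]) * (t - x[j]) / (x[j + 1] - x[j])
  }, numeric(1))
}

## Gaussian band sum and its analytic second derivative.
gaussSum <- function(x, center, height, fwhm) {
  s <- numeric(length(x))
  for (i in seq_along(center)) {
    k <- 4 * log(2) / fwhm[i]^2
    s <- s + height[i] * exp(-k * (x - center[i])^2)
  }
  s
}
gaussSumD2 <- function(x, center, height, fwhm) {
  s <- numeric(length(x))
  for (i in seq_along(center)) {
    k <- 4 * log(2) / fwhm[i]^2
    d <- x - center[i]
    s <- s + height[i] * exp(-k * d^2) * (4 * k^2 * d^2 - 2 * k)
  }
  s
}

## A tiny paired study set built by hand: one grid, cells constructed as
## matrigel + beta * water, with paired PBS spectra.
makePairedSet <- function(betas, grid = defaultGrid()) {
  m <- absorbance(matrigelReference(grid))[, 1]
  w <- absorbance(makeWaterSpectrum(grid, chamberConfig(10)))[, 1]
  cols <- list(); info <- list()
  for (i in seq_along(betas)) {
    cid <- sprintf("c%d", i); pid <- sprintf("p%d", i)
    cols[[cid]] <- m + betas[i] * w
    cols[[pid]] <- w
    info[[cid]] <- data.frame(id = cid, role = "cell", pbs_id = pid)
    info[[pid]] <- data.frame(id = pid, role = "pbs", pbs_id = NA)
  }
  IRSpectra(grid, do.call(cbind, cols), info = do.call(rbind, info))
}

## Random smooth spectra for I/O round trips.
randomSet <- function(n = 3, p = 40, seed = 1) {
  set.seed(seed)
  wn <- sort(runif(p, 1000, 3600))
  a <- matrix(rnorm(p * n), p)
  IRSpectra(wn, a, info = data.frame(id = paste0("s", seq_len(n)),
                                     role = "cell",
                                     label = sample(letters[1:2], n, TRUE)))
}
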