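# Shared fixtures and independent oracles, built in code.

# DetectionMatrix from a named list of per-experiment unit-id sets
dmFromSets <- function(sets, unitLevel = "protein") {
  units <- unique(unlist(sets))
  m <- sapply(sets, function(s) as.integer(units %in% s))
  m <- matrix(m, nrow = length(units),
              dimnames = list(units, names(sets)))
  DetectionMatrix(m, unitLevel = unitLevel)
}

# emulate real unlabeled contamination: rename generator-injected fakes
relabelNoise <- function(m) {
  d <- detections(m)
  rownames(d) <- sub("^NOISE_", "FP_", rownames(d))
  DetectionMatrix(d, unitLevel(m))
}

# brute-force SSE grid oracle for the recovery model
gridSearchSSE <- function(pts, aGrid, bGrid, cGrid = 0) {
  best <- list(sse = Inf)
  for (a in aGrid) for (b in bGrid) for (cc in cGrid) {
    sse <- sum((pts$y - (a * (1 - exp(-pts$x / b)) + cc * pts$x))^2)
    if (sse < best$sse) best <- list(a = a, b = b, c = cc, sse = sse)
  }
  best
}

# independent loglinear oracle: direct Poisson likelihood maximization,
# bypassing glm/IRLS entirely
directLoglinearNhat <- function(h, model, dropEta = character()) {
  t <- h@t
  bits <- t(vapply(seq_len(2L^t - 1L),
                   function(i) as.integer(intToBits(i))[seq_len(t)],
                   integer(t)))
  s <- rowSums(bits)
  etaCols <- vapply(3:t, function(j) as.numeric(s >= j),
                    numeric(nrow(bits)))
  colnames(etaCols) <- paste0("eta", 3:t)
  etaCols <- etaCols[, setdiff(colnames(etaCols), dropEta), drop = FALSE]
  X <- switch(model,
    M0 = cbind(1, s),
    Mt = cbind(1, bits),
    MthChao = cbind(1, bits, etaCols))
  y <- h@frequencies
  negll <- function(beta) {
    mu <- exp(as.vector(X %*% beta))
    -sum(y * log(mu) - mu)
  }
  init <- rep(0, ncol(X))
  o <- optim(init, negll, method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-14))
  list(nHat = h@n + exp(o$par[1]), logLik = -o$value - sum(lgamma(y + 1)))
}

# capture-count frequencies f_s from a history table
captureCountFreqs <- function(h) {
  t <- h@t
  bits <- t(vapply(seq_len(2L^t - 1L),
                   function(i) as.integer(intToBits(i))[seq_len(t)],
                   integer(t)))
  tapply(h@frequencies, rowSums(bits), sum)
}
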