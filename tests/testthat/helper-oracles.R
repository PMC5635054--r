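# Independent oracles used across the suite. These deliberately avoid the
# package's own linear-algebra and labeling code paths.

# OLS via explicit SVD pseudo-inverse, with per-column t statistics
oracle_ols <- function(X, y, df = nrow(X) - qr(X)$rank) {
  s <- svd(X)
  pinv <- s$v %*% diag(1 / s$d, length(s$d)) %*% t(s$u)
  beta <- as.numeric(pinv %*% y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / df
  covb <- s$v %*% diag(1 / s$d^2, length(s$d)) %*% t(s$v)
  tstat <- beta / sqrt(sigma2 * diag(covb))
  list(beta = beta, sigma2 = sigma2, t = tstat, df = df)
}

# connected-component labels by iterative minimum-label propagation
# (flood fill run to fixpoint), independent of the graph-based labeler
flood_fill_labels <- function(mask, connectivity) {
  d <- dim(mask)
  off <- switch(as.character(connectivity),
                "6"  = rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                             c(0,0,1), c(0,0,-1)),
                "18" = {
                  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                  g[rowSums(abs(g)) %in% 1:2, , drop = FALSE]
                },
                "26" = {
                  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                  g[rowSums(abs(g)) >= 1, , drop = FALSE]
                })
  act <- which(mask)
  lab <- array(0, d)
  lab[act] <- act                      # seed with linear index
  pos <- arrayInd(act, d)
  # precompute valid neighbor linear indices per offset
  nb <- lapply(seq_len(nrow(off)), function(r) {
    np <- sweep(pos, 2, off[r, ], `+`)
    ok <- np[,1] >= 1 & np[,1] <= d[1] & np[,2] >= 1 & np[,2] <= d[2] &
          np[,3] >= 1 & np[,3] <= d[3]
    nl <- rep(NA_integer_, length(act))
    nl[ok] <- np[ok,1] + (np[ok,2]-1)*d[1] + (np[ok,3]-1)*d[1]*d[2]
    valid <- !is.na(nl)
    drop <- valid
    drop[valid] <- !mask[nl[valid]]    # neighbor outside the active set
    nl[drop] <- NA_integer_
    nl
  })
  repeat {
    cur <- lab[act]
    new <- cur
    for (r in seq_along(nb)) {
      nl <- nb[[r]]
      ok <- !is.na(nl)
      new[ok] <- pmin(new[ok], lab[nl[ok]])
    }
    if (all(new == cur)) break
    lab[act] <- new
  }
  # canonicalize to 1..K in order of first appearance
  u <- unique(lab[act])
  canon <- array(0L, d)
  canon[act] <- match(lab[act], u)
  canon
}

# partition equality of two integer label arrays (same components, any ids)
same_partition <- function(a, b) {
  act_a <- which(a > 0); act_b <- which(b > 0)
  if (!identical(act_a, act_b)) return(FALSE)
  key <- paste(a[act_a], b[act_b])
  length(unique(key)) == length(unique(a[act_a])) &&
    length(unique(key)) == length(unique(b[act_b]))
}

# minimal recording: given channel list of numeric vectors
make_rec <- function(channels, fs, markers = NULL) {
  data <- do.call(rbind, channels)
  eeg_recording(data, fs, names(channels), markers)
}

# fraction of periodogram power lying within tol_hz of multiples of f_base
harmonic_power_fraction <- function(x, fs, f_base, tol_hz = 0.05) {
  n <- length(x)
  P <- Mod(fft(x - mean(x))[seq_len(floor(n / 2))])^2
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  dist <- abs((f / f_base) - round(f / f_base)) * f_base
  sum(P[dist <= tol_hz & f >= f_base / 2]) / sum(P)
}

# total periodogram power within tol_hz of multiples of f_base (absolute)
harmonic_power <- function(x, fs, f_base, tol_hz = 0.05) {
  n <- length(x)
  P <- Mod(fft(x - mean(x))[seq_len(floor(n / 2))])^2
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  dist <- abs((f / f_base) - round(f / f_base)) * f_base
  sum(P[dist <= tol_hz & f >= f_base / 2])
}

band_power_psd <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(fft(x - mean(x))[seq_len(floor(n / 2))])^2
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  sum(P[f >= lo & f <= hi])
}
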