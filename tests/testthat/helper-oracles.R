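# Independent oracles, coded separately from the package internals.

# --- reference EMD sifting (same algorithm, independent implementation) ----

ref_extrema <- function(x) {
  rv <- rle(x)
  ends <- cumsum(rv$lengths)
  starts <- ends - rv$lengths + 1L
  mids <- (starts + ends) %/% 2L
  v <- rv$values
  m <- length(v)
  if (m < 3) return(list(max = integer(0), min = integer(0)))
  i <- 2:(m - 1)
  list(max = mids[i][v[i] > v[i - 1] & v[i] > v[i + 1]],
       min = mids[i][v[i] < v[i - 1] & v[i] < v[i + 1]])
}

ref_nat_spline <- function(xs, ys, xout) {
  m <- length(xs)
  if (m == 1) return(rep(ys, length(xout)))
  if (m == 2) return(ys[1] + (ys[2] - ys[1]) / (xs[2] - xs[1]) * (xout - xs[1]))
  h <- diff(xs)
  A <- matrix(0, m, m)
  rhs <- numeric(m)
  A[1, 1] <- 1
  A[m, m] <- 1
  for (k in 2:(m - 1)) {
    A[k, k - 1] <- h[k - 1]
    A[k, k] <- 2 * (h[k - 1] + h[k])
    A[k, k + 1] <- h[k]
    rhs[k] <- 3 * ((ys[k + 1] - ys[k]) / h[k] - (ys[k] - ys[k - 1]) / h[k - 1])
  }
  c2 <- solve(A, rhs)
  vapply(xout, function(xt) {
    seg <- max(1, min(m - 1, findInterval(xt, xs)))
    dx <- xs[seg + 1] - xs[seg]
    b <- (ys[seg + 1] - ys[seg]) / dx - dx * (2 * c2[seg] + c2[seg + 1]) / 3
    d <- (c2[seg + 1] - c2[seg]) / (3 * dx)
    u <- xt - xs[seg]
    ys[seg] + b * u + c2[seg] * u^2 + d * u^3
  }, numeric(1))
}

ref_mirror <- function(idx, v, n, nm = 2) {
  xs <- idx - 1 # 0-based positions
  sel_l <- which(xs > 0)[seq_len(min(nm, sum(xs > 0)))]
  sel_r <- rev(which(xs < n - 1))[seq_len(min(nm, sum(xs < n - 1)))]
  px <- c(-xs[sel_l], xs, 2 * (n - 1) - xs[sel_r])
  py <- c(v[idx][sel_l], v[idx], v[idx][sel_r])
  o <- order(px)
  list(x = px[o], y = py[o])
}

ref_sift_once <- function(h) {
  ex <- ref_extrema(h)
  if (length(ex$max) + length(ex$min) < 3 || !length(ex$max) || !length(ex$min))
    return(NULL)
  n <- length(h)
  up <- ref_mirror(ex$max, h, n)
  lo <- ref_mirror(ex$min, h, n)
  h - (ref_nat_spline(up$x, up$y, 0:(n - 1)) +
       ref_nat_spline(lo$x, lo$y, 0:(n - 1))) / 2
}

ref_emd <- function(x, max_imfs = 8, sd_thresh = 0.2, max_sift = 50) {
  r <- x
  imfs <- list()
  for (i in seq_len(max_imfs)) {
    ex <- ref_extrema(r)
    if (length(ex$max) + length(ex$min) < 3 || !length(ex$max) || !length(ex$min))
      break
    h <- r
    for (it in seq_len(max_sift)) {
      hn <- ref_sift_once(h)
      if (is.null(hn)) break
      sdv <- sum((h - hn)^2) / sum(h^2)
      h <- hn
      if (sdv < sd_thresh) break
    }
    imfs[[i]] <- h
    r <- r - h
  }
  list(imfs = imfs, residual = r)
}

# --- naive labeling rule (explicit loops) ---------------------------------

ref_label_imf <- function(imf, rpeaks, half_window, statistic) {
  if (length(rpeaks) == 0) return(0L)
  pp <- numeric(length(rpeaks))
  for (j in seq_along(rpeaks)) {
    lo <- rpeaks[j] - half_window
    hi <- rpeaks[j] + half_window
    if (lo < 1) lo <- 1
    if (hi > length(imf)) hi <- length(imf)
    mx <- -Inf
    mn <- Inf
    for (t in lo:hi) {
      if (imf[t] > mx) mx <- imf[t]
      if (imf[t] < mn) mn <- imf[t]
    }
    pp[j] <- mx - mn
  }
  m <- if (statistic == "median") median(pp) else max(pp)
  pg <- max(imf) - min(imf)
  if (m > 1.4 * sd(imf) && m > 0.75 * pg) 1L else 0L
}

# --- pairwise AUC with half-ties ------------------------------------------

ref_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(0.5)
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# --- optimal R-peak assignment by enumeration (small lists) ---------------

ref_match_count <- function(detected, reference, tol) {
  if (!length(detected) || !length(reference)) return(0L)
  best <- 0L
  recurse <- function(ri, used, count) {
    if (ri > length(reference)) {
      best <<- max(best, count)
      return()
    }
    recurse(ri + 1, used, count) # leave this reference unmatched
    for (di in seq_along(detected)) {
      if (!used[di] && abs(detected[di] - reference[ri]) <= tol) {
        used[di] <- TRUE
        recurse(ri + 1, used, count + 1L)
        used[di] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(detected)), 0L)
  best
}
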