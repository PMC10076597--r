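# Independent brute-force oracles and small geometry builders used across
# the suite. Oracles are deliberately naive (enumeration / sorting), never
# calling the implementation paths they check.

# smallest observed gray with cumulative frequency >= p/100
oracle_percentile <- function(g, p) {
  tab <- table(g)
  vals <- as.numeric(names(tab))
  cum <- cumsum(as.numeric(tab)) / length(g)
  vals[which(cum >= p / 100 - 1e-12)[1]]
}

# exhaustive 256-bin between-class-variance search
oracle_otsu <- function(g, vmax) {
  nb <- 256L
  bin <- pmin(floor(g / (vmax + 1) * nb), nb - 1L)
  best <- -Inf; best_k <- NA
  for (k in 1:(nb - 1)) {
    lo <- bin < k
    w0 <- mean(lo)
    if (w0 == 0 || w0 == 1) next
    bcv <- w0 * (1 - w0) * (mean(g[lo]) - mean(g[!lo]))^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  best_k / nb * (vmax + 1)
}

# exhaustive inscribed-sphere local thickness (same definition as the
# implementation, computed by full enumeration; feasible up to ~20^3)
oracle_thickness <- function(m) {
  dd <- dim(m)
  idx <- which(m == 1)
  co <- arrayInd(idx, dd)
  bg <- arrayInd(which(m == 0), dd)
  edt <- vapply(seq_along(idx), function(i) {
    p <- co[i, ]
    db <- if (nrow(bg)) sqrt(min(colSums((t(bg) - p)^2))) else Inf
    min(db, min(c(p, dd - p + 1)))
  }, 0)
  th <- numeric(length(idx))
  for (i in seq_along(idx)) {
    c0 <- co[i, ]; r <- edt[i]
    span <- 2 * ceiling(r - 1e-9) - 1
    cover <- sqrt(colSums((t(co) - c0)^2)) < r
    th[cover] <- pmax(th[cover], span)
  }
  th
}

# digitized solid ball of integer radius R (odd diameter 2R + 1)
digit_ball <- function(R, pad = 3L) {
  dd <- rep(2L * R + 2L * pad + 1L, 3)
  c0 <- (dd + 1) / 2
  Y <- array(seq_len(dd[1]), dd)
  X <- array(rep(seq_len(dd[2]), each = dd[1]), dd)
  Z <- array(rep(seq_len(dd[3]), each = dd[1] * dd[2]), dd)
  array(as.integer((Y - c0[1])^2 + (X - c0[2])^2 + (Z - c0[3])^2 <= R^2),
        dd)
}

# z-aligned digitized cylinder, integer center
digit_cylinder <- function(r, len, margin = 7L) {
  dd <- c(2L * r + 2L * margin + 1L, 2L * r + 2L * margin + 1L,
          as.integer(len))
  c0 <- r + margin + 1
  Y <- array(seq_len(dd[1]), dd)
  X <- array(rep(seq_len(dd[2]), each = dd[1]), dd)
  array(as.integer((Y - c0)^2 + (X - c0)^2 <= r^2), dd)
}

rand_gray_volume <- function(dim = c(12L, 11L, 9L), seed = 1,
                             voxel_size_um = 6, lo = 100, hi = 60000) {
  set.seed(seed)
  gray_volume(array(sample(lo:hi, prod(dim), replace = TRUE), dim),
              voxel_size_um, 16L)
}
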