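# Independent brute-force oracles, written against the definitions only.
# Deliberately slow and loop-based so they share no code path with the
# package implementations they check.

# All 26 neighbour offsets / the 13 unique directions, re-derived here.
.bf_offsets26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})
.bf_dirs13 <- .bf_offsets26[apply(.bf_offsets26, 1, function(o)
  o[3] > 0 || (o[3] == 0 && (o[2] > 0 || (o[2] == 0 && o[1] > 0)))), ,
  drop = FALSE]

bf_nglcm <- function(lab, mask, bins) {
  d <- dim(lab)
  mats <- list()
  for (k in seq_len(nrow(.bf_dirs13))) {
    off <- .bf_dirs13[k, ]
    cnt <- matrix(0, bins, bins)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (!mask[x, y, z]) next
      nx <- x + off[1]; ny <- y + off[2]; nz <- z + off[3]
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3])
        next
      if (!mask[nx, ny, nz]) next
      i <- lab[x, y, z]; j <- lab[nx, ny, nz]
      cnt[i, j] <- cnt[i, j] + 1
      cnt[j, i] <- cnt[j, i] + 1
    }
    if (sum(cnt) > 0) mats[[length(mats) + 1]] <- cnt / sum(cnt)
  }
  if (!length(mats)) stop("no pairs")
  Reduce(`+`, mats) / length(mats)
}

bf_ngtdm <- function(lab, mask, bins) {
  d <- dim(lab)
  s <- numeric(bins); cnt <- numeric(bins); n_valid <- 0
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    nb <- c()
    for (k in seq_len(nrow(.bf_offsets26))) {
      o <- .bf_offsets26[k, ]
      nx <- x + o[1]; ny <- y + o[2]; nz <- z + o[3]
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3])
        next
      if (mask[nx, ny, nz]) nb <- c(nb, lab[nx, ny, nz])
    }
    if (!length(nb)) next
    n_valid <- n_valid + 1
    l <- lab[x, y, z]
    cnt[l] <- cnt[l] + 1
    s[l] <- s[l] + abs(l - mean(nb))
  }
  list(p = cnt / n_valid, s = s, n_valid = n_valid)
}

# Product-limit estimator from the definition: at each distinct event time
# multiply by (1 - d/n_at_risk).
bf_km_at <- function(times, events, t) {
  surv <- 1
  for (u in sort(unique(times[events == 1]))) {
    if (u > t) break
    n_risk <- sum(times >= u)
    d <- sum(times == u & events == 1)
    surv <- surv * (1 - d / n_risk)
  }
  surv
}

# Two-group log-rank chi-square from the risk tables.
bf_logrank2 <- function(times, events, group) {
  g <- as.integer(as.factor(group))
  o1 <- 0; e1 <- 0; v <- 0
  for (u in sort(unique(times[events == 1]))) {
    at <- times >= u
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(times == u & events == 1)
    d1 <- sum(times == u & events == 1 & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Random small label phantoms for the texture oracle comparison.
random_label_phantom <- function(seed, max_dim = 6, bins = 4) {
  set.seed(seed)
  d <- sample(2:max_dim, 3, replace = TRUE)
  mask <- array(runif(prod(d)) < 0.7, d)
  if (sum(mask) < 2) mask[1:2] <- TRUE
  lab <- array(NA_integer_, d)
  lab[mask] <- sample.int(bins, sum(mask), replace = TRUE)
  list(lab = lab, mask = mask, bins = bins, dim = d)
}

# Wrap a label phantom as the package's label_volume.
as_label_volume <- function(ph) {
  structure(list(data = ph$lab, bins = ph$bins, mask = ph$mask),
            class = "label_volume")
}

default_times <- function(n = 80, dt = 3.3) seq(0, by = dt, length.out = n)
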