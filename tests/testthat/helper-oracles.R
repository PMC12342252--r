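# Independent brute-force oracles used to check the package's algorithms.

# O(n^2) topographic prominence straight from the definition: for every
# interior local maximum (leftmost sample of a plateau), scan outward to the
# nearest strictly higher sample (or the edge) on each side, take the lowest
# point passed on each side, and subtract the higher of the two bases.
brute_force_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  idx <- integer(0)
  prom <- numeric(0)
  for (i in 2:(n - 1)) {
    if (!(x[i] > x[i - 1])) next
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    if (j >= n || x[j + 1] > x[i]) next
    # left base
    lo_l <- x[i]
    kk <- i - 1
    while (kk >= 1 && x[kk] <= x[i]) {
      lo_l <- min(lo_l, x[kk])
      kk <- kk - 1
    }
    # right base
    lo_r <- x[i]
    kk <- i + 1
    while (kk <= n && x[kk] <= x[i]) {
      lo_r <- min(lo_r, x[kk])
      kk <- kk + 1
    }
    p <- x[i] - max(lo_l, lo_r)
    if (p >= min_prominence) {
      idx <- c(idx, i)
      prom <- c(prom, p)
    }
  }
  list(index = idx, prominence = prom)
}

# Krippendorff's alpha by explicit pair enumeration: D_o from all ordered
# pairable pairs within items (weighted 1/(m_u - 1)), D_e from all ordered
# pairs of the pooled pairable values.
brute_force_alpha <- function(m, level = "nominal") {
  m <- m[rowSums(!is.na(m)) >= 2, , drop = FALSE]
  vals_pool <- unlist(apply(m, 1, function(r) r[!is.na(r)], simplify = FALSE))
  vals <- sort(unique(vals_pool))
  nc <- sapply(vals, function(v) sum(vals_pool == v))
  n <- length(vals_pool)
  delta2 <- function(a, b) {
    if (a == b) return(0)
    if (level == "nominal") return(1)
    ia <- which(vals == min(a, b))
    ib <- which(vals == max(a, b))
    (sum(nc[ia:ib]) - (nc[ia] + nc[ib]) / 2)^2
  }
  d_o_sum <- 0
  for (u in seq_len(nrow(m))) {
    r <- m[u, ][!is.na(m[u, ])]
    mu <- length(r)
    for (a in seq_len(mu)) {
      for (b in seq_len(mu)) {
        if (a != b) d_o_sum <- d_o_sum + delta2(r[a], r[b]) / (mu - 1)
      }
    }
  }
  d_o <- d_o_sum / n
  d_e_sum <- 0
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b) d_e_sum <- d_e_sum + delta2(vals_pool[a], vals_pool[b])
    }
  }
  d_e <- d_e_sum / (n * (n - 1))
  if (d_e == 0) stop("alpha undefined")
  1 - d_o / d_e
}

# random piecewise-smooth test signal for peak-finder stress tests
random_signal <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- cumsum(rnorm(n))
  wiggle <- sin(seq(0, runif(1, 1, 8) * pi, length.out = n)) * runif(1, 0, 3)
  x <- base / max(abs(base)) + wiggle + rnorm(n, 0, 0.2)
  # sprinkle exact plateaus to exercise the tie rule
  if (n > 10 && runif(1) < 0.5) {
    at <- sample(2:(n - 2), 1)
    x[at + 1] <- x[at]
  }
  x
}

# small separable feature table without the simulator (for model tests)
toy_features <- function(n_per_class = 15, gap = 3, seed = 1, noise = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  label <- rep(c("control", "bradykinesia"), each = n_per_class)
  shift <- ifelse(label == "bradykinesia", gap, 0)
  tbl <- tibble::tibble(subject_id = sprintf("s%02d", 1:n), label = label)
  for (col in feature_columns()) {
    tbl[[col]] <- rnorm(n, 0, noise) + shift
  }
  tbl
}
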