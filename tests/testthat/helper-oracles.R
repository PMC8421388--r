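# Independent oracles used to cross-check pipeline operations. These are
# deliberately naive (brute force / closed form) and share no code with the
# implementations they verify.

# 4-connected component labelling by breadth-first search.
oracle_label4 <- function(bw) {
  h <- nrow(bw); w <- ncol(bw)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {   # column-major like bwlabel
    if (!bw[i, j] || lab[i, j]) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
            bw[q[1], q[2]] && !lab[q[1], q[2]]) {
          lab[q[1], q[2]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Exhaustive one-to-one matching between two small point sets: maximises the
# number of links within `maxd`, breaking ties by smallest total distance.
# Returns an integer vector: for each current point, the matched previous
# index or NA.
oracle_match <- function(prev, cur, maxd) {
  np <- nrow(prev); nc <- nrow(cur)
  stopifnot(np <= 6, nc <= 6)
  d <- sqrt(outer(prev[, 1], cur[, 1], "-")^2 +
            outer(prev[, 2], cur[, 2], "-")^2)
  best <- list(links = -1L, total = Inf, assign = rep(NA_integer_, nc))
  recurse <- function(ci, used_prev, assign, total, links) {
    if (ci > nc) {
      if (links > best$links ||
          (links == best$links && total < best$total - 1e-12)) {
        best <<- list(links = links, total = total, assign = assign)
      }
      return(invisible())
    }
    recurse(ci + 1L, used_prev, assign, total, links)  # leave unmatched
    for (pi in seq_len(np)) {
      if (!used_prev[pi] && d[pi, ci] <= maxd) {
        used_prev[pi] <- TRUE; assign[ci] <- pi
        recurse(ci + 1L, used_prev, assign, total + d[pi, ci], links + 1L)
        used_prev[pi] <- FALSE; assign[ci] <- NA_integer_
      }
    }
  }
  recurse(1L, rep(FALSE, np), rep(NA_integer_, nc), 0, 0L)
  best$assign
}

# Hand product-limit estimator: returns survival at each distinct event time.
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- as.logical(event)[ord]
  ev_times <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(ev_times))
  for (k in seq_along(ev_times)) {
    t <- ev_times[k]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / n_risk)
    out[k] <- s
  }
  data.frame(time = ev_times, survival = out)
}

# Maximiser of the Efron partial likelihood for a single binary covariate,
# by golden-section search on the scalar log-likelihood.
oracle_cox_efron <- function(time, event, x) {
  event <- as.logical(event); x <- as.numeric(x)
  ev_times <- sort(unique(time[event]))
  loglik <- function(beta) {
    ll <- 0
    for (t in ev_times) {
      D <- which(time == t & event)
      R <- which(time >= t)
      d <- length(D)
      sumR <- sum(exp(x[R] * beta))
      sumD <- sum(exp(x[D] * beta))
      ll <- ll + sum(x[D] * beta)
      for (l in seq_len(d) - 1)
        ll <- ll - log(sumR - (l / d) * sumD)
    }
    ll
  }
  stats::optimize(loglik, c(-8, 8), maximum = TRUE, tol = 1e-10)$maximum
}

# Circularly roll a matrix content by (dx, dy): x rightwards (columns), y
# downwards (rows).
roll_matrix <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

# Binary disk image helper: disks given as rows (x, y, radius), 0-based
# centres, painted at `value` on a `h` x `w` zero background.
disk_image <- function(h, w, disks, value = 1000) {
  img <- matrix(0, h, w)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  for (k in seq_len(nrow(disks)))
    img[(xs - disks[k, 1])^2 + (ys - disks[k, 2])^2 <= disks[k, 3]^2] <- value
  img
}

# A tiny shared fixture of survival records with heavy ties.
tied_cohort <- function(seed = 7) {
  set.seed(seed)
  n <- 60
  g <- rep(0:1, each = n / 2)
  t_raw <- rexp(n, rate = 0.02 * 1.8^g)
  t_obs <- pmin(ceiling(t_raw / 24) * 24, 168)   # 24 h imaging grid
  data.frame(id = seq_len(n), group = factor(ifelse(g == 1, "b", "a")),
             time_h = t_obs, event = t_raw <= 168, x = g)
}
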