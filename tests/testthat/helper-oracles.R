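# Independent oracles used to validate the package implementations.
# These are deliberately naive (enumeration / O(n^2) scans / hand formulas)
# and share no code with the functions they check.

# --- Wilcoxon rank-sum: full enumeration of rank assignments -------------
# Two-sided p by enumerating all C(n1+n2, n1) assignments of the pooled
# ranks to group 1 and counting assignments whose rank sum is at least as
# extreme (two-sided, doubling the smaller tail) as observed.
enum_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(n1)])
  sets <- utils::combn(n, n1)
  ws <- colSums(matrix(sort(rk)[sets], nrow = n1))
  lo <- mean(ws <= w_obs)
  hi <- mean(ws >= w_obs)
  min(1, 2 * min(lo, hi))
}

# --- Conditional multinomial expectation of the chemotaxis index ---------
# E[(B - A)/(A + B) | A + B > 0] by direct enumeration of all outcomes of
# a multinomial with n trials and probabilities p = (control, odorant,
# central).
enum_ci_expectation <- function(p, n = 10) {
  tot <- 0; norm <- 0
  for (a in 0:n) {
    for (b in 0:(n - a)) {
      pr <- stats::dmultinom(c(a, b, n - a - b), prob = p)
      if (a + b > 0) {
        tot <- tot + pr * (b - a) / (a + b)
        norm <- norm + pr
      }
    }
  }
  tot / norm
}

# --- Benjamini-Hochberg step-up, by the definition -----------------------
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# --- Kruskal-Wallis H by the explicit rank-sum formula (no ties) ---------
kw_h_formula <- function(groups) {
  values <- unlist(groups)
  n <- lengths(groups)
  N <- length(values)
  rk <- rank(values)
  rs <- split(rk, rep(seq_along(groups), n))
  12 / (N * (N + 1)) * sum(vapply(seq_along(groups), function(i) {
    sum(rs[[i]])^2 / n[i]
  }, numeric(1))) - 3 * (N + 1)
}

# --- Pirouette detection: exhaustive O(n^2) sub-interval scan ------------
# Plain nested loops over every (start, end) step pair, recomputing every
# quantity (headings, wrapped increments, window sums, baselines) by direct
# summation, followed by its own candidate merging. Mirrors the detection
# definition, not the implementation.
brute_force_pirouettes <- function(track, window = 3, angle_threshold = 120,
                                   drop_threshold = 0.40, baseline = 2,
                                   min_step = 0.01, min_duration = 0.8,
                                   merge_gap = 1, min_baseline_frac = 0.5) {
  fr <- track$frames
  nf <- nrow(fr)
  m <- nf - 1
  t0 <- fr$time[-nf]; t1 <- fr$time[-1]
  dx <- diff(fr$cx); dy <- diff(fr$cy)
  dur <- diff(fr$time)
  svalid <- fr$valid[-nf] & fr$valid[-1]
  disp <- sqrt(dx^2 + dy^2)
  spd <- disp / dur
  hdef <- svalid & !is.na(disp) & disp >= min_step
  hdg <- ifelse(hdef, atan2(dy, dx) * 180 / pi, NA_real_)
  wrap <- function(a) {
    w <- a %% 360
    if (!is.na(w) && w > 180) w <- w - 360
    w
  }
  n_expected <- max(1, round(baseline / track$nominal_dt))

  cands <- list()
  for (i in seq_len(m)) {
    if (!hdef[i]) next
    # baseline over [t0[i] - baseline, t0[i])
    bidx <- which(t0 >= t0[i] - baseline - 1e-9 & t0 < t0[i] - 1e-12)
    bval <- bidx[svalid[bidx]]
    base_ok <- length(bval) >= min_baseline_frac * n_expected &&
      length(bval) >= 1
    if (!base_ok) next
    base_speed <- sum(spd[bval] * dur[bval]) / sum(dur[bval])
    for (j in i:m) {
      if (!hdef[j]) break                      # contiguity broken
      w <- t1[j] - t0[i]
      if (w > window + 1e-9) break
      if (w < min_duration - 1e-9) next
      net <- 0
      if (j > i) {
        for (s in (i + 1):j) net <- net + wrap(hdg[s] - hdg[s - 1])
      }
      if (abs(net) <= angle_threshold) next
      evspd <- sum(spd[i:j] * dur[i:j]) / w
      if (evspd > (1 - drop_threshold) * base_speed + 1e-12) next
      cands[[length(cands) + 1]] <-
        data.frame(t_start = t0[i], t_end = t1[j], net = net,
                   event_speed = evspd, baseline_speed = base_speed)
    }
  }
  if (length(cands) == 0) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      net_turn = numeric(0)))
  }
  cd <- do.call(rbind, cands)
  cd <- cd[order(cd$t_start, cd$t_end), , drop = FALSE]
  events <- list()
  cl <- list(idx = 1, end = cd$t_end[1])
  flush <- function(cl) {
    dr <- 1 - cd$event_speed[cl$idx] / cd$baseline_speed[cl$idx]
    best <- cl$idx[order(-round(abs(cd$net[cl$idx]), 9), -dr,
                         cd$t_start[cl$idx])[1]]
    data.frame(t_start = cd$t_start[best], t_end = cd$t_end[best],
               net_turn = cd$net[best],
               baseline_speed = cd$baseline_speed[best],
               event_speed = cd$event_speed[best],
               speed_drop = 1 - cd$event_speed[best] / cd$baseline_speed[best],
               n_candidates = length(cl$idx))
  }
  if (nrow(cd) > 1) {
    for (q in 2:nrow(cd)) {
      if (cd$t_start[q] - cl$end >= merge_gap) {
        events[[length(events) + 1]] <- flush(cl)
        cl <- list(idx = q, end = cd$t_end[q])
      } else {
        cl$idx <- c(cl$idx, q)
        cl$end <- max(cl$end, cd$t_end[q])
      }
    }
  }
  events[[length(events) + 1]] <- flush(cl)
  out <- do.call(rbind, events)
  out[order(out$t_start), , drop = FALSE]
}
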