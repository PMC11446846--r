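# Independent reference implementations used to cross-check the package.
# These are deliberately written in the most literal style possible (scalar
# loops, sort-based formulas) and share no code with the implementation.

# --- scalar forward-Euler LIF integrator ------------------------------------
# Integrates one trial neuron-by-neuron with plain R loops, replicating the
# documented update order: leak (refractory clamp), delayed recurrent
# delivery, external delivery, threshold/reset/queue. Delta synapse kernel.
# edges: data.frame(pre, post, w) with 1-based indices; events: list(step,
# target (0-based), w) sorted by step.
oracle_lif <- function(n, edges, events, n_steps, params) {
  dt <- params$dt
  dt_over_tau <- dt / params$tau_mem
  refract_steps <- as.integer(round(params$t_refract / dt))
  delay_steps <- as.integer(round(params$syn_delay / dt))
  n_slots <- delay_steps + 1L
  v <- rep(params$v_rest, n)
  refr <- rep(0L, n)
  buf <- matrix(0, n_slots, n)
  out_by_pre <- lapply(seq_len(n), function(i)
    edges[edges$pre == i, , drop = FALSE])
  sp_n <- integer(0); sp_s <- integer(0)
  ev_ptr <- 1L
  n_ev <- length(events$step)
  for (s in seq_len(n_steps)) {
    for (i in seq_len(n)) {
      if (refr[i] > 0L) {
        refr[i] <- refr[i] - 1L
        v[i] <- params$v_reset
      } else {
        v[i] <- v[i] + dt_over_tau * (params$v_rest - v[i])
      }
    }
    slot <- (s %% n_slots) + 1L
    for (i in seq_len(n)) {
      if (buf[slot, i] != 0) {
        if (refr[i] == 0L) v[i] <- v[i] + buf[slot, i]
        buf[slot, i] <- 0
      }
    }
    while (ev_ptr <= n_ev && events$step[ev_ptr] == s) {
      tgt <- events$target[ev_ptr] + 1L
      if (refr[tgt] == 0L) v[tgt] <- v[tgt] + events$w[ev_ptr]
      ev_ptr <- ev_ptr + 1L
    }
    for (i in seq_len(n)) {
      if (refr[i] == 0L && v[i] >= params$v_thresh) {
        sp_n <- c(sp_n, i); sp_s <- c(sp_s, s)
        v[i] <- params$v_reset
        refr[i] <- refract_steps
        due <- s + delay_steps
        if (due <= n_steps) {
          oe <- out_by_pre[[i]]
          if (nrow(oe)) {
            dslot <- (due %% n_slots) + 1L
            for (k in seq_len(nrow(oe)))
              buf[dslot, oe$post[k]] <- buf[dslot, oe$post[k]] + oe$w[k]
          }
        }
      }
    }
  }
  data.frame(neuron = sp_n, t = sp_s * (dt / 1000))
}

# --- algebraic least-squares sphere -----------------------------------------
# |p|^2 = 2 p.c + d, d = r^2 - |c|^2: one linear solve, no iteration.
oracle_sphere <- function(points) {
  A <- cbind(2 * points[, 1], 2 * points[, 2], 2 * points[, 3], 1)
  b <- points[, 1]^2 + points[, 2]^2 + points[, 3]^2
  beta <- solve(t(A) %*% A, t(A) %*% b)
  centre <- beta[1:3]
  list(center = as.numeric(centre),
       radius = sqrt(beta[4] + sum(centre^2)))
}

# --- sort-based percentile (linear interpolation between closest ranks) -----
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo >= length(x)) return(x[length(x)])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# --- brute-force run scanner -------------------------------------------------
# Maximal runs of flag == TRUE, via a frame-by-frame walk.
oracle_runs <- function(flag) {
  out <- NULL
  i <- 1L
  n <- length(flag)
  while (i <= n) {
    if (flag[i]) {
      j <- i
      while (j < n && flag[j + 1L]) j <- j + 1L
      out <- rbind(out, data.frame(start = i, end = j))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0)) else out
}

# --- brute-force SIZ scanner -------------------------------------------------
# Entries/dwells/swing-containment by rle over the in-zone indicator within
# the window (a run touching the window start counts as an entry).
oracle_siz <- function(in_zone, swing_onsets, f0, f1, frame_rate) {
  iz <- in_zone[f0:f1]
  r <- rle(iz)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values
  entry <- starts[keep] + f0 - 1L
  exit <- ends[keep] + f0  # first frame out
  n_ev <- length(entry)
  ws <- 0L
  for (k in seq_len(n_ev))
    if (any(swing_onsets >= entry[k] & swing_onsets < exit[k])) ws <- ws + 1L
  list(count = n_ev, dwell = (exit - entry) / frame_rate, n_with_swing = ws)
}

# --- fixture builders ---------------------------------------------------------
# Tarsal tips realizing a given stance indicator on a known sphere: on the
# surface during stance, lifted during swing.
tips_from_phases <- function(stance, center = c(1, -2, 3), radius = 3,
                             clearance = 0.5) {
  u <- c(1, 1, -1) / sqrt(3)
  radial <- radius + ifelse(stance, 0, clearance)
  outer(radial, u) + matrix(center, length(stance), 3, byrow = TRUE)
}

true_ball <- function(center = c(1, -2, 3), radius = 3) {
  structure(list(center = center, radius = radius, rms_residual = 0,
                 iterations = 0L), class = "ball_fit")
}

gait_from_phases <- function(stance, frame_rate = 200, min_phase_ms = 0) {
  classify_gait(tips_from_phases(stance), true_ball(),
                frame_rate = frame_rate, min_phase_ms = min_phase_ms)
}
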