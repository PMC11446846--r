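# Connectome-constrained leaky integrate-and-fire simulation:
# parameters, Poisson stimulation protocols, the trial loop, trial-averaged
# rates, top responders and stimulation-rate sweeps.

#' Leaky integrate-and-fire parameters
#'
#' Membrane and synapse constants for the network model. The intrinsic rate
#' of every neuron is zero: with no external input the network is silent, and
#' Poisson stimulation is the only drive. Defaults follow the published
#' whole-brain fly LIF model of Shiu et al. (2024, eLife), whose constants
#' the connectome simulations in this field reuse; every value can be
#' overridden.
#'
#' @param v_rest resting potential, mV.
#' @param v_thresh spike threshold, mV (must exceed `v_rest`).
#' @param v_reset post-spike reset, mV (at most `v_rest`).
#' @param tau_mem membrane time constant, ms.
#' @param t_refract absolute refractory period, ms.
#' @param tau_syn synaptic trace time constant, ms (used by the exponential
#'   kernel only).
#' @param syn_delay conduction delay, ms (rounded to the nearest integration
#'   step).
#' @param w_unit membrane-potential increment per synapse per presynaptic
#'   spike, mV; connection strength is `sign * synapse count * w_unit`.
#' @param dt integration step, ms.
#' @param kernel `"delta"` (each spike deposits its full weight at arrival)
#'   or `"exp"` (weights are low-pass filtered with `tau_syn`; total
#'   delivered charge is identical).
#' @return a `lif_params` list.
#' @references Shiu, P.K. et al. (2024) A leaky integrate-and-fire
#'   computational model based on the connectome of the entire adult
#'   Drosophila brain reveals insights into sensorimotor processing.
#' @export
lif_params <- function(v_rest = -52, v_thresh = -45, v_reset = -52,
                       tau_mem = 20, t_refract = 2.2, tau_syn = 5,
                       syn_delay = 1.8, w_unit = 0.275, dt = 0.05,
                       kernel = c("delta", "exp")) {
  kernel <- match.arg(kernel)
  if (!(v_reset <= v_rest && v_rest < v_thresh))
    stopf("require v_reset <= v_rest < v_thresh (got %g, %g, %g)",
          v_reset, v_rest, v_thresh)
  for (nm in c("tau_mem", "t_refract", "tau_syn", "dt"))
    if (get(nm) <= 0) stopf("%s must be > 0", nm)
  if (syn_delay < 0) stopf("syn_delay must be >= 0")
  if (w_unit <= 0) stopf("w_unit must be > 0")
  structure(list(v_rest = v_rest, v_thresh = v_thresh, v_reset = v_reset,
                 tau_mem = tau_mem, t_refract = t_refract, tau_syn = tau_syn,
                 syn_delay = syn_delay, w_unit = w_unit, dt = dt,
                 kernel = kernel),
            class = "lif_params")
}

#' Poisson stimulation epoch
#'
#' One stimulation block: the listed neurons each receive an independent
#' homogeneous Poisson input train at `rate` Hz during `[t_start, t_end)`.
#' Each input spike depolarizes its target by `strength * w_unit` mV —
#' `strength` plays the role of the synapse count of the optogenetic drive.
#'
#' @param targets neuron ids to stimulate.
#' @param rate Poisson rate, Hz (>= 0).
#' @param t_start,t_end epoch window, s.
#' @param strength input strength in synapse equivalents (default 25).
#' @return a `stim_epoch` list.
#' @export
stim_epoch <- function(targets, rate, t_start = 0, t_end = 1, strength = 25) {
  if (rate < 0) stopf("stimulation rate must be >= 0")
  if (!(t_start >= 0 && t_start < t_end))
    stopf("require 0 <= t_start < t_end")
  structure(list(targets = as.integer(targets), rate = rate,
                 t_start = t_start, t_end = t_end, strength = strength),
            class = "stim_epoch")
}

#' Stimulation/silencing protocol
#'
#' Bundles epochs, the silenced set and the trial structure. The standard
#' protocol is 30 trials of 1,000 ms integrated at 0.05 ms steps, with rates
#' averaged across trials.
#'
#' @param epochs list of [stim_epoch()] objects (may be empty).
#' @param silenced neuron ids whose outgoing connections are severed before
#'   integration (they still integrate and may spike).
#' @param duration trial length, s.
#' @param n_trials number of independent trials (>= 1).
#' @param seed integer seed; every trial draws from its own substream derived
#'   from this seed and the (trial, target, epoch) indices, so adding targets
#'   or epochs never perturbs existing streams.
#' @return a `stim_protocol` list.
#' @export
stim_protocol <- function(epochs = list(), silenced = integer(0),
                          duration = 1, n_trials = 30, seed = 1L) {
  if (inherits(epochs, "stim_epoch")) epochs <- list(epochs)
  stopifnot(all(vapply(epochs, inherits, logical(1), "stim_epoch")))
  if (n_trials < 1) stopf("n_trials must be >= 1")
  for (ep in epochs)
    if (ep$t_end > duration + 1e-12)
      stopf("epoch end %g s exceeds trial duration %g s", ep$t_end, duration)
  structure(list(epochs = epochs, silenced = as.integer(silenced),
                 duration = duration, n_trials = as.integer(n_trials),
                 seed = as.integer(seed)),
            class = "stim_protocol")
}

#' Homogeneous Poisson spike train on the integration grid
#'
#' Draws a Poisson process of the given rate restricted to
#' `[t_start, t_end)`, discretized to the `dt` grid: each step fires
#' independently with probability `rate * dt`. Spike times are the left edge
#' of their step.
#'
#' @param rate Hz (>= 0).
#' @param t_start,t_end window, s.
#' @param dt integration step, ms.
#' @param seed integer seed for this train's substream.
#' @return numeric vector of spike times, s (possibly empty).
#' @export
poisson_train <- function(rate, t_start, t_end, dt = 0.05, seed = 1L) {
  if (rate < 0) stopf("rate must be >= 0")
  if (t_start > t_end) stopf("t_start must be <= t_end")
  dt_s <- dt / 1000
  if (rate == 0 || t_end - t_start < dt_s / 2) return(numeric(0))
  b0 <- as.integer(round(t_start / dt_s))
  b1 <- as.integer(round(t_end / dt_s))
  n_bins <- b1 - b0
  if (n_bins <= 0L) return(numeric(0))
  p <- rate * dt_s
  if (p > 1) stopf("rate %g Hz exceeds one spike per %g ms step", rate, dt)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hit <- stats::runif(n_bins) < p
  (b0 + which(hit) - 1L) * dt_s
}

# Save/restore the global RNG state so seeded substreams do not clobber the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# External input events for one trial: data.frame(step, target_idx0, w_mV),
# sorted by step. Substream per (trial, target, epoch).
external_events <- function(protocol, params, ids, trial) {
  dt_s <- params$dt / 1000
  steps <- integer(0); tgt <- integer(0); w <- numeric(0)
  for (k in seq_along(protocol$epochs)) {
    ep <- protocol$epochs[[k]]
    for (id in ep$targets) {
      idx <- match(id, ids)
      s <- substream_seed(protocol$seed, trial, idx, k)
      times <- poisson_train(ep$rate, ep$t_start, ep$t_end, params$dt, seed = s)
      if (length(times)) {
        steps <- c(steps, as.integer(round(times / dt_s)) + 1L)
        tgt <- c(tgt, rep(idx - 1L, length(times)))
        w <- c(w, rep(ep$strength * params$w_unit, length(times)))
      }
    }
  }
  o <- order(steps)
  list(step = steps[o], target = tgt[o], w = w[o])
}

#' Simulate the network under a stimulation protocol
#'
#' Forward-Euler integration of the signed, synapse-count-weighted LIF
#' network. Silenced neurons have their outgoing weights severed before
#' integration (they still integrate and may spike). With an empty epoch
#' list no neuron ever spikes, because the model has no intrinsic activity.
#'
#' @param conn a `signed_connectome`.
#' @param params a [lif_params()] object.
#' @param protocol a [stim_protocol()] object.
#' @return a `spike_raster`: list with `spikes` (data.frame `trial`, `id`,
#'   `t` in s), `ids`, `n_trials`, `duration`, `params`.
#' @export
simulate_network <- function(conn, params = lif_params(),
                             protocol = stim_protocol()) {
  stopifnot(inherits(conn, "signed_connectome"),
            inherits(params, "lif_params"),
            inherits(protocol, "stim_protocol"))
  ids <- conn$neurons$id
  proto_ids <- unique(c(unlist(lapply(protocol$epochs, `[[`, "targets")),
                        protocol$silenced))
  unknown <- setdiff(proto_ids, ids)
  if (length(unknown))
    stopf("protocol references unknown neuron id(s): %s",
          paste(unknown, collapse = ", "))
  n_steps <- protocol$duration * 1000 / params$dt
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stopf("dt = %g ms does not divide the trial duration %g s",
          params$dt, protocol$duration)
  n_steps <- as.integer(round(n_steps))

  sil <- silence_neurons(conn, protocol$silenced)
  e <- sil$edges
  epre <- match(e$pre, ids) - 1L
  epost <- match(e$post, ids) - 1L
  ew <- as.double(e$sign) * e$count * params$w_unit
  refract_steps <- as.integer(round(params$t_refract / params$dt))
  delay_steps <- as.integer(round(params$syn_delay / params$dt))
  kern <- if (params$kernel == "exp") 1L else 0L
  dt_s <- params$dt / 1000

  out <- vector("list", protocol$n_trials)
  for (trial in seq_len(protocol$n_trials)) {
    ev <- external_events(protocol, params, ids, trial)
    res <- lif_run_trial(length(ids), epre, epost, ew,
                         ev$step, ev$target, ev$w,
                         n_steps, params$dt,
                         params$v_rest, params$v_thresh, params$v_reset,
                         params$tau_mem, refract_steps, delay_steps,
                         params$tau_syn, kern)
    out[[trial]] <- data.frame(trial = rep(trial, length(res$neuron)),
                               id = ids[res$neuron + 1L],
                               t = res$step * dt_s)
  }
  structure(list(spikes = do.call(rbind, out), ids = ids,
                 n_trials = protocol$n_trials, duration = protocol$duration,
                 params = params),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d neurons, %d trials x %g s, %d spikes\n",
              length(x$ids), x$n_trials, x$duration, nrow(x$spikes)))
  invisible(x)
}

#' Trial-averaged firing rates
#'
#' Scalar mode (default): for each neuron, spikes inside the window divided
#' by `n_trials * window length` — the trial-averaged rate in Hz.
#' Time-resolved mode (`bin` given): per-neuron binned trial-averaged rate,
#' optionally smoothed with a Gaussian kernel (`smooth_sigma` ms, the
#' heat-map convention uses 25 ms); smoothing preserves the time-integral of
#' interior activity.
#'
#' @param raster a `spike_raster`.
#' @param window `c(start, end)` in s, within the trial; default full trial.
#' @param bin bin width in ms for time-resolved mode, or `NULL` for scalar.
#' @param smooth_sigma Gaussian sigma in ms, or `NULL` for no smoothing.
#' @return scalar mode: named numeric vector (Hz) over all neurons.
#'   Time-resolved: list with `rate` (matrix neurons x bins, Hz), `t` (bin
#'   centers, s), `ids`.
#' @export
firing_rates <- function(raster, window = NULL, bin = NULL,
                         smooth_sigma = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (is.null(window)) window <- c(0, raster$duration)
  if (window[2] <= window[1]) stopf("empty rate window")
  if (window[1] < 0 || window[2] > raster$duration + 1e-12)
    stopf("window outside the trial")
  sp <- raster$spikes
  if (is.null(bin)) {
    inw <- sp$t > window[1] & sp$t <= window[2]
    counts <- table(factor(sp$id[inw], levels = raster$ids))
    r <- as.numeric(counts) / (raster$n_trials * (window[2] - window[1]))
    names(r) <- raster$ids
    return(r)
  }
  bin_s <- bin / 1000
  edges <- seq(window[1], window[2], by = bin_s)
  if (edges[length(edges)] < window[2] - 1e-12)
    edges <- c(edges, window[2])
  nb <- length(edges) - 1L
  mat <- matrix(0, nrow = length(raster$ids), ncol = nb,
                dimnames = list(raster$ids, NULL))
  inw <- sp$t > window[1] & sp$t <= window[2]
  if (any(inw)) {
    bi <- pmin(findInterval(sp$t[inw], edges, left.open = TRUE), nb)
    ri <- match(sp$id[inw], raster$ids)
    for (k in seq_along(bi)) mat[ri[k], bi[k]] <- mat[ri[k], bi[k]] + 1
  }
  widths <- diff(edges)
  mat <- sweep(mat, 2, raster$n_trials * widths, "/")
  if (!is.null(smooth_sigma) && smooth_sigma > 0) {
    mat <- t(apply(mat, 1, gaussian_smooth, sigma = smooth_sigma, bin = bin))
  }
  list(rate = mat, t = (edges[-1] + edges[-length(edges)]) / 2,
       ids = raster$ids, smooth_sigma = smooth_sigma)
}

# Discrete Gaussian smoothing of a binned rate; kernel truncated at 4 sigma
# and normalized to sum 1, zero-padded convolution.
gaussian_smooth <- function(x, sigma, bin) {
  half <- max(1L, as.integer(ceiling(4 * sigma / bin)))
  k <- stats::dnorm(seq(-half, half) * bin, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(numeric(half), x, numeric(half))
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(xp[i:(i + 2 * half)] * rev(k))
  out
}

#' Top responding neurons
#'
#' Ranks neurons by a scalar trial-averaged rate (descending) and returns the
#' first `k` ids; ties are broken by ascending id. Used to select e.g. the
#' top 100 responders for heat-map display.
#'
#' @param rates named numeric vector from [firing_rates()] scalar mode.
#' @param k number of ids to return (>= 1).
#' @return integer vector of ids, length `min(k, length(rates))`.
#' @export
top_responders <- function(rates, k = 100L) {
  if (k < 1) stopf("k must be >= 1")
  ids <- as.integer(names(rates))
  o <- order(-rates, ids)
  utils::head(ids[o], k)
}

#' Two-axis stimulation-rate sweep with optional silenced counterpart
#'
#' Co-stimulates two target groups across a grid of Poisson rates and reads
#' out the trial-averaged rate of the readout neurons in each cell — the
#' in-silico analogue of co-activating a walking command with a sensory
#' drive over a range of optogenetic intensities. When `silenced` is
#' non-empty the whole grid is repeated with those neurons' outputs severed
#' and the difference map (silenced - intact) is returned, the readout that
#' reveals release-of-inhibition effects.
#'
#' Matched substreams are used across cells and across the intact/silenced
#' pair, so difference maps are free of trial-resampling noise.
#'
#' @param conn a `signed_connectome`.
#' @param params a [lif_params()].
#' @param axis1,axis2 lists `list(targets =, rates =, strength =)`; `rates`
#'   is the vector of Poisson rates (Hz) swept along that axis (`strength`
#'   defaults to 25).
#' @param readout ids whose mean rate fills the grid; must not intersect
#'   `silenced`.
#' @param silenced ids silenced in the paired grid (empty for intact-only).
#' @param window readout window `c(start, end)` s; defaults to the full
#'   stimulation window.
#' @param duration,n_trials,seed trial structure (defaults 1 s, 30, 1).
#' @return a `sweep_result`: list with `intact` (matrix
#'   `length(axis1$rates)` x `length(axis2$rates)`), and when silencing is
#'   requested `silenced_grid` and `difference` (silenced - intact); plus the
#'   axes.
#' @export
rate_sweep <- function(conn, params, axis1, axis2, readout,
                       silenced = integer(0), window = NULL,
                       duration = 1, n_trials = 30L, seed = 1L) {
  stopifnot(is.list(axis1), is.list(axis2))
  if (!length(axis1$rates) || !length(axis2$rates))
    stopf("both axes need a non-empty rate list")
  if (any(axis1$rates < 0) || any(axis2$rates < 0))
    stopf("stimulation rates must be >= 0")
  readout <- as.integer(readout)
  silenced <- as.integer(silenced)
  if (length(intersect(readout, silenced)))
    stopf("readout neuron(s) %s are silenced: readout undefined",
          paste(intersect(readout, silenced), collapse = ", "))
  if (is.null(window)) window <- c(0, duration)
  s1 <- axis1$strength %||% 25
  s2 <- axis2$strength %||% 25

  run_grid <- function(sil) {
    g <- matrix(NA_real_, length(axis1$rates), length(axis2$rates),
                dimnames = list(axis1$rates, axis2$rates))
    for (i in seq_along(axis1$rates)) {
      for (j in seq_along(axis2$rates)) {
        eps <- list()
        if (axis1$rates[i] > 0)
          eps <- c(eps, list(stim_epoch(axis1$targets, axis1$rates[i],
                                        window[1], window[2], strength = s1)))
        ep2 <- stim_epoch(axis2$targets, max(axis2$rates[j], 0),
                          window[1], window[2], strength = s2)
        # keep epoch index stable so axis-2 streams match across cells
        eps <- if (length(eps)) list(eps[[1]], ep2) else
          list(stim_epoch(axis1$targets, 0, window[1], window[2],
                          strength = s1), ep2)
        pr <- stim_protocol(eps, silenced = sil, duration = duration,
                            n_trials = n_trials, seed = seed)
        ras <- simulate_network(conn, params, pr)
        r <- firing_rates(ras, window = window)
        g[i, j] <- mean(r[as.character(readout)])
      }
    }
    g
  }

  intact <- run_grid(integer(0))
  out <- list(intact = intact, axis1 = axis1, axis2 = axis2,
              readout = readout, window = window)
  if (length(silenced)) {
    out$silenced_ids <- silenced
    out$silenced_grid <- run_grid(silenced)
    out$difference <- out$silenced_grid - intact
  }
  structure(out, class = "sweep_result")
}
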