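#' Simulate the continuous nIC-1EC network
#'
#' Integrates the full integrate-and-fire network: `nIC` inhibitory cells
#' with leak, calcium-gated potassium (I_AHP) and synaptic currents, all
#' mutually inhibiting one another (no self-inhibition) and all excited by
#' one excitatory cell that fires periodically under constant drive. The EC
#' obeys the same threshold/reset rule as the ICs. At each spike the firing
#' cell's potential resets to `vR`, its synaptic gate reopens to 1 and — for
#' ICs — its calcium jumps by `dCa` (applied at the spike instant, before
#' the next decay interval).
#'
#' Calcium and the synaptic gates obey linear ODEs between spikes and are
#' advanced by their exact exponential decay factors each step; membrane
#' potentials use exponential Euler with conductances frozen at the step
#' start. Threshold crossings are detected at step end and the spike time is
#' the step end. If two ICs cross in the same step the one with lower
#' calcium (the more excitable one) fires and the other is held off by the
#' winner's reset inhibition.
#'
#' @param p a [model_params()] object.
#' @param nIC number of inhibitory cells (0 allowed: EC alone).
#' @param tmax simulated time, ms.
#' @param dt integration step, ms (default 0.01; must resolve the
#'   inter-spike interval, `dt <= t3/50`).
#' @param ca0 initial IC calcium vector (recycled to length `nIC`;
#'   default 0).
#' @param v0 initial IC potentials (default all `vR`).
#' @param vEC0 initial EC potential (default `vR`).
#' @param record_dt trace sampling interval in ms, or `NULL` for no trace.
#' @param max_interchanges stop early once the identity of the firing IC
#'   has changed this many times (0 = run to `tmax`). Useful to time-box
#'   first-burst measurements.
#' @param ec include the excitatory cell (default `TRUE`). With
#'   `ec = FALSE` the ICs receive only their applied current `Iapp` — the
#'   isolated step-current protocol used to demonstrate spike-frequency
#'   adaptation.
#'
#' @return A list of class `"network_sim"`:
#' \describe{
#'   \item{spikes}{data frame `(time, neuron)`; neuron 0 is the EC,
#'     1..nIC the inhibitory cells.}
#'   \item{spike_ca}{matrix with one row per IC spike: every IC's calcium
#'     just before that spike's calcium jump (burst-initial values are read
#'     from the first row of each burst).}
#'   \item{trace}{data frame of sampled state (`time`, `v1..`, `vEC`,
#'     `Ca1..`, `si1..`, `se`), or `NULL`.}
#' }
#' @examples
#' p <- model_params()
#' sim <- simulate_network(p, nIC = 2, tmax = 500, ca0 = c(0, 3))
#' head(sim$spikes)
#' @export
simulate_network <- function(p, nIC = 2, tmax = 1000, dt = 0.01,
                             ca0 = 0, v0 = NULL, vEC0 = p$vR,
                             record_dt = NULL, max_interchanges = 0,
                             ec = TRUE) {
  stopifnot(inherits(p, "model_params"), nIC >= 0, tmax > 0, dt > 0)
  if (dt > p$t3 / 50) {
    stop("step size dt = ", dt, " too coarse: must be at most t3/50 = ",
         p$t3 / 50, " ms to resolve the inter-spike interval", call. = FALSE)
  }
  ca0 <- rep_len(as.numeric(ca0), nIC)
  if (any(ca0 < 0)) stop("initial calcium must be non-negative")
  v0 <- if (is.null(v0)) rep(p$vR, nIC) else rep_len(as.numeric(v0), nIC)
  record_every <- if (is.null(record_dt)) 0L else max(1L, round(record_dt / dt))

  raw <- sim_network_cpp(unlist(p), as.integer(nIC), ca0, v0, vEC0,
                         tmax, dt, as.integer(record_every),
                         as.integer(max_interchanges), isTRUE(ec))

  trace <- NULL
  if (record_every > 0) {
    trace <- as.data.frame(raw$trace)
    names(trace) <- c("time", if (nIC > 0) paste0("v", seq_len(nIC)), "vEC",
                      if (nIC > 0) paste0("Ca", seq_len(nIC)),
                      if (nIC > 0) paste0("si", seq_len(nIC)), "se")
  }
  structure(list(spikes = data.frame(time = raw$spike_t,
                                     neuron = raw$spike_id),
                 spike_ca = raw$spike_ca,
                 trace = trace, nIC = nIC, dt = dt, p = p),
            class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  nic_sp <- sum(x$spikes$neuron > 0)
  cat(sprintf("<network_sim> %d ICs, %d IC spikes, %d EC spikes\n",
              x$nIC, nic_sp, sum(x$spikes$neuron == 0)))
  invisible(x)
}

#' Extract the burst table from a simulation
#'
#' Partitions the IC spike train into maximal runs of a single firing cell.
#' Each run is one burst; its length is the number of spikes per burst
#' (NSPB), and the calcium of every IC just before the run's first spike is
#' the burst-initial calcium vector — the quantity the discrete map evolves.
#'
#' @param sim a [simulate_network()] result.
#' @return A data frame with columns `burst`, `cell` (firing IC id),
#'   `nspb`, `t_start`, and `Ca1..CanIC` (burst-initial calcium).
#' @export
extract_bursts <- function(sim) {
  stopifnot(inherits(sim, "network_sim"))
  ic <- sim$spikes$neuron > 0
  if (!any(ic)) stop("no IC spikes in the train", call. = FALSE)
  ids <- sim$spikes$neuron[ic]
  tt <- sim$spikes$time[ic]
  runs <- rle(ids)
  first <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  ca <- sim$spike_ca[first, , drop = FALSE]
  colnames(ca) <- paste0("Ca", seq_len(ncol(ca)))
  cbind(data.frame(burst = seq_along(runs$values), cell = runs$values,
                   nspb = runs$lengths, t_start = tt[first]),
        as.data.frame(ca))
}
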