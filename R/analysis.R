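#' First-burst NSPB from either system
#'
#' Both helpers answer the same question for a given pair of initial
#' calcium levels `(x0, y0)` of IC1 and IC2: how many spikes does the first
#' burst contain? The more excitable (lower-calcium) cell bursts first, so
#' the map prediction is `nspb(min, max)`; the continuous measurement
#' initializes the network with calcium `(x0, y0)`, all potentials at `vR`
#' and gates closed, lets the EC pace, and counts the first maximal run of
#' one IC's spikes.
#'
#' @param x0,y0 initial calcium of IC1 and IC2.
#' @inheritParams nspb_real
#' @return Spike count (possibly `Inf` from the map when the cells never
#'   interchange; `NA` from the simulator if no interchange occurred within
#'   the time allowed).
#' @export
first_burst_nspb_map <- function(x0, y0, p, dc = derive_constants(p)) {
  nspb(min(x0, y0), max(x0, y0), p, dc)
}

#' @rdname first_burst_nspb_map
#' @param dt integration step, ms.
#' @param tmax simulation cap, ms (doubled once internally if the first
#'   interchange has not happened yet).
#' @export
first_burst_nspb_continuous <- function(x0, y0, p, dt = 0.01, tmax = 2000) {
  for (Tcap in c(tmax, 4 * tmax)) {
    sim <- simulate_network(p, nIC = 2, tmax = Tcap, dt = dt,
                            ca0 = c(x0, y0), max_interchanges = 1)
    ic <- sim$spikes$neuron > 0
    if (!any(ic)) next
    runs <- rle(sim$spikes$neuron[ic])
    if (length(runs$lengths) >= 2) return(runs$lengths[1])
  }
  NA_integer_
}

#' Long-run (stable) NSPB from either system
#'
#' `stable_nspb_map()` iterates the burst map and reports the terminal
#' burst count; `stable_nspb_continuous()` runs the full network and
#' requires the last `last` bursts to share one NSPB, returning `NA` when
#' the tail has not settled. Burn-in choices are deliberate
#' operationalizations of "stable": 200 map bursts and a 10 s run with a
#' 10-burst constancy requirement.
#'
#' @inheritParams nspb_real
#' @param init initial calcium state `c(Cx, Cy)` for the map (default
#'   `c(0, 3)`), or length-2 `ca0` for the simulator.
#' @param steps map bursts to iterate (default 200).
#' @return Integer NSPB, or `NA` (continuous tail not settled) or `Inf`
#'   (map: no interchange).
#' @export
stable_nspb_map <- function(p, dc = derive_constants(p), init = c(0, 3),
                            steps = 200) {
  state <- init
  n <- NA_real_
  for (i in seq_len(steps)) {
    st <- tryCatch(map_step(state, p, dc), error = function(e) NULL)
    if (is.null(st)) return(Inf)
    state <- st$state
    n <- st$n
  }
  n
}

#' @rdname stable_nspb_map
#' @param tmax simulated time for the continuous run, ms (default 10000).
#' @param dt integration step, ms.
#' @param last number of trailing bursts that must agree (default 10).
#' @export
stable_nspb_continuous <- function(p, init = c(0, 3), tmax = 10000,
                                   dt = 0.01, last = 10) {
  # bursts can be sparse (long inter-burst gaps) and transients long;
  # extend the run once before declaring the tail unsettled
  for (Tcap in tmax * c(1, 4)) {
    sim <- simulate_network(p, nIC = 2, tmax = Tcap, dt = dt, ca0 = init)
    ic <- sim$spikes$neuron > 0
    if (!any(ic)) next
    runs <- rle(sim$spikes$neuron[ic])
    len <- runs$lengths
    if (length(len) < last + 1) next
    tail_len <- len[seq(length(len) - last, length(len) - 1)]  # drop cut-off run
    if (all(tail_len == tail_len[1])) return(tail_len[1])
  }
  NA_integer_
}

#' NSPB over a grid of initial calcium levels
#'
#' Evaluates the first-burst NSPB on a grid of initial calcium pairs with
#' the analytic formula and, optionally, the continuous simulator, and
#' scores their agreement (fraction of grid cells within `tol` spikes).
#' Diagonal-adjacent cells (nearly equal initial calcium) give short
#' bursts; the count grows with the calcium gap.
#'
#' @param grid_x,grid_y numeric grids for the two cells' initial calcium
#'   (should lie in `[0, Abar)`).
#' @inheritParams nspb_real
#' @param with_continuous also run the simulator per cell (default
#'   `FALSE`).
#' @param dt integration step for the continuous side.
#' @param tol agreement tolerance in spikes (default 1).
#' @return A list of class `"sweep_result"` with `grid_x`, `grid_y`,
#'   `nspb_map` (matrix, rows indexed by `grid_x`), `nspb_continuous`
#'   (matrix or `NULL`), and `agreement` (fraction, or `NA`).
#' @export
sweep_initial_ca <- function(grid_x, grid_y = grid_x, p,
                             dc = derive_constants(p),
                             with_continuous = FALSE, dt = 0.01, tol = 1) {
  nm <- outer(grid_x, grid_y,
              Vectorize(function(a, b) first_burst_nspb_map(a, b, p, dc)))
  nc <- NULL
  agree <- NA_real_
  if (with_continuous) {
    nc <- matrix(NA_real_, length(grid_x), length(grid_y))
    for (i in seq_along(grid_x)) {
      for (j in seq_along(grid_y)) {
        nc[i, j] <- first_burst_nspb_continuous(grid_x[i], grid_y[j], p,
                                                dt = dt)
      }
    }
    ok <- is.finite(nm) & is.finite(nc)
    agree <- sum(ok & abs(nm - nc) <= tol) / length(nm)
  }
  structure(list(axis1 = "Ca1(0)", axis2 = "Ca2(0)",
                 grid_x = grid_x, grid_y = grid_y,
                 nspb_map = nm, nspb_continuous = nc, agreement = agree),
            class = "sweep_result")
}

#' Stable NSPB over a conductance grid
#'
#' Long-run burst counts as functions of the AHP conductance `gAHP` and the
#' inhibitory conductance `gi`, from the map and optionally from the
#' continuous system. NSPB falls with `gAHP` (less calcium needed to
#' hyperpolarize the active cell) and rises with `gi` (stronger inhibition
#' takes longer to overcome).
#'
#' @param gahp_values,gi_values positive parameter grids.
#' @param p baseline [model_params()]; `gAHP`/`gi` are overridden per cell.
#' @param with_continuous also run the simulator per cell.
#' @param init initial calcium state passed to the long-run helpers.
#' @param dt,tmax continuous-side integration settings.
#' @param tol agreement tolerance in spikes.
#' @return A `"sweep_result"` (rows indexed by `gahp_values`).
#' @export
sweep_gahp_gi <- function(gahp_values, gi_values, p, with_continuous = FALSE,
                          init = c(0, 3), dt = 0.01, tmax = 10000, tol = 1) {
  stopifnot(all(gahp_values > 0), all(gi_values > 0))
  nm <- matrix(NA_real_, length(gahp_values), length(gi_values))
  nc <- if (with_continuous) nm else NULL
  for (i in seq_along(gahp_values)) {
    for (j in seq_along(gi_values)) {
      q <- p
      q$gAHP <- gahp_values[i]
      q$gi <- gi_values[j]
      dcq <- derive_constants(q)
      nm[i, j] <- stable_nspb_map(q, dcq, init = init)
      if (with_continuous) {
        nc[i, j] <- stable_nspb_continuous(q, init = init, tmax = tmax,
                                           dt = dt)
      }
    }
  }
  agree <- NA_real_
  if (with_continuous) {
    ok <- is.finite(nm) & is.finite(nc)
    agree <- sum(ok & abs(nm - nc) <= tol) / length(nm)
  }
  structure(list(axis1 = "gAHP", axis2 = "gi",
                 grid_x = gahp_values, grid_y = gi_values,
                 nspb_map = nm, nspb_continuous = nc, agreement = agree),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s x %s, %d x %d grid\n", x$axis1, x$axis2,
              length(x$grid_x), length(x$grid_y)))
  if (!is.null(x$nspb_continuous)) {
    cat(sprintf("  map vs continuous agreement: %.3f\n", x$agreement))
  }
  invisible(x)
}

#' Bifurcation scan of the stable burst count
#'
#' Tracks the long-run NSPB branch of both systems along one parameter
#' (`gAHP` or `gi`). The branch is an integer-valued step function; each
#' step edge is a saddle-node event at which one stable burst count
#' disappears and the neighboring one takes over. Transition locations are
#' reported as the midpoint of the two grid values flanking each jump.
#'
#' @param param `"gAHP"` or `"gi"`.
#' @param values sorted positive parameter values.
#' @param p baseline [model_params()].
#' @param with_continuous also scan the continuous system (default `TRUE`).
#' @param init,dt,tmax long-run settings, as in [stable_nspb_continuous()].
#' @return A data frame of class `"bifurcation_branch"` with columns
#'   `value`, `nspb_map`, and (optionally) `nspb_continuous`; attributes
#'   `transitions_map` / `transitions_continuous` hold the jump locations.
#' @export
bifurcation_scan <- function(param = c("gAHP", "gi"), values, p,
                             with_continuous = TRUE, init = c(0, 3),
                             dt = 0.01, tmax = 10000) {
  param <- match.arg(param)
  stopifnot(all(values > 0), !is.unsorted(values))
  nm <- numeric(length(values))
  nc <- if (with_continuous) numeric(length(values)) else NULL
  for (i in seq_along(values)) {
    q <- p
    q[[param]] <- values[i]
    dcq <- derive_constants(q)
    nm[i] <- stable_nspb_map(q, dcq, init = init)
    if (with_continuous) {
      nc[i] <- stable_nspb_continuous(q, init = init, tmax = tmax, dt = dt)
    }
  }
  out <- data.frame(value = values, nspb_map = nm)
  if (with_continuous) out$nspb_continuous <- nc
  attr(out, "param") <- param
  attr(out, "transitions_map") <- branch_transitions(values, nm)
  if (with_continuous) {
    attr(out, "transitions_continuous") <- branch_transitions(values, nc)
  }
  class(out) <- c("bifurcation_branch", "data.frame")
  out
}

# midpoints of grid intervals across which the integer branch jumps;
# NA entries (unsettled continuous tails) are bridged over
branch_transitions <- function(values, branch) {
  ok <- which(is.finite(branch))
  if (length(ok) < 2) return(numeric(0))
  v <- values[ok]
  b <- branch[ok]
  jumps <- which(diff(b) != 0)
  (v[jumps] + v[jumps + 1]) / 2
}
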