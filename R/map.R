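#' Quasi-steady subthreshold membrane potential
#'
#' Between spikes the only active currents are the leak, the calcium-gated
#' potassium current and (for the inhibited cell) the slow synaptic
#' inhibition; calcium and the inhibitory gate barely move within one
#' inter-spike interval, so the membrane potential sits at the fixed point
#' of the voltage equation:
#' \deqn{v_{sub} = E_K + \frac{g_l(E_L-E_K) + g_i s_i (E_{GABA}-E_K) +
#'   I_{app}}{g_l + g_{AHP}\,x_{Ca} + g_i s_i}, \qquad
#'   x_{Ca} = \frac{Ca}{Ca + k_1}.}
#' The active cell is evaluated with `si_level = 0` (no self-inhibition);
#' the silent cell with the gate left at the end of the interval,
#' `dc$siEnd`. Comparing the two values is what decides the interchange.
#'
#' @param Ca calcium level(s), model uM (vectorized).
#' @param si_level inhibitory gate seen by the cell, in \[0, 1\].
#' @param p a [model_params()] object.
#' @return Potential in mV; strictly decreasing in `Ca`.
#' @examples
#' p <- model_params()
#' vsub(0, 0, p)    # uninhibited, calcium-free cell: EL + Iapp/gl
#' @export
vsub <- function(Ca, si_level, p) {
  xCa <- Ca / (Ca + p$k1)
  gsyn <- p$gi * si_level
  p$EK + (p$gl * (p$EL - p$EK) + gsyn * (p$EGABA - p$EK) + p$Iapp) /
    (p$gl + p$gAHP * xCa + gsyn)
}

#' Iterated calcium of the active and silent cells
#'
#' Per cycle, the active cell gains `dCa` at its spike and then decays by
#' the factor `r = exp(-kCa * t3)`; the silent cell only decays. Closing
#' the geometric sum gives, after `n` cycles,
#' \deqn{Ca_a(n) = r^n a_0 + \bar A (1 - r^n), \qquad Ca_s(n) = r^n s_0,}
#' with \eqn{\bar A = d_{Ca}\,r/(1-r)} the asymptotic end-of-interval
#' calcium level.
#'
#' @param a0,s0 burst-initial calcium of the active / silent cell.
#' @param n number of completed cycles (non-negative; vectorized).
#' @param dc a [derive_constants()] object.
#' @return Calcium level(s) in model uM.
#' @export
ca_active <- function(a0, n, dc) {
  stopifnot(all(n >= 0))
  rn <- dc$r^n
  rn * a0 + dc$Abar * (1 - rn)
}

#' @rdname ca_active
#' @export
ca_silent <- function(s0, n, dc) {
  stopifnot(all(n >= 0))
  s0 * dc$r^n
}

#' Real-valued burst length from the closed-form quadratic
#'
#' Solves for the cycle count `n` at which the active cell's subthreshold
#' potential has dropped to the silent cell's. Substituting the iterated
#' calcium expressions into the potential balance `a + b*x_n = c + d*y_n`
#' and clearing denominators yields a quadratic in \eqn{\rho = r^n},
#' \deqn{m_1 \rho^2 + m_2 \rho + m_3 = 0,} with
#' \deqn{m_1 = m\,s_0(a_0 - \bar A),}
#' \deqn{m_2 = m[s_0(\bar A + k_1) + k_1(a_0 - \bar A)] -
#'             [d(a_0 - \bar A) - b s_0],}
#' \deqn{m_3 = (\bar A + k_1)(m k_1 - d) + b k_1,}
#' and returns \eqn{n_{Ca} = \ln\rho / \ln r} for the admissible root.
#'
#' Root handling: the principal root \eqn{(-m_2 + \sqrt{m_2^2 - 4m_1m_3})
#' / (2m_1)} is used when it is positive and keeps both cleared
#' denominators positive; otherwise the companion root is tried (with a
#' warning). Roots are evaluated in the cancellation-free form. When
#' \eqn{|m_1|} is below `1e-12` (e.g. `s0 = 0` or `a0 = Abar`) the
#' quadratic degenerates and the linear equation `m2 * rho + m3 = 0` is
#' solved instead. A negative discriminant or no admissible positive root
#' means the potentials never equalize: the cells never interchange, and
#' `Inf` is returned. Note \eqn{\rho > 1} (i.e. \eqn{n_{Ca} < 0}) is
#' admissible: it signals that the active cell is already less excitable
#' than the silent one, so the interchange happens on the first cycle.
#'
#' @param x0,y0 burst-initial calcium of the active / silent cell.
#' @param p a [model_params()] object.
#' @param dc a [derive_constants()] object; defaults to
#'   `derive_constants(p)`.
#' @return The real cycle count `n_Ca` (possibly negative), or `Inf` when
#'   no interchange occurs.
#' @seealso [nspb()] for the integer spike count.
#' @export
nspb_real <- function(x0, y0, p, dc = derive_constants(p)) {
  stopifnot(x0 >= 0, y0 >= 0)
  a0 <- x0
  s0 <- y0
  Abar <- dc$Abar
  k1 <- dc$k1
  m <- dc$m
  b <- dc$b
  d <- dc$d
  m1 <- m * s0 * (a0 - Abar)
  m2 <- m * (s0 * (Abar + k1) + k1 * (a0 - Abar)) - (d * (a0 - Abar) - b * s0)
  m3 <- (Abar + k1) * (m * k1 - d) + b * k1

  # cleared denominators must stay positive for a root to correspond to a
  # genuine potential balance (they came from Ca_a(n)+k1 and Ca_s(n)+k1)
  admissible <- function(rho) {
    is.finite(rho) && rho > 0 &&
      (a0 - Abar) * rho + Abar + k1 > 0 && s0 * rho + k1 > 0
  }

  if (abs(m1) < 1e-12) {
    if (abs(m2) < 1e-15) return(Inf)
    rho <- -m3 / m2
    if (!admissible(rho)) return(Inf)
    return(log(rho) / log(dc$r))
  }

  disc <- m2^2 - 4 * m1 * m3
  if (disc < 0) return(Inf)
  # evaluate the root pair without subtractive cancellation
  if (m2 >= 0) {
    root_minus <- (-m2 - sqrt(disc)) / (2 * m1)
    root_plus <- if (root_minus != 0) m3 / (m1 * root_minus) else
      (-m2 + sqrt(disc)) / (2 * m1)
  } else {
    root_plus <- (-m2 + sqrt(disc)) / (2 * m1)
    root_minus <- if (root_plus != 0) m3 / (m1 * root_plus) else
      (-m2 - sqrt(disc)) / (2 * m1)
  }
  if (admissible(root_plus)) {
    rho <- root_plus
  } else if (admissible(root_minus)) {
    warning("principal quadratic root inadmissible; using companion root")
    rho <- root_minus
  } else {
    return(Inf)
  }
  log(rho) / log(dc$r)
}

#' Number of spikes per burst (NSPB)
#'
#' The integer burst length: the smallest integer *strictly* greater than
#' the real crossing point [nspb_real()] (so an exact integer crossing
#' still yields one more spike), floored at 1 because the active cell
#' fires at least once before any interchange can be observed.
#'
#' @inheritParams nspb_real
#' @return A positive count, or `Inf` when the cells never interchange.
#' @examples
#' p <- model_params()
#' nspb(0, 3, p)
#' @export
nspb <- function(x0, y0, p, dc = derive_constants(p)) {
  n <- nspb_real(x0, y0, p, dc)
  if (!is.finite(n)) return(Inf)
  max(1, floor(n) + 1)
}

#' One step of the two-cell burst map
#'
#' Given burst-initial calcium `(Cx, Cy)` of the active and silent cell,
#' the active cell fires `n = nspb(Cx, Cy)` spikes and the roles swap:
#' \deqn{C_x' = r^n C_y, \qquad C_y' = r^n C_x + \bar A(1 - r^n).}
#' The new active cell is the former silent one.
#'
#' @param state numeric length-2 vector `c(Cx, Cy)`: active then silent.
#' @inheritParams nspb_real
#' @return A list with `state` (the new `c(Cx, Cy)`) and `n` (the NSPB of
#'   the completed burst).
#' @export
map_step <- function(state, p, dc = derive_constants(p)) {
  stopifnot(length(state) == 2, all(state >= 0))
  n <- nspb(state[1], state[2], p, dc)
  if (!is.finite(n)) {
    stop("burst map undefined: cells never interchange from state (",
         state[1], ", ", state[2], ")", call. = FALSE)
  }
  rn <- dc$r^n
  list(state = c(rn * state[2], rn * state[1] + dc$Abar * (1 - rn)), n = n)
}

#' Iterate the two-cell burst map
#'
#' @param state starting `c(Cx, Cy)`.
#' @param steps number of bursts to iterate.
#' @inheritParams nspb_real
#' @return A data frame with columns `step`, `Cx`, `Cy` (calcium at the
#'   start of each burst) and `nspb` (spikes fired in that burst).
#' @export
iterate_map <- function(state, steps, p, dc = derive_constants(p)) {
  out <- data.frame(step = seq_len(steps), Cx = NA_real_, Cy = NA_real_,
                    nspb = NA_real_)
  for (i in seq_len(steps)) {
    out$Cx[i] <- state[1]
    out$Cy[i] <- state[2]
    st <- map_step(state, p, dc)
    out$nspb[i] <- st$n
    state <- st$state
  }
  out
}

#' Fixed point of the burst map at burst count k
#'
#' Freezing the burst count at `n = k` makes the map affine,
#' `x -> r^k D x + d_k` with `D` the swap matrix, whose unique fixed point
#' has the closed form
#' \deqn{D_k = \left(\frac{\bar A r^k}{1 + r^k},\;
#'       \frac{\bar A}{1 + r^k}\right).}
#' `D_k` is a genuine, stable fixed point of the full (nonlinear) burst map
#' exactly when the frozen count is self-consistent, i.e.
#' \eqn{k - 1 < n_{Ca}(D_k) < k}; near such a point the map contracts
#' distances by the factor \eqn{r^k} per burst.
#'
#' @param k positive integer burst count.
#' @inheritParams nspb_real
#' @return A list of class `"fixed_point_result"` with elements `k`,
#'   `point` (length-2 calcium vector), `nCa` (the real crossing count at
#'   the point) and `stable` (logical, the self-consistency test).
#' @export
fixed_point <- function(k, p, dc = derive_constants(p)) {
  stopifnot(k >= 1, k == round(k))
  rk <- dc$r^k
  # solve (I - r^k D) x = (0, Abar (1 - r^k)) directly
  A <- diag(2) - rk * matrix(c(0, 1, 1, 0), 2, 2)
  point <- solve(A, c(0, dc$Abar * (1 - rk)))
  nCa <- nspb_real(point[1], point[2], p, dc)
  structure(list(k = as.integer(k), point = point, nCa = nCa,
                 stable = is.finite(nCa) && (k - 1 < nCa) && (nCa < k)),
            class = "fixed_point_result")
}

#' @export
print.fixed_point_result <- function(x, ...) {
  cat(sprintf("<fixed point D_%d>  Cx = %.6f  Cy = %.6f\n",
              x$k, x$point[1], x$point[2]))
  cat(sprintf("  n_Ca at point = %.6f  -> %s\n", x$nCa,
              if (x$stable) "stable (k-1 < n_Ca < k)" else "not stable"))
  invisible(x)
}

#' Find an AHP conductance giving a stable burst count k
#'
#' The real burst length at the fixed point, `n_Ca(D_k)`, decreases
#' continuously from infinity (no interchange as `gAHP -> 0`) to below 1
#' (`gAHP` very large), so for every `k` there is a `gAHP` at which the
#' fixed point `D_k` is stable. This routine bisects `gAHP` to place
#' `n_Ca(D_k)` at the middle of the stability window, `k - 1/2`. Note
#' `D_k` itself does not depend on `gAHP` (only on `r` and `Abar`), so the
#' bisection only re-derives the potential-balance coefficients.
#'
#' @param k desired burst count.
#' @param p a [model_params()] object (its `gAHP` is ignored).
#' @param bracket length-2 positive vector bracketing the solution.
#' @param tol bisection tolerance on `n_Ca(D_k) - (k - 1/2)`.
#' @return The `gAHP` value found.
#' @export
find_gAHP_for_k <- function(k, p, bracket = c(1e-3, 1e5), tol = 1e-6) {
  stopifnot(length(bracket) == 2, all(bracket > 0), bracket[1] < bracket[2])
  f <- function(g) {
    q <- p
    q$gAHP <- g
    dc <- derive_constants(q)
    fp <- fixed_point(k, q, dc)
    if (!is.finite(fp$nCa)) return(Inf)  # no interchange: burst too long
    fp$nCa - (k - 0.5)
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (!(flo > 0 && fhi < 0)) {
    stop("bracket does not straddle the target burst count: n_Ca offsets ",
         "at endpoints are ", format(flo), " and ", format(fhi),
         call. = FALSE)
  }
  for (i in 1:200) {
    mid <- sqrt(lo * hi)  # gAHP spans decades; bisect in log scale
    fm <- f(mid)
    if (is.finite(fm) && abs(fm) < tol) return(mid)
    if (fm > 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}
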