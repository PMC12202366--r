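#' Cyclic-shift permutation of the (m+1)-cell map
#'
#' The state vector lists the active cell first and the silent cells in
#' ascending calcium order (next to fire first). One burst rotates the
#' roles: every silent cell moves up one rank and the former active cell
#' drops to the last rank. `perm_matrix(m)` is that cyclic shift as an
#' (m+1) x (m+1) permutation matrix.
#'
#' @param m number of silent cells (so the network has m+1 ICs).
#' @return An (m+1) x (m+1) 0/1 matrix.
#' @export
perm_matrix <- function(m) {
  stopifnot(m >= 1)
  E <- matrix(0, m + 1, m + 1)
  for (i in seq_len(m)) E[i, i + 1] <- 1
  E[m + 1, 1] <- 1
  E
}

#' One step of the (m+1)-cell burst map
#'
#' The active cell (entry 1) competes with the most excitable silent cell
#' (entry 2, the lowest-calcium one); the burst length is
#' `n = nspb(Ca[1], Ca[2])`. All cells then decay by `r^n`, the active cell
#' additionally accumulates toward `Abar`, and the ranks rotate:
#' \deqn{Ca' = r^n E_m Ca + (0, \ldots, 0, \bar A(1 - r^n))^T.}
#' With `m = 1` this is exactly the two-cell [map_step()].
#'
#' The construction assumes inhibition is strong and calcium accumulation
#' fast enough that the retiring cell ends its burst with more calcium than
#' every silent cell; if the assumption fails the returned ordering is no
#' longer ascending. By default this raises a warning and the state is kept
#' as produced; with `resort = TRUE` the silent ranks are re-sorted instead.
#'
#' @param ca numeric vector of length m+1: active cell's calcium first,
#'   then silent cells in ascending calcium order.
#' @inheritParams nspb_real
#' @param resort re-sort the silent cells if the rank-order assumption is
#'   violated (default `FALSE`: warn and keep).
#' @return A list with `ca` (new state vector) and `n` (the burst's NSPB).
#' @export
multi_map_step <- function(ca, p, dc = derive_constants(p), resort = FALSE) {
  m <- length(ca) - 1
  stopifnot(m >= 1, all(ca >= 0))
  n <- nspb(ca[1], ca[2], p, dc)
  if (!is.finite(n)) {
    stop("burst map undefined: cells never interchange from state (",
         paste(signif(ca, 6), collapse = ", "), ")", call. = FALSE)
  }
  rn <- dc$r^n
  new_ca <- rn * c(ca[-1], ca[1])
  new_ca[m + 1] <- new_ca[m + 1] + dc$Abar * (1 - rn)
  # with a single silent cell the rank ordering is vacuous; for m >= 2 a
  # retiring cell that re-enters below another silent cell breaks the
  # ascending-order reading of the state vector
  if (m >= 2 && new_ca[m + 1] < max(new_ca[1:m])) {
    if (resort) {
      new_ca[-1] <- sort(new_ca[-1])
    } else {
      warning("rank-order assumption violated: retiring cell's calcium (",
              signif(new_ca[m + 1], 6),
              ") does not exceed every silent cell's")
    }
  }
  list(ca = new_ca, n = n)
}

#' Iterate the (m+1)-cell burst map
#'
#' @param ca starting state (active first, silents ascending).
#' @param steps number of bursts.
#' @inheritParams multi_map_step
#' @return A data frame with `step`, one `Ca` column per rank (state at the
#'   start of each burst), and `nspb`.
#' @export
iterate_multi_map <- function(ca, steps, p, dc = derive_constants(p),
                              resort = FALSE) {
  mm <- length(ca)
  out <- matrix(NA_real_, steps, mm + 1)
  for (i in seq_len(steps)) {
    out[i, seq_len(mm)] <- ca
    st <- multi_map_step(ca, p, dc, resort = resort)
    out[i, mm + 1] <- st$n
    ca <- st$ca
  }
  out <- as.data.frame(out)
  names(out) <- c(paste0("Ca", seq_len(mm)), "nspb")
  cbind(step = seq_len(steps), out)
}

#' Compose s frozen-count burst maps into one affine map
#'
#' With the burst counts frozen at `n_vec = (n1, ..., ns)`, each burst is
#' the affine map `x -> r^(ni) E_m x + d_(ni)` and their composition is
#' again affine:
#' \deqn{F_{\vec n}(x) = r^{n_1 + \cdots + n_s} E_m^s\, x + \vec d_{\vec n},}
#' where the offset accumulates each burst's injection, shifted through the
#' remaining rotations. The spectral radius of the linear part is
#' `r^(sum(n_vec)) < 1`, so the composed map is a contraction.
#'
#' @param n_vec integer vector of s burst counts.
#' @param m number of silent cells.
#' @param dc a [derive_constants()] object.
#' @return A list with `M` (the (m+1)^2 linear part) and `offset`.
#' @export
compose_maps <- function(n_vec, m, dc) {
  stopifnot(length(n_vec) >= 1, all(n_vec >= 1))
  E <- perm_matrix(m)
  M <- diag(m + 1)
  offset <- rep(0, m + 1)
  for (n in n_vec) {
    d_n <- c(rep(0, m), dc$Abar * (1 - dc$r^n))
    offset <- dc$r^n * (E %*% offset) + d_n
    M <- dc$r^n * (E %*% M)
  }
  list(M = M, offset = as.numeric(offset))
}

#' s-periodic orbits of the (m+1)-cell map
#'
#' Solves for the state that repeats after a prescribed pattern of s burst
#' counts `n_vec = (n1, ..., ns)`, as the fixed point of the composed
#' affine map: \eqn{D = (I - r^{\sum n_i} E_m^s)^{-1} \vec d_{\vec n}}
#' (always uniquely solvable since the linear part has spectral radius
#' below 1). The point is a genuine stable s-periodic orbit of the full
#' nonlinear map when the frozen counts are self-consistent: at every stage
#' `i` of the orbit the real crossing count satisfies
#' `n_i - 1 < n_Ca < n_i`. The check iterates [multi_map_step()]'s
#' competition through the orbit; on failure the violating stage is
#' reported.
#'
#' @param n_vec integer vector of s burst counts, `s < m + 1`.
#' @param m number of silent cells.
#' @inheritParams nspb_real
#' @return A list of class `"periodic_orbit"`: `n_vec`, `point` (the
#'   orbit's base state), `stable`, `nCa_stages` (the real crossing count
#'   at each stage) and `violated` (index of the first failed stage, or
#'   `NA`).
#' @export
s_periodic_point <- function(n_vec, m, p, dc = derive_constants(p)) {
  s <- length(n_vec)
  stopifnot(m >= 1, s >= 1)
  if (s >= m + 1) {
    stop("pattern length s = ", s, " must be below the cell count m+1 = ",
         m + 1, call. = FALSE)
  }
  comp <- compose_maps(n_vec, m, dc)
  point <- as.numeric(solve(diag(m + 1) - comp$M, comp$offset))
  # self-consistency along the orbit
  x <- point
  nCa_stages <- numeric(s)
  violated <- NA_integer_
  for (i in seq_len(s)) {
    nCa_stages[i] <- nspb_real(x[1], x[2], p, dc)
    ok <- is.finite(nCa_stages[i]) &&
      (n_vec[i] - 1 < nCa_stages[i]) && (nCa_stages[i] < n_vec[i])
    if (!ok && is.na(violated)) violated <- i
    rn <- dc$r^n_vec[i]
    x <- rn * c(x[-1], x[1])
    x[m + 1] <- x[m + 1] + dc$Abar * (1 - rn)
  }
  structure(list(n_vec = as.integer(n_vec), m = m, point = point,
                 stable = is.na(violated), nCa_stages = nCa_stages,
                 violated = violated),
            class = "periodic_orbit")
}

#' @export
print.periodic_orbit <- function(x, ...) {
  cat(sprintf("<%d-periodic orbit> pattern (%s), %d+1 cells\n",
              length(x$n_vec), paste(x$n_vec, collapse = ","), x$m))
  cat("  base state:", paste(signif(x$point, 6), collapse = ", "), "\n")
  cat("  stable:", x$stable,
      if (!is.na(x$violated)) paste0(" (stage ", x$violated, " violated)"),
      "\n")
  invisible(x)
}
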