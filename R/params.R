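#' Model parameters for the calcium-modulated bursting network
#'
#' Constructs and validates the full biophysical parameter set of the
#' integrate-and-fire network: leaky inhibitory cells (ICs) carrying a
#' calcium-gated potassium afterhyperpolarization current (I_AHP), mutually
#' coupled by exponentially decaying GABAergic inhibition, all driven by one
#' suprathreshold excitatory cell (EC) through fast AMPA-like excitation.
#'
#' All printed constants are treated as one self-consistent model-unit system
#' (voltages in mV, time in ms, calcium in model uM); no unit conversion is
#' applied anywhere in the package.
#'
#' @param Cm membrane capacitance (default 1).
#' @param gl leak conductance (default 0.18).
#' @param EL leak reversal potential, mV (default -60).
#' @param vT spike threshold, mV (default -50).
#' @param vR reset potential, mV (default -75).
#' @param gAHP maximal conductance of the calcium-gated potassium current
#'   (default 50).
#' @param k1 calcium half-activation constant of I_AHP (default 10).
#' @param EK potassium reversal potential, mV (default -90).
#' @param kCa calcium decay rate, 1/ms (default 0.001).
#' @param dCa calcium increment added at each spike (default 1).
#' @param Iapp applied current to each IC (default 0.2).
#' @param Istim applied current to the EC (default 2).
#' @param gi IC-to-IC inhibitory conductance (default 25).
#' @param ge EC-to-IC excitatory conductance (default 4).
#' @param EGABA inhibitory reversal potential, mV (default -80).
#' @param EAMPA excitatory reversal potential, mV (default 0).
#' @param betai inhibitory synaptic decay rate, 1/ms (default 0.1).
#' @param betae excitatory synaptic decay rate, 1/ms (default 2).
#' @param t3 inter-spike interval of the active cell, ms. `NULL` (the
#'   default) means "derive from the EC pacing period", i.e.
#'   [ec_period()], since the EC paces IC firing one spike per cycle.
#'
#' @return An object of class `"model_params"`: a named list of the
#'   validated constants, with `t3` resolved to a number.
#' @seealso [ec_period()], [derive_constants()], [read_config()]
#' @examples
#' p <- model_params()
#' p$t3  # EC pacing period, about 17.5 ms
#' @export
model_params <- function(Cm = 1, gl = 0.18, EL = -60, vT = -50, vR = -75,
                         gAHP = 50, k1 = 10, EK = -90, kCa = 0.001,
                         dCa = 1, Iapp = 0.2, Istim = 2, gi = 25, ge = 4,
                         EGABA = -80, EAMPA = 0, betai = 0.1, betae = 2,
                         t3 = NULL) {
  p <- list(Cm = Cm, gl = gl, EL = EL, vT = vT, vR = vR, gAHP = gAHP,
            k1 = k1, EK = EK, kCa = kCa, dCa = dCa, Iapp = Iapp,
            Istim = Istim, gi = gi, ge = ge, EGABA = EGABA, EAMPA = EAMPA,
            betai = betai, betae = betae, t3 = t3)
  p <- lapply(p, function(x) if (is.null(x)) x else as.numeric(x))
  class(p) <- "model_params"
  validate_params(p)
  if (is.null(p$t3)) p$t3 <- ec_period(p)
  validate_params(p)
  p
}

validate_params <- function(p) {
  pos <- c("Cm", "gl", "gAHP", "k1", "kCa", "dCa", "gi", "ge",
           "betai", "betae")
  for (f in pos) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) {
      stop("invalid parameter: `", f, "` must be strictly positive, got ",
           p[[f]], call. = FALSE)
    }
  }
  if (!is.null(p$t3) && (!is.finite(p$t3) || p$t3 <= 0)) {
    stop("invalid parameter: `t3` must be strictly positive, got ",
         p$t3, call. = FALSE)
  }
  if (p$vR >= p$vT) {
    stop("invalid parameter: `vR` must be below `vT` (got vR = ", p$vR,
         ", vT = ", p$vT, ")", call. = FALSE)
  }
  if (!(p$EK < p$EL && p$EL < p$vT)) {
    stop("invalid parameter: ordering EK < EL < vT violated (EK = ", p$EK,
         ", EL = ", p$EL, ", vT = ", p$vT, ")", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  nm <- names(x)
  for (f in nm) cat(sprintf("  %-6s = %g\n", f, x[[f]]))
  invisible(x)
}

#' Firing period of the excitatory cell
#'
#' The EC is a plain leaky integrate-and-fire unit with constant drive, so
#' its period between reset and threshold has the closed form
#' \deqn{T = (C_m/g_l)\,\ln\frac{v_\infty - v_R}{v_\infty - v_T}, \qquad
#'       v_\infty = E_L + I_{stim}/g_l,}
#' valid when the EC is suprathreshold (\eqn{v_\infty > v_T}). Under the
#' default constants T is about 17.54 ms. Because the EC paces IC spiking,
#' this period doubles as the default inter-spike interval `t3` of the
#' discrete map.
#'
#' @param p a [model_params()] object.
#' @return Period in ms.
#' @examples
#' ec_period(model_params())
#' @export
ec_period <- function(p) {
  vinf <- p$EL + p$Istim / p$gl
  if (vinf <= p$vT) {
    stop("EC does not fire: EL + Istim/gl = ", vinf,
         " is not above threshold vT = ", p$vT, call. = FALSE)
  }
  (p$Cm / p$gl) * log((vinf - p$vR) / (vinf - p$vT))
}

#' Map-level constants derived from the biophysical parameters
#'
#' Computes the quantities that the discrete-map reduction works with:
#' \itemize{
#'   \item `r = exp(-kCa * t3)`, the fraction of calcium retained over one
#'     inter-spike interval;
#'   \item `Abar = dCa * r / (1 - r)`, the asymptotic calcium level the
#'     end-of-interval measurements of an eternally active cell approach
#'     (each cycle adds `dCa` at the spike and then decays by `r`, so the
#'     fixed point of `Ca -> (Ca + dCa) * r` is `dCa * r / (1 - r)`);
#'   \item `siEnd = exp(-betai * t3)`, the inhibitory gate remaining at the
#'     end of an interval (the gate resets to 1 at each presynaptic spike);
#'   \item the four rational coefficients `a`, `b`, `c`, `d` that reduce the
#'     subthreshold-potential balance between active and silent cell to the
#'     linear form `a + b*x = c + d*y` in the calcium activations
#'     `x = Ca/(Ca+k1)`, and their combination `m = (-a - b + c + d)/k1`
#'     entering the NSPB quadratic.
#' }
#'
#' `m` is divided by `k1` (not multiplied): expanding
#' `a + b*x = c + d*y` with `x = 1 - k1/(Ca_a + k1)` gives
#' `-b/(Ca_a + k1) + d/(Ca_s + k1) = (-a - b + c + d)/k1`, and only this
#' reading makes the quadratic coefficients consistent with the direct
#' cycle-by-cycle switch criterion (checked against the brute-force oracle
#' in the test suite).
#'
#' @param p a [model_params()] object.
#' @return An object of class `"derived_constants"`: a list with elements
#'   `r`, `Abar`, `siEnd`, `a`, `b`, `c`, `d`, `m`, plus `k1`, `dCa`, `t3`
#'   carried along for the map functions.
#' @examples
#' dc <- derive_constants(model_params())
#' dc$Abar * (1 - dc$r) / dc$r  # recovers dCa
#' @export
derive_constants <- function(p) {
  stopifnot(inherits(p, "model_params"))
  validate_params(p)
  r <- exp(-p$kCa * p$t3)
  Abar <- p$dCa * r / (1 - r)
  siEnd <- exp(-p$betai * p$t3)
  denA <- p$gl * (p$EL - p$EK) + p$Iapp
  denS <- p$gl * (p$EL - p$EK) + p$gi * siEnd * (p$EGABA - p$EK) + p$Iapp
  a <- p$gl / denA
  b <- p$gAHP / denA
  cc <- (p$gl + p$gi * siEnd) / denS
  d <- p$gAHP / denS
  m <- (-a - b + cc + d) / p$k1
  structure(list(r = r, Abar = Abar, siEnd = siEnd,
                 a = a, b = b, c = cc, d = d, m = m,
                 k1 = p$k1, dCa = p$dCa, t3 = p$t3),
            class = "derived_constants")
}

#' @export
print.derived_constants <- function(x, ...) {
  cat("<derived_constants>\n")
  cat(sprintf("  r     = %.6f   (calcium retained per cycle)\n", x$r))
  cat(sprintf("  Abar  = %.4f  (asymptotic calcium)\n", x$Abar))
  cat(sprintf("  siEnd = %.6f   (inhibition left at ISI end)\n", x$siEnd))
  cat(sprintf("  a = %.6g  b = %.6g\n  c = %.6g  d = %.6g\n  m = %.6g\n",
              x$a, x$b, x$c, x$d, x$m))
  invisible(x)
}

#' Read and write model configuration files
#'
#' A configuration file is a flat JSON object with one key per
#' [model_params()] field. Unknown keys are an error (they would silently
#' change nothing). `t3` may be omitted or `null`, in which case it is
#' derived from the EC period as usual.
#'
#' @param path file path of the JSON configuration.
#' @return `read_config()` returns a validated [model_params()] object.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(model_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(model_params, cfg)
}

#' @rdname read_config
#' @param p a [model_params()] object to serialize.
#' @return `write_config()` returns `path` invisibly.
#' @export
write_config <- function(p, path) {
  stopifnot(inherits(p, "model_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname read_config
#' @details `write_default_config()` writes the default constants (with
#'   `EGABA` and `EAMPA` stated explicitly, since the comparison experiments
#'   depend on them) and is the canonical starting point for configuring
#'   runs.
#' @export
write_default_config <- function(path) {
  write_config(model_params(), path)
}
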