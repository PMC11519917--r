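#' Luminophore emission kinetics parameters
#'
#' Describes a one-compartment excitation/decay luminophore: during the
#' excitation pulse the emission rises as `F0 * (1 - exp(-(t - t_on)/tau_p))`
#' towards the equilibrium emission `F0`; after the pulse stops at `t_off` the
#' phosphorescence decays monoexponentially from the peak emission
#' `Fm = F0 * (1 - exp(-(t_off - t_on)/tau_p))` with lifetime `tau_d`. A
#' constant, non-decaying background emission rate `background` (ambient light
#' plus any sensor offset expressed as an emission rate) is present at all
#' times; because both straddled frames share the same exposure duration it
#' cancels exactly in the integrated decay `P`.
#'
#' @param tau_d luminescence decay lifetime (microseconds), `> 0`.
#' @param f0 equilibrium emission rate (arbitrary intensity per microsecond).
#' @param tau_p excitation rise time (microseconds). Defaults to `tau_d`:
#'   rise and decay of a single excited-state population share kinetics.
#' @param t_on time the excitation starts (microseconds).
#' @param t_off time the excitation stops (microseconds); may be `Inf` for a
#'   pulse that never ends (only the rise branch is then defined).
#' @param background constant background emission rate, `>= 0`.
#' @return An object of class `kinetics_params`.
#' @seealso [emission_timecourse()], [frame_integrals()]
#' @export
#' @examples
#' kp <- kinetics_params(tau_d = 62, t_off = 80)
#' emission_timecourse(kp, c(0, 40, 80, 142))
kinetics_params <- function(tau_d, f0 = 1, tau_p = NULL, t_on = 0,
                            t_off = Inf, background = 0) {
  if (is.null(tau_p)) tau_p <- tau_d
  if (!is.numeric(tau_d) || length(tau_d) != 1L || !is.finite(tau_d) ||
      tau_d <= 0)
    stop("'tau_d' must be a single positive number (microseconds)")
  if (!is.numeric(tau_p) || length(tau_p) != 1L || !is.finite(tau_p) ||
      tau_p <= 0)
    stop("'tau_p' must be a single positive number (microseconds)")
  if (!is.numeric(f0) || length(f0) != 1L || f0 < 0)
    stop("'f0' must be a single non-negative number")
  if (!is.numeric(background) || length(background) != 1L || background < 0)
    stop("'background' must be a single non-negative number")
  if (!(t_off > t_on)) stop("'t_off' must be greater than 't_on'")
  structure(
    list(f0 = f0, tau_p = tau_p, tau_d = tau_d,
         t_on = t_on, t_off = t_off, background = background),
    class = "kinetics_params")
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat("Luminophore kinetics: F0 =", x$f0,
      " tau_p =", x$tau_p, "us  tau_d =", x$tau_d, "us\n")
  cat("  pulse [", x$t_on, ",", x$t_off, "] us, background", x$background,
      "per us\n")
  invisible(x)
}

# peak emission reached at the end of the pulse (f0 scale)
.peak_emission <- function(params) {
  if (!is.finite(params$t_off)) return(params$f0)
  params$f0 * (-expm1(-(params$t_off - params$t_on) / params$tau_p))
}

#' Luminophore emission as a function of time
#'
#' Evaluates the piecewise closed-form emission: constant background before
#' the pulse, exponential rise towards `F0` during the pulse, monoexponential
#' decay from the peak emission `Fm` after the pulse. The curve is continuous
#' at the pulse end.
#'
#' @param params a [kinetics_params()] object.
#' @param times numeric vector of time points (microseconds), sorted
#'   ascending.
#' @return Numeric vector of emission rates, one per time point.
#' @export
#' @examples
#' kp <- kinetics_params(tau_d = 62, t_off = 80)
#' emission_timecourse(kp, c(79.999, 80, 80.001))  # continuous at pulse end
emission_timecourse <- function(params, times) {
  stopifnot(inherits(params, "kinetics_params"))
  if (!is.numeric(times) || length(times) == 0L)
    stop("'times' must be a non-empty numeric vector")
  if (is.unsorted(times, strictly = FALSE))
    stop("'times' must be sorted in ascending order")
  .emission_eval(params, times)
}

# evaluation core without the sortedness contract, for quadrature callers
.emission_eval <- function(params, times) {
  out <- rep(params$background, length(times))
  rise <- times >= params$t_on & times <= params$t_off
  out[rise] <- out[rise] +
    params$f0 * (-expm1(-(times[rise] - params$t_on) / params$tau_p))
  if (is.finite(params$t_off)) {
    dec <- times > params$t_off
    fm <- .peak_emission(params)
    out[dec] <- out[dec] + fm * exp(-(times[dec] - params$t_off) / params$tau_d)
  }
  out
}

#' Stern-Volmer lifetime law
#'
#' Collisional quenching of the luminophore triplet state by oxygen follows
#' `tau_d0 / tau_d = 1 + K_SV * [O2]`, i.e. the lifetime decreases
#' hyperbolically from the unquenched value `tau_d0` as oxygen increases.
#'
#' @param tau_d0 unquenched lifetime at 0% air saturation (microseconds).
#' @param ksv Stern-Volmer quenching constant (per % air saturation), `>= 0`.
#' @return An object of classes `sv_law`, `lifetime_law`.
#' @export
#' @examples
#' law <- sv_law(tau_d0 = 62, ksv = (62 / 22 - 1) / 100)  # 22 us at air sat.
#' lifetime_from_o2(law, c(0, 100))
sv_law <- function(tau_d0, ksv) {
  if (!is.numeric(tau_d0) || length(tau_d0) != 1L || tau_d0 <= 0)
    stop("'tau_d0' must be a single positive number (microseconds)")
  if (!is.numeric(ksv) || length(ksv) != 1L || ksv < 0)
    stop("'ksv' must be a single non-negative number")
  structure(list(tau_d0 = tau_d0, ksv = ksv),
            class = c("sv_law", "lifetime_law"))
}

#' @export
print.sv_law <- function(x, ...) {
  cat("Stern-Volmer law: tau_d0 =", x$tau_d0, "us, K_SV =", x$ksv,
      "per % air sat.\n")
  invisible(x)
}

#' Empirical lifetime-vs-oxygen law
#'
#' An empirical calibration of lifetime against oxygen of the form
#' `1 / (a * exp(-o2 / b) + c)`, evaluated literally as printed for a
#' PtTFPP planar optode. The units of the parenthesized term are ambiguous in
#' the source calibration, so `interpretation` selects how the expression is
#' read: `"rate"` (default) treats it as a decay rate in 1/ms and reports the
#' lifetime in microseconds (`1000 / (...)`); `"lifetime"` treats the whole
#' expression as a lifetime in microseconds. Note that under either reading
#' the law increases with oxygen; it is provided for reproducing timing
#' calculations made with it, not as a physically canonical quenching model
#' (use [sv_law()] for that).
#'
#' @param a,b,c law parameters; defaults are the fitted planar-optode values
#'   (`a = 35.77`, `b = 56.3` % air sat., `c = 22.63`).
#' @param interpretation `"rate"` or `"lifetime"`, see Details.
#' @return An object of classes `empirical_law`, `lifetime_law`.
#' @export
empirical_law <- function(a = 35.77, b = 56.3, c = 22.63,
                          interpretation = c("rate", "lifetime")) {
  interpretation <- match.arg(interpretation)
  if (a < 0 || b <= 0 || c <= 0)
    stop("'a' must be >= 0 and 'b', 'c' must be > 0 for a positive lifetime")
  structure(list(a = a, b = b, c = c, interpretation = interpretation),
            class = c("empirical_law", "lifetime_law"))
}

#' @export
print.empirical_law <- function(x, ...) {
  cat("Empirical lifetime law: 1/(", x$a, "* exp(-o2/", x$b, ") +", x$c,
      "), interpretation:", x$interpretation, "\n")
  invisible(x)
}

#' Luminescence lifetime at a given oxygen level
#'
#' @param law a [sv_law()] or [empirical_law()] object.
#' @param o2 oxygen level(s), % air saturation, `>= 0`.
#' @return Lifetime(s) in microseconds.
#' @export
lifetime_from_o2 <- function(law, o2) {
  if (!is.numeric(o2) || any(!is.finite(o2)) || any(o2 < 0))
    stop("'o2' must be finite and non-negative (% air saturation)")
  UseMethod("lifetime_from_o2")
}

#' @export
lifetime_from_o2.sv_law <- function(law, o2) {
  law$tau_d0 / (1 + law$ksv * o2)
}

#' @export
lifetime_from_o2.empirical_law <- function(law, o2) {
  rate <- law$a * exp(-o2 / law$b) + law$c
  switch(law$interpretation,
         rate = 1000 / rate,  # rate in 1/ms -> lifetime in us
         lifetime = 1 / rate)
}

#' Invert the Stern-Volmer law: oxygen from lifetime
#'
#' @param law a [sv_law()] object with `ksv > 0`.
#' @param tau_d measured lifetime(s), microseconds, `0 < tau_d <= tau_d0`.
#' @return Oxygen level(s), % air saturation. Round-trips with
#'   [lifetime_from_o2()] to machine precision.
#' @export
o2_from_lifetime <- function(law, tau_d) {
  stopifnot(inherits(law, "sv_law"))
  if (law$ksv == 0)
    stop("oxygen is undefined for 'ksv' = 0 (unquenched sensor)")
  if (any(!is.finite(tau_d)) || any(tau_d <= 0))
    stop("'tau_d' must be finite and positive")
  if (any(tau_d > law$tau_d0 * (1 + 1e-12)))
    stop("'tau_d' exceeds the unquenched lifetime 'tau_d0': ",
         "super-unquenched signal is outside the Stern-Volmer range")
  (law$tau_d0 / tau_d - 1) / law$ksv
}
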