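# Sagittal segment-angle waveform templates for the synthetic gait generator.
#
# The shank template is built by integrating a prescribed angular-velocity
# shape over one gait cycle (phase 0 = heel strike): a gently negative, flat
# stance baseline; a sharp negative trough at toe-off; a broad negative lobe
# in early swing (shank swings backward); a dominant positive lobe in
# mid-swing (rapid forward rotation); and a sharp negative trough at the next
# heel strike. Integrating and closing the loop (zero net rotation per cycle)
# yields an angle trace whose finite-difference velocity carries exactly the
# trough/peak signature the event detector keys on.
#
# The knee-flexion template is the rectified negative excursion of the shank
# template (knee flexion mirrors the backward shank swing), normalised to
# unit range. The thigh angle is *derived* as shank + knee, so the knee
# sagittal angle (thigh - shank) reproduces the knee template exactly. A
# phase shift of the knee bump is the one free shape parameter; it is solved
# per trial so the thigh range of motion meets its own target.

.template_cache <- new.env(parent = emptyenv())

# Nominal stance fraction of the templates; realised cycles are piecewise
# time-warped from this to their actual stance fraction.
TEMPLATE_STANCE_FRACTION <- 0.58

#' Gait waveform templates
#'
#' Returns the unit-range shank angle template, the derived knee flexion
#' template, and interpolating functions over gait-cycle phase.
#'
#' @param n Number of phase grid points.
#' @return A list with `phi` (phase grid), `shank` and `knee` (unit-range
#'   template values, `shank[1] == 0`, `knee[1] == 0`), `c0` (nominal stance
#'   fraction), and interpolators `shank_fun(phi)`, `knee_fun(phi, shift)`.
#' @keywords internal
#' @export
gait_templates <- function(n = 400L) {
  key <- as.character(n)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  c0 <- TEMPLATE_STANCE_FRACTION
  phi <- (seq_len(n) - 0.5) / n
  gauss <- function(x, mu, s) exp(-0.5 * ((x - mu) / s)^2)
  # early-swing backward lobe kept well clear of the toe-off trough so the
  # sampled velocity minimum stays centred on the event
  v <- -0.25 * (phi < c0) -
    4.0 * gauss(phi, c0, 0.020) -
    3.5 * gauss(phi, c0 + 0.20 * (1 - c0), 0.04) -
    4.0 * (gauss(phi, 0, 0.020) + gauss(phi, 1, 0.020))
  lobe <- gauss(phi, c0 + 0.55 * (1 - c0), 0.09)
  v <- v - (sum(v) / sum(lobe)) * lobe   # close the loop via the swing lobe
  S <- cumsum(v) / n
  S <- S - S[1]
  S <- S / diff(range(S))
  K <- pmax(-S, 0)
  K <- K / max(K)
  shank_fun <- stats::approxfun(phi, S, yleft = 0, yright = S[n], rule = 2)
  knee_base <- stats::approxfun(phi, K, yleft = 0, yright = 0)
  knee_fun <- function(p, shift = 0) knee_base(p - shift)
  out <- list(phi = phi, shank = S, knee = K, c0 = c0,
              shank_fun = shank_fun, knee_fun = knee_fun)
  .template_cache[[key]] <- out
  out
}

# Thigh range of motion implied by shank amplitude `a_shank`, knee amplitude
# `a_knee`, and knee bump shift `shift` (phase units).
thigh_rom_at_shift <- function(a_shank, a_knee, shift, tmpl = gait_templates()) {
  k <- tmpl$knee_fun(tmpl$phi, shift)
  m <- max(k)
  if (m <= 0) return(a_shank)
  diff(range(a_shank * tmpl$shank + (a_knee / m) * k))
}

# Solve the knee bump shift so the thigh ROM matches `target_thigh`.
# The ROM is (empirically) increasing in the shift over [0, 0.30]; a
# bracketing grid search plus uniroot refinement is used. When the target
# lies outside the achievable band, the closest endpoint is returned.
solve_knee_shift <- function(a_shank, a_knee, target_thigh,
                             tmpl = gait_templates()) {
  grid <- seq(0, 0.30, by = 0.02)
  f <- vapply(grid, function(d) thigh_rom_at_shift(a_shank, a_knee, d, tmpl),
              0) - target_thigh
  if (all(f > 0)) return(grid[which.min(abs(f))])
  if (all(f < 0)) return(grid[which.min(abs(f))])
  i <- which(f[-1] * f[-length(f)] <= 0)[1]
  stats::uniroot(function(d) thigh_rom_at_shift(a_shank, a_knee, d, tmpl) -
                   target_thigh,
                 lower = grid[i], upper = grid[i + 1], tol = 1e-4)$root
}

# Render one leg's shank and thigh angle traces on a time grid.
#
# hs_times: heel-strike times of the *extended* cycle sequence (covering the
# whole grid, including lead-in/lead-out cycles); stance_frac, a_shank,
# a_knee: per-cycle values (length = length(hs_times) - 1); shift: knee bump
# phase shift (scalar, per trial/leg).
render_leg <- function(tt, hs_times, stance_frac, a_shank, a_knee, shift,
                       tmpl = gait_templates()) {
  ncyc <- length(hs_times) - 1L
  stopifnot(length(stance_frac) == ncyc, length(a_shank) == ncyc,
            length(a_knee) == ncyc)
  cyc <- findInterval(tt, hs_times, rightmost.closed = FALSE)
  cyc <- pmin(pmax(cyc, 1L), ncyc)
  u <- (tt - hs_times[cyc]) / (hs_times[cyc + 1L] - hs_times[cyc])
  u <- pmin(pmax(u, 0), 1)
  c0 <- tmpl$c0
  cr <- stance_frac[cyc]
  ph <- ifelse(u <= cr, u * c0 / cr, c0 + (u - cr) * (1 - c0) / (1 - cr))
  kk <- tmpl$knee_fun(ph, shift)
  km <- max(tmpl$knee_fun(tmpl$phi, shift))
  shank <- a_shank[cyc] * tmpl$shank_fun(ph)
  knee <- (a_knee[cyc] / km) * kk
  list(shank = shank, thigh = shank + knee)
}
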