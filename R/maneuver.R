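#' Parameters of a simulated forced-expiration manoeuvre
#'
#' The clean expiratory flow profile is a quarter-sine rise to peak flow
#' followed by an exponential decay,
#' \deqn{f(t) = PEF \sin(\pi t / (2 t_r)) \; [t \le t_r], \qquad
#'       f(t) = PEF e^{-(t - t_r)/\tau} \; [t > t_r],}
#' rescaled so the total exhaled volume equals the requested FVC. The two
#' clinically meaningful dials are `pef` (peak expiratory flow, L/s) and `fvc`
#' (forced vital capacity, L); `rise_time` and `decay_tau` shape how fast the
#' peak is reached and how fast flow decays.
#'
#' @param fvc Forced vital capacity in liters (> 0).
#' @param pef Peak expiratory flow in L/s (> 0).
#' @param rise_time Time to peak flow in seconds (> 0).
#' @param decay_tau Exponential decay constant in seconds (> 0).
#' @param duration Total exhalation time in seconds; must be at least
#'   `6 * decay_tau` so the manoeuvre runs essentially to completion.
#' @param artifact One of `"none"`, `"cough"`, `"early_termination"`,
#'   `"submaximal"`, `"extra_breath"`. Any artifact other than `"none"` makes
#'   the manoeuvre unacceptable.
#' @param artifact_params Named list of artifact-specific scalars; missing
#'   entries are filled with defaults (see [inject_artifact()]).
#' @param seed Integer seed used when artifact parameters are drawn at random.
#' @param dt Sampling step in seconds.
#' @return An object of class `maneuver_params`.
#' @export
maneuver_params <- function(fvc = 4.0, pef = 8.0, rise_time = 0.1,
                            decay_tau = 0.6, duration = 6 * decay_tau,
                            artifact = c("none", "cough", "early_termination",
                                         "submaximal", "extra_breath"),
                            artifact_params = list(), seed = 1L, dt = 0.01) {
  artifact <- match.arg(artifact)
  for (nm in c("fvc", "pef", "rise_time", "decay_tau")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid parameter: `", nm, "` must be a single positive number",
           call. = FALSE)
  }
  if (duration < 6 * decay_tau)
    stop("invalid parameter: `duration` must be at least 6 * decay_tau",
         call. = FALSE)
  if (dt <= 0) stop("invalid parameter: `dt` must be positive", call. = FALSE)
  structure(list(fvc = fvc, pef = pef, rise_time = rise_time,
                 decay_tau = decay_tau, duration = duration,
                 artifact = artifact, artifact_params = artifact_params,
                 seed = as.integer(seed), dt = dt),
            class = "maneuver_params")
}

#' Simulate a clean forced-expiration manoeuvre
#'
#' Evaluates the flow profile described in [maneuver_params()] on a uniform
#' time grid, rescales it so that the total exhaled volume (trapezoidal
#' quadrature of flow over time) equals `fvc` exactly, and integrates flow
#' into the cumulative exhaled volume. The artifact requested in `params` is
#' *not* applied here; see [inject_artifact()].
#'
#' @param params A [maneuver_params()] object.
#' @return An object of class `maneuver` with fields `time` (s), `flow` (L/s),
#'   `volume` (L, cumulative), `label` (`"acceptable"`), `artifact`
#'   (`"none"`), `artifact_annotation` (`NULL`) and `params`.
#' @examples
#' m <- simulate_maneuver(maneuver_params(fvc = 4, pef = 8))
#' max(m$volume)  # 4, by construction
#' @export
simulate_maneuver <- function(params) {
  stopifnot(inherits(params, "maneuver_params"))
  t <- seq(0, params$duration, by = params$dt)
  f <- ifelse(t <= params$rise_time,
              params$pef * sin(pi * t / (2 * params$rise_time)),
              params$pef * exp(-(t - params$rise_time) / params$decay_tau))
  vol_raw <- pracma::trapz(t, f)
  f <- f * params$fvc / vol_raw
  v <- as.numeric(pracma::cumtrapz(t, f))
  structure(list(time = t, flow = f, volume = v, label = "acceptable",
                 artifact = "none", artifact_annotation = NULL,
                 params = params),
            class = "maneuver")
}

default_artifact_params <- function(artifact, m, seed) {
  p <- m$params
  set.seed(seed)
  dur <- max(m$time)
  switch(artifact,
    cough = list(onset = runif(1, 0.6, 0.85) * dur, width = 0.08,
                 amplitude = 0.5 * p$pef),
    early_termination = list(truncation_fraction = runif(1, 0.5, 0.85)),
    submaximal = list(scale = runif(1, 0.5, 0.75), flatten = 0.88),
    extra_breath = list(onset = runif(1, 0.35, 0.6) * dur, breath_dur = 0.4,
                        amplitude = 0.3 * p$pef),
    stop("unknown artifact: ", artifact, call. = FALSE))
}

#' Inject an acceptability-invalidating artifact into a clean manoeuvre
#'
#' Four artifact families cover the classic reasons a manoeuvre fails visual
#' inspection:
#' * `cough` — an additive, compactly supported flow oscillation (one positive
#'   and one negative Gaussian lobe) centred at `onset`; the series is altered
#'   only inside `[onset - 3 width, onset + 3 width]`.
#' * `early_termination` — the series is truncated when the exhaled volume
#'   reaches `truncation_fraction * fvc` (fraction < 0.9).
#' * `submaximal` — flow globally scaled by `scale` (< 0.8) and the peak
#'   flattened by capping at `flatten * max`.
#' * `extra_breath` — a negative-flow (inhalation) half-sine interval inserted
#'   at `onset`, after which exhalation resumes.
#'
#' Volume is re-integrated from the perturbed flow, the label is set to
#' `"unacceptable"`, and the perturbed time interval is recorded in
#' `artifact_annotation` so that downstream renderers can locate the artifact.
#'
#' @param m A clean [simulate_maneuver()] result.
#' @param params A [maneuver_params()] object with `artifact != "none"`;
#'   entries of `params$artifact_params` override the defaults drawn from
#'   `params$seed`.
#' @return A `maneuver` with perturbed `flow`/`volume`, `label =
#'   "unacceptable"` and `artifact_annotation = list(t_start, t_end)`.
#' @export
inject_artifact <- function(m, params) {
  stopifnot(inherits(m, "maneuver"), inherits(params, "maneuver_params"))
  if (params$artifact == "none")
    stop("invalid request: artifact is \"none\"; nothing to inject",
         call. = FALSE)
  if (m$artifact != "none")
    stop("invalid request: manoeuvre already carries an artifact",
         call. = FALSE)
  ap <- default_artifact_params(params$artifact, m, params$seed)
  ap[names(params$artifact_params)] <- params$artifact_params
  t <- m$time; f <- m$flow
  ann <- NULL
  if (params$artifact == "cough") {
    t0 <- ap$onset; w <- ap$width; A <- ap$amplitude
    win <- t >= t0 - 3 * w & t <= t0 + 3 * w
    lobe <- A * (exp(-((t - (t0 - w)) / w)^2) - exp(-((t - (t0 + w)) / w)^2))
    f[win] <- f[win] + lobe[win]
    ann <- list(t_start = t0 - 3 * w, t_end = t0 + 3 * w)
  } else if (params$artifact == "early_termination") {
    frac <- ap$truncation_fraction
    if (frac >= 0.9)
      stop("invalid parameter: truncation_fraction must be < 0.9",
           call. = FALSE)
    cut <- which(m$volume >= frac * params$fvc)[1]
    if (is.na(cut)) cut <- length(t)
    t <- t[1:cut]; f <- f[1:cut]
    ann <- list(t_start = max(t) * 0.9, t_end = max(t))
  } else if (params$artifact == "submaximal") {
    f <- f * ap$scale
    f <- pmin(f, ap$flatten * max(f))
    ann <- list(t_start = 0, t_end = max(t))
  } else if (params$artifact == "extra_breath") {
    t0 <- ap$onset; d <- ap$breath_dur
    win <- t >= t0 & t <= t0 + d
    dip <- (max(f[win]) + ap$amplitude) * sin(pi * (t - t0) / d)
    f[win] <- f[win] - dip[win]
    ann <- list(t_start = t0, t_end = t0 + d)
  }
  v <- as.numeric(pracma::cumtrapz(t, f))
  structure(list(time = t, flow = f, volume = v, label = "unacceptable",
                 artifact = params$artifact, artifact_annotation = ann,
                 params = params),
            class = "maneuver")
}

#' @export
print.maneuver <- function(x, ...) {
  cat("<maneuver> ", length(x$time), " samples over ",
      sprintf("%.2f", max(x$time)), " s; FVC(realized) = ",
      sprintf("%.2f", max(x$volume)), " L; PEF(realized) = ",
      sprintf("%.2f", max(x$flow)), " L/s; artifact = ", x$artifact,
      "; label = ", x$label, "\n", sep = "")
  invisible(x)
}
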