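#' Construct a FRAP trace
#'
#' A normalized fluorescence recovery curve: time in minutes with 0 at the
#' bleach, intensity 0 at the bleach and approaching the pre-bleach
#' baseline 1 at full recovery.
#'
#' @param times time points (min), non-negative and strictly increasing.
#' @param intensity normalized intensities, finite.
#' @return data frame of class `frap_trace` with columns `time_min`,
#'   `intensity`.
#' @export
frap_trace <- function(times, intensity) {
  stopifnot(length(times) == length(intensity), all(times >= 0),
            all(diff(times) > 0), all(is.finite(intensity)))
  df <- data.frame(time_min = times, intensity = intensity)
  class(df) <- c("frap_trace", "data.frame")
  df
}

#' Diffusion-reaction FRAP recovery model
#'
#' Two-component recovery of a bleached membrane spot: a freely diffusing
#' fraction `phi` recovering at the characteristic diffusive rate
#' `k_diff = D / r^2` and a bound fraction `1 - phi` turning over at
#' `k_reac`:
#' \deqn{f(t) = \phi\,[1 - \mathrm{erf}(1 / (2\sqrt{k_{diff} t}))] +
#'   (1-\phi)\,[1 - e^{-k_{reac} t}]}
#' The model satisfies f(0) = 0, f(t) -> 1 as t -> infinity, and is
#' non-decreasing in t.
#'
#' @param t time since bleach (min), >= 0.
#' @param phi free fraction in [0, 1].
#' @param k_diff diffusive rate D / r^2 (min^-1), >= 0.
#' @param k_reac bound-pool turnover rate (min^-1), >= 0.
#' @return recovery fraction(s) in [0, 1).
#' @export
frap_model <- function(t, phi, k_diff, k_reac) {
  stopifnot(all(t >= 0), phi >= 0, phi <= 1, k_diff >= 0, k_reac >= 0)
  arg <- ifelse(t > 0 & k_diff > 0, 1 / (2 * sqrt(k_diff * t)), Inf)
  diffusive <- 1 - erf(arg)
  reactive <- 1 - exp(-k_reac * t)
  phi * diffusive + (1 - phi) * reactive
}

#' Normalize a raw FRAP trace
#'
#' Subtracts the post-bleach value and divides by the bleach depth
#' (baseline minus post-bleach), mapping the baseline to 1 and the bleach
#' point to 0. When an unbleached control trace is provided it is first
#' normalized to its own baseline and divided out point-wise, correcting
#' observational photobleaching.
#'
#' @param times time points (min) of the raw trace; the bleach time is
#'   `times[bleach_index]`.
#' @param raw raw intensities of the bleached region.
#' @param bleach_index index of the first post-bleach point; at least 3
#'   pre-bleach points are required before it.
#' @param control optional raw intensities of an unbleached control region,
#'   same length.
#' @return a [frap_trace()] starting at the bleach (time rebased to 0).
#' @export
normalize_trace <- function(times, raw, bleach_index, control = NULL) {
  stopifnot(length(times) == length(raw), bleach_index >= 4,
            bleach_index <= length(raw))
  pre <- seq_len(bleach_index - 1)
  if (!is.null(control)) {
    stopifnot(length(control) == length(raw))
    raw <- raw / (control / mean(control[pre]))
  }
  baseline <- mean(raw[pre])
  post <- raw[bleach_index]
  if (baseline <= post) stop("no bleach depth: baseline <= post-bleach value")
  sel <- bleach_index:length(raw)
  frap_trace(times[sel] - times[bleach_index],
             (raw[sel] - post) / (baseline - post))
}

#' Fit the diffusion-reaction model to a FRAP trace
#'
#' Nonlinear least squares over `(phi, k_reac)` with `k_diff` held fixed at
#' `D / r^2` (converted to min^-1), following the two-free-parameter
#' procedure in which the free diffusion coefficient is taken from
#' single-molecule tracking rather than fitted. Multi-start optimization
#' (seeded) guards against the shallow trade-off between `phi` and `k_reac`
#' on short traces. The synaptic enrichment is reported as `1 / phi` (all
#' molecules, bound plus free, over free molecules).
#'
#' @param trace a [frap_trace()] with at least 8 points.
#' @param D free diffusion coefficient (um^2/s), fixed.
#' @param r bleach-spot radius (um).
#' @param n_starts number of optimization starts (default 5).
#' @param seed RNG seed for the starts.
#' @return list of class `frap_fit`: `phi`, `k_reac` (min^-1), `k_diff`
#'   (min^-1), `D`, `r`, `enrichment` = 1/phi, `rss`, `n_starts`,
#'   `k_reac_identifiable` (FALSE when the bound pool is too small for
#'   `k_reac` to move the residuals).
#' @export
fit_frap <- function(trace, D = 0.1, r = 0.5, n_starts = 5, seed = 1) {
  stopifnot(inherits(trace, "frap_trace"), nrow(trace) >= 8, D > 0, r > 0)
  k_diff <- D * 60 / r^2           # um^2/s over um^2, in min^-1
  t <- trace$time_min
  yv <- trace$intensity
  resid_fn <- function(par) frap_model(t, par[1], k_diff, par[2]) - yv
  starts <- with_seed(stage_seed(seed, "fit_frap"), {
    cbind(phi = runif(n_starts, 0.05, 0.95),
          k_reac = 10^runif(n_starts, -3, 0))
  })
  starts[1, ] <- c(0.5, 0.01)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = resid_fn,
                         lower = c(0, 0), upper = c(1, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info < 1 || fit$info > 4) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("FRAP fit failed to converge from any start")
  phi <- best$par[[1]]
  k_reac <- best$par[[2]]
  # k_reac is unidentifiable when the bound pool is (numerically) absent:
  # doubling k_reac must change the residual sum of squares appreciably
  rss <- best$deviance
  rss2 <- sum(resid_fn(c(phi, max(k_reac * 2, 1e-6)))^2)
  identifiable <- (1 - phi) > 1e-3 &&
    abs(rss2 - rss) > 1e-9 * max(1, rss)
  structure(list(phi = phi, k_reac = k_reac, k_diff = k_diff, D = D, r = r,
                 enrichment = if (phi > 0) 1 / phi else Inf,
                 rss = rss, n_starts = n_starts,
                 k_reac_identifiable = identifiable),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "FRAP fit: phi = %.3f, k_reac = %.3g /min (k_diff fixed %.3g /min)\n",
    x$phi, x$k_reac, x$k_diff))
  cat(sprintf("synaptic enrichment 1/phi = %.2f%s\n", x$enrichment,
              if (x$k_reac_identifiable) "" else "  [k_reac unidentifiable]"))
  invisible(x)
}

#' Synaptic enrichment from the free fraction
#'
#' Total (bound + free) over free molecules: `1 / phi`.
#'
#' @param phi free fraction in (0, 1].
#' @return enrichment ratio.
#' @export
enrichment_from_phi <- function(phi) {
  stopifnot(phi > 0, phi <= 1)
  1 / phi
}
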