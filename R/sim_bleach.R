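# Synthetic single-cluster photobleaching staircases.

#' Parameters for the synthetic photobleaching-staircase generator
#'
#' A cluster of `n_fluor` fluorophores is imaged until all of them have
#' bleached. Each fluorophore bleaches independently with a per-frame hazard
#' `bleach_rate`; the trace intensity is the number of surviving fluorophores
#' times `step`, plus Gaussian noise. Bleach frames are drawn distinct
#' (collisions redrawn) so that the ground-truth step count is observable as
#' the number of downward discontinuities, and conditioned to fall inside the
#' trace, emulating traces that are followed until the cluster is dark.
#'
#' @param n_fluor Number of fluorophores (integer >= 0).
#' @param step Intensity contribution of one fluorophore (a.u., > 0).
#' @param bleach_rate Per-fluorophore, per-frame bleaching probability hazard.
#' @param noise_sd Gaussian noise sd (a.u.).
#' @param frames Trace length in frames.
#' @param min_gap Minimum separation (frames) between consecutive bleach
#'   events and before the first one. Default 3. Events closer than this
#'   merge into a single observable discontinuity, making the ground-truth
#'   count unidentifiable from the trace; the constraint emulates selecting
#'   traces with resolvable steps, as done when counting steps manually.
#' @param seed Optional integer seed.
#' @return An object of class `bleach_sim_params`.
#' @export
bleach_sim_params <- function(n_fluor = 6L,
                              step = 1,
                              bleach_rate = 0.02,
                              noise_sd = 0.2,
                              frames = 400L,
                              min_gap = 3L,
                              seed = NULL) {
  assert_that(n_fluor >= 0, "n_fluor must be >= 0")
  assert_that(step > 0, "step must be > 0")
  assert_that(bleach_rate > 0 && bleach_rate < 1, "bleach_rate must be in (0,1)")
  assert_that(frames >= 10, "frames must be >= 10")
  assert_that(min_gap >= 1, "min_gap must be >= 1")
  assert_that(frames > (n_fluor + 1L) * min_gap, "frames too short for n_fluor events min_gap apart")
  structure(list(n_fluor = as.integer(n_fluor), step = step,
                 bleach_rate = bleach_rate, noise_sd = noise_sd,
                 frames = as.integer(frames), min_gap = as.integer(min_gap),
                 seed = seed),
            class = "bleach_sim_params")
}

#' Simulate a photobleaching staircase trace
#'
#' @param params A [bleach_sim_params()] object.
#' @return A list with `trace` (numeric vector, one intensity per frame) and
#'   `truth` (list: `n_fluor`, sorted `bleach_frames` — the first frame at
#'   which each fluorophore is dark — and `step`).
#' @export
simulate_bleach_trace <- function(params) {
  stopifnot(inherits(params, "bleach_sim_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  # geometric bleach frames (first dark frame), conditioned to lie inside the
  # trace with at least min_gap frames before the first event and between
  # consecutive events
  times <- integer(0)
  if (p$n_fluor > 0) {
    repeat {
      cand <- sort(stats::rgeom(p$n_fluor, p$bleach_rate) + 2L)
      if (all(cand <= p$frames) && cand[1] > p$min_gap &&
          (p$n_fluor == 1L || all(diff(cand) >= p$min_gap))) { times <- cand; break }
    }
  }
  # fluorophores still fluorescent at frame f: first dark frame > f
  alive <- vapply(seq_len(p$frames), function(f) sum(times > f), numeric(1))
  trace <- alive * p$step + rnorm(p$frames, 0, p$noise_sd)
  list(trace = trace,
       truth = list(n_fluor = p$n_fluor, bleach_frames = times, step = p$step))
}
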