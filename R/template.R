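#' ERP component template
#'
#' The synthetic generator models each ERP component as a Gaussian bump in
#' time: amplitude per channel times `exp(-(t - peak)^2 / (2 * sd^2))` with
#' `sd = width / 2.355` (width is full width at half maximum). A template
#' holds one component set per stimulus class plus additive condition
#' effects per (component, channel, condition).
#'
#' @param components Data frame with columns `class`, `component`,
#'   `peak_ms`, `width_ms`, and one amplitude column (microvolts) per
#'   channel in `channels`.
#' @param channels Channel names; must all be present as columns.
#' @param condition_effects Data frame with columns `component`, `channel`,
#'   `condition`, `offset_uV`; offsets are added to the named component's
#'   amplitude at the named channel for that condition (all classes).
#' @return An object of class `erp_template`.
#' @seealso [default_erp_template()], [template_signal()]
#' @export
erp_template <- function(components, channels = POSTURE_CHANNELS,
                         condition_effects = NULL) {
  stopifnot(all(c("class", "component", "peak_ms", "width_ms") %in% names(components)),
            all(channels %in% names(components)))
  if (any(components$width_ms <= 0)) stop("component widths must be > 0")
  if (any(components$peak_ms < 0 | components$peak_ms > 800)) {
    stop("component peak latencies must lie in [0, 800] ms")
  }
  if (is.null(condition_effects)) {
    condition_effects <- data.frame(component = character(0), channel = character(0),
                                    condition = character(0), offset_uV = numeric(0))
  }
  structure(list(components = components, channels = channels,
                 condition_effects = condition_effects),
            class = "erp_template")
}

#' Default oddball ERP template
#'
#' Component sequence and topographies emulating an auditory oddball: an
#' early P1, a fronto-central auditory N1 near 100 ms, a P2 near 175 ms, an
#' N2, and a P3 whose topography depends on the stimulus class -- a parietal
#' P3b (maximal at Pz/CPz) for frequent and rare tones, larger for the rare
#' targets, and a frontal P3a (maximal at Fz/FCz) for novel sounds.
#'
#' The postural condition effect is modeled as a gain change of the P3b
#' generator: additive offsets on the standing P3 amplitude at every
#' channel, proportional to the canonical P3b topography (the rare-tone P3
#' amplitudes normalized to Pz), so that `p3b_effect_uV` is exactly the
#' ground-truth standing-minus-sitting P3b difference at Pz and the other
#' channels shift in proportion to their P3b loading -- a scalp-wide
#' modulation of one component rather than an isolated single-electrode
#' change.
#'
#' @param p3b_effect_uV Standing minus sitting P3b amplitude difference at
#'   Pz, microvolts (negative = attenuated while standing).
#' @return An `erp_template`.
#' @examples
#' tpl <- default_erp_template(p3b_effect_uV = -0.7)
#' tpl$condition_effects
#' @export
default_erp_template <- function(p3b_effect_uV = -0.7) {
  amp <- function(...) c(...)
  # columns follow POSTURE_CHANNELS: Fz FCz Cz CPz Pz Oz Fpz Fp1
  rows <- list(
    list("frequent", "P1",  50,  40, amp(0.5, 0.6, 0.8, 0.7, 0.6, 0.4, 0.3, 0.3)),
    list("frequent", "N1", 100,  70, amp(-3.5, -4.0, -4.0, -3.0, -2.5, -1.0, -2.0, -2.0)),
    list("frequent", "P2", 175,  90, amp(2.5, 3.0, 3.0, 2.5, 2.0, 1.0, 1.5, 1.5)),
    list("frequent", "N2", 240,  80, amp(-1.5, -1.5, -1.2, -1.0, -0.8, -0.4, -0.8, -0.8)),
    list("frequent", "P3", 400, 280, amp(0.5, 0.8, 1.2, 1.7, 2.0, 0.8, 0.3, 0.3)),
    list("rare",     "P1",  50,  40, amp(0.5, 0.6, 0.8, 0.7, 0.6, 0.4, 0.3, 0.3)),
    list("rare",     "N1", 100,  70, amp(-3.5, -4.0, -4.0, -3.0, -2.5, -1.0, -2.0, -2.0)),
    list("rare",     "P2", 175,  90, amp(2.5, 3.0, 3.0, 2.5, 2.0, 1.0, 1.5, 1.5)),
    list("rare",     "N2", 240,  80, amp(-2.5, -2.5, -2.0, -1.5, -1.2, -0.6, -1.2, -1.2)),
    list("rare",     "P3", 450, 300, amp(2.0, 3.0, 5.0, 7.0, 8.0, 3.0, 1.0, 1.0)),
    list("novelty",  "P1",  50,  40, amp(0.5, 0.6, 0.8, 0.7, 0.6, 0.4, 0.3, 0.3)),
    list("novelty",  "N1", 100,  70, amp(-3.5, -4.0, -4.0, -3.0, -2.5, -1.0, -2.0, -2.0)),
    list("novelty",  "P2", 175,  90, amp(2.5, 3.0, 3.0, 2.5, 2.0, 1.0, 1.5, 1.5)),
    list("novelty",  "N2", 240,  80, amp(-2.0, -2.0, -1.6, -1.2, -1.0, -0.5, -1.0, -1.0)),
    list("novelty",  "P3", 380, 250, amp(7.0, 6.5, 5.0, 3.5, 2.5, 1.0, 3.0, 3.0))
  )
  components <- do.call(rbind, lapply(rows, function(r) {
    out <- data.frame(class = r[[1]], component = r[[2]], peak_ms = r[[3]],
                      width_ms = r[[4]], stringsAsFactors = FALSE)
    out[POSTURE_CHANNELS] <- as.list(r[[5]])
    out
  }))
  p3b_topo <- as.numeric(components[components$class == "rare" &
                                      components$component == "P3",
                                    POSTURE_CHANNELS])
  effects <- data.frame(
    component = "P3",
    channel = POSTURE_CHANNELS,
    condition = "standing",
    offset_uV = p3b_effect_uV * p3b_topo / p3b_topo[POSTURE_CHANNELS == "Pz"],
    stringsAsFactors = FALSE
  )
  erp_template(components, POSTURE_CHANNELS, effects)
}

#' Evaluate a template as a channel-by-time signal
#'
#' Sums the Gaussian bumps of one stimulus class, with condition effects
#' applied and the P3 amplitudes scaled by a participant-specific gain.
#' Times before stimulus onset (t < 0) evaluate the same bumps (their tails
#' are effectively zero there for the default latencies).
#'
#' @param template An [erp_template()].
#' @param class Stimulus class.
#' @param condition Condition label (matched against `condition_effects`).
#' @param times_ms Times at which to evaluate, ms relative to onset.
#' @param p3_gain Multiplicative gain applied to P3 amplitudes before the
#'   additive condition offset (models between-subject P3 variability).
#' @return Matrix `channels x length(times_ms)` in microvolts.
#' @export
template_signal <- function(template, class, condition, times_ms, p3_gain = 1) {
  comp <- template$components[template$components$class == class, , drop = FALSE]
  if (nrow(comp) == 0) stop("template has no components for class ", class)
  chans <- template$channels
  out <- matrix(0, length(chans), length(times_ms),
                dimnames = list(chans, NULL))
  eff <- template$condition_effects
  for (i in seq_len(nrow(comp))) {
    a <- as.numeric(comp[i, chans])
    if (comp$component[i] == "P3") a <- a * p3_gain
    sel <- eff$component == comp$component[i] & eff$condition == condition
    if (any(sel)) {
      idx <- match(eff$channel[sel], chans)
      a[idx] <- a[idx] + eff$offset_uV[sel]
    }
    s <- comp$width_ms[i] / 2.355
    bump <- exp(-((times_ms - comp$peak_ms[i])^2) / (2 * s^2))
    out <- out + outer(a, bump)
  }
  out
}
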