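# Classifier operationalization constants. The pattern taxonomy itself
# (RS/PS/TS/MMO/SWB/PPB) is standard; these numeric thresholds are this
# package's documented operationalization of it and are exposed as
# arguments of classifyPattern().
PATTERN_DEFAULTS <- list(
  osc_prominence_mV = 1,     # minimal prominence of a sub-threshold maximum
  osc_ceiling_mV = -20,      # sub-threshold maxima must peak below this
  osc_separation_ms = 2,     # minimal separation between oscillation peaks
  spike_mask_ms = 3,         # half-width of the mask around spike peaks
  intra_burst_isi_ms = 25,   # ISI within a spike group
  silent_gap_factor = 3,     # silent phase: gap > factor x median ISI ...
  silent_gap_min_ms = 50,    # ... and longer than this floor
  mmo_min_oscillations = 3,  # inter-spike oscillations needed for MMO
  plateau_level_mV = -20,    # supra-threshold plateau level
  plateau_min_ms = 20,       # minimal plateau duration (PPB)
  short_window_ms = 500,     # short-term response window
  long_window_ms = 1000      # long-term response window
)

#' Detect sub-threshold oscillations
#'
#' Local voltage maxima that are not action potentials: samples within
#' `spike_mask_ms` of a spike peak are masked out, and the remaining local
#' maxima must have prominence of at least `prominence_mV`, peak below
#' `ceiling_mV`, and be at least `separation_ms` apart.
#'
#' @param trace a `sim_trace`.
#' @param spikes optional `spike_features`; computed if NULL.
#' @param prominence_mV,ceiling_mV,separation_ms,spike_mask_ms detection
#'   parameters (defaults: 1 mV, -20 mV, 2 ms, 3 ms).
#' @return Data frame `t_ms`, `V_mV`, `prominence` of oscillation peaks.
#' @export
detectSubthresholdOscillations <- function(trace, spikes = NULL,
                                           prominence_mV = PATTERN_DEFAULTS$osc_prominence_mV,
                                           ceiling_mV = PATTERN_DEFAULTS$osc_ceiling_mV,
                                           separation_ms = PATTERN_DEFAULTS$osc_separation_ms,
                                           spike_mask_ms = PATTERN_DEFAULTS$spike_mask_ms) {
  if (is.null(spikes)) spikes <- detectSpikes(trace)
  t <- trace$t_ms
  V <- trace$V_mV
  masked <- rep(FALSE, length(t))
  for (ts in spikes$spike_times)
    masked[t >= ts - spike_mask_ms & ts + spike_mask_ms >= t] <- TRUE
  # candidate local maxima (strict on the left, non-strict on the right so
  # flat-topped sampled maxima register once)
  dV <- diff(V)
  cand <- which(c(FALSE, dV > 0) & c(dV <= 0, FALSE))
  cand <- cand[!masked[cand] & V[cand] < ceiling_mV]
  if (!length(cand))
    return(data.frame(t_ms = numeric(0), V_mV = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(cand, function(i) peak_prominence(V, i), numeric(1))
  keep <- prom >= prominence_mV
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) > 1) {
    sel <- logical(length(cand))
    last_t <- -Inf
    for (i in seq_along(cand)) {
      if (t[cand[i]] - last_t >= separation_ms) {
        sel[i] <- TRUE
        last_t <- t[cand[i]]
      }
    }
    cand <- cand[sel]
    prom <- prom[sel]
  }
  data.frame(t_ms = t[cand], V_mV = V[cand], prominence = prom)
}

# Topographic prominence of a local maximum: height above the higher of the
# two saddle minima separating it from the nearest higher ground.
peak_prominence <- function(V, i) {
  v <- V[i]
  left <- if (i > 1) V[seq_len(i - 1)] else numeric(0)
  right <- if (i < length(V)) V[seq.int(i + 1, length(V))] else numeric(0)
  saddle <- function(side) {
    if (!length(side)) return(-Inf)
    higher <- which(side > v)
    if (length(higher)) min(side[seq_len(min(higher))]) else min(side)
  }
  v - max(saddle(rev(left)), saddle(right))
}

#' Classify the spiking pattern of a voltage trace
#'
#' Assigns one of six labels based on short- (< 500 ms) and long-term
#' (> 1000 ms) responses to a constant current step:
#' \describe{
#'   \item{RS}{resting state: at most one spike (at stimulus onset).}
#'   \item{PS}{phasic spiking: several spikes, all within the first 500 ms
#'     and none after 1000 ms.}
#'   \item{TS}{tonic spiking: sustained spiking not matching any pattern
#'     below (the fallback label).}
#'   \item{MMO}{mixed-mode oscillations: spikes interleaved with
#'     sub-threshold oscillations (at least `mmo_min_oscillations`
#'     oscillations falling between consecutive spikes) without a bursting
#'     silent phase.}
#'   \item{SWB}{square-wave bursting: spike groups (intra-group ISI < 25 ms,
#'     at least two groups of two or more spikes) separated by at least one
#'     oscillation-filled silent phase (a gap exceeding both 3x the median
#'     ISI and 50 ms).}
#'   \item{PPB}{pseudo-plateau bursting: any depolarized plateau, i.e. a
#'     contiguous excursion above -20 mV lasting at least 20 ms (pituitary-
#'     or cardiac-type events; the subtype is reported as evidence).}
#' }
#' Rules are applied in priority order PPB, RS, PS, SWB, MMO, TS. All
#' numeric thresholds are exposed via `opts`.
#'
#' @param trace a `sim_trace` covering at least 1500 ms of stimulation.
#' @param stim_window `c(start, end)` ms of the stimulation; defaults to the
#'   trace protocol.
#' @param opts list of classifier constants (see `PATTERN_DEFAULTS`).
#' @return A `pattern_label` list: `label`, `evidence` (spike counts in the
#'   short/long windows, oscillation count, burst structure, plateau
#'   fraction and subtype), `warning` (character, possibly empty).
#' @export
classifyPattern <- function(trace, stim_window = NULL,
                            opts = PATTERN_DEFAULTS) {
  opts <- utils::modifyList(PATTERN_DEFAULTS, opts)
  if (is.null(stim_window)) {
    proto <- attr(trace, "protocol")
    stim_window <- if (!is.null(proto))
      c(proto$onset, proto$onset + proto$duration) else range(trace$t_ms)
  }
  if (diff(stim_window) < 1500 - 1e-9)
    stop("classification requires at least 1500 ms of stimulation")
  spikes <- detectSpikes(trace, window = stim_window)
  osc <- detectSubthresholdOscillations(trace, spikes,
                                        prominence_mV = opts$osc_prominence_mV,
                                        ceiling_mV = opts$osc_ceiling_mV,
                                        separation_ms = opts$osc_separation_ms,
                                        spike_mask_ms = opts$spike_mask_ms)
  st <- spikes$spike_times
  rel <- st - stim_window[1]

  # plateau events: contiguous time above the plateau level
  above <- trace$V_mV > opts$plateau_level_mV
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dur <- trace$t_ms[ends] - trace$t_ms[starts]
  plat <- which(r$values & dur >= opts$plateau_min_ms)
  plateau_ms <- sum(dur[plat])
  plateau_fraction <- plateau_ms / diff(stim_window)

  evidence <- list(
    n_spikes = spikes$n_spikes,
    n_spikes_short = sum(rel <= opts$short_window_ms),
    n_spikes_late = sum(rel > opts$long_window_ms),
    n_oscillations = nrow(osc),
    firing_rate = spikes$firing_rate,
    plateau_fraction = plateau_fraction,
    plateau_events = length(plat),
    burst_sizes = integer(0),
    ppb_subtype = NA_character_)
  warn <- character(0)

  label <- if (length(plat) > 0) {
    # pituitary-type plateaus carry supra-threshold oscillations on the
    # decaying plateau; cardiac-type are smooth with a sharp leading spike
    osc_high <- detectSubthresholdOscillations(
      trace, spikes, prominence_mV = opts$osc_prominence_mV,
      ceiling_mV = Inf, separation_ms = opts$osc_separation_ms,
      spike_mask_ms = opts$spike_mask_ms)
    n_high <- sum(osc_high$V_mV > opts$plateau_level_mV)
    evidence$ppb_subtype <- if (n_high >= 3) "pituitary" else "cardiac"
    "PPB"
  } else if (spikes$n_spikes <= 1) {
    "RS"
  } else if (evidence$n_spikes_late == 0 &&
             evidence$n_spikes_short == spikes$n_spikes) {
    "PS"
  } else {
    isi <- diff(st)
    groups <- cumsum(c(0, isi > opts$intra_burst_isi_ms))
    sizes <- as.integer(table(groups))
    evidence$burst_sizes <- sizes
    osc_between <- function(t0, t1) sum(osc$t_ms > t0 & osc$t_ms < t1)
    n_inter_osc <- sum(vapply(seq_along(isi), function(g)
      osc_between(st[g], st[g + 1]), numeric(1)))
    evidence$n_inter_spike_oscillations <- n_inter_osc
    silent_len <- max(opts$silent_gap_factor * stats::median(isi),
                      opts$silent_gap_min_ms)
    silent <- which(isi > silent_len)
    silent_with_osc <- silent[vapply(silent, function(g)
      osc_between(st[g], st[g + 1]) >= 1, logical(1))]
    evidence$n_silent_phases <- length(silent_with_osc)
    if (sum(sizes >= 2) >= 2 && length(silent_with_osc) >= 1) {
      "SWB"
    } else if (n_inter_osc >= opts$mmo_min_oscillations) {
      "MMO"
    } else {
      "TS"
    }
  }
  structure(list(label = label, evidence = evidence, warning = warn),
            class = "pattern_label")
}

#' @export
print.pattern_label <- function(x, ...) {
  cat(sprintf("Spiking pattern: %s (%d spikes, %d sub-threshold oscillations",
              x$label, x$evidence$n_spikes, x$evidence$n_oscillations))
  if (!is.na(x$evidence$ppb_subtype))
    cat(", ", x$evidence$ppb_subtype, "-type", sep = "")
  cat(")\n")
  invisible(x)
}

#' Phase-transition diagram over an (input current, eta) grid
#'
#' Simulates the hybrid model at every (I, eta) grid cell for `duration` ms
#' and classifies the spiking pattern. Cells where the fractional gate
#' diverges receive the distinct label `"UNST"` (first-class output, not a
#' silent gap).
#'
#' @param gate fractional gate, `"n"`, `"m"` or `"h"`.
#' @param I_values current grid, default 0 to 20 by 1 nA.
#' @param eta_values order grid, default 0.2 to 1.0 by 0.1.
#' @param duration stimulation length (ms), default 1500.
#' @param dt integration step (ms).
#' @param params `hhParams()`.
#' @param opts classifier constants, see [classifyPattern()].
#' @return A `phase_diagram`: list with `labels` (matrix I x eta), `I`,
#'   `eta`, `gate`, and `evidence` (list-matrix).
#' @export
sweepPhaseDiagram <- function(gate, I_values = seq(0, 20, by = 1),
                              eta_values = seq(0.2, 1, by = 0.1),
                              duration = 1500, dt = 0.01,
                              params = hhParams(), opts = PATTERN_DEFAULTS) {
  gate <- match.arg(gate, c("n", "m", "h"))
  labels <- matrix(NA_character_, nrow = length(I_values),
                   ncol = length(eta_values),
                   dimnames = list(I = as.character(I_values),
                                   eta = as.character(eta_values)))
  evidence <- vector("list", length(labels))
  dim(evidence) <- dim(labels)
  proto <- stepCurrentProtocol(0, onset = 0, duration = duration)
  for (j in seq_along(eta_values)) {
    fc <- fractionalConfig(gate, eta = eta_values[j], dt = dt)
    for (i in seq_along(I_values)) {
      proto$amplitude <- I_values[i]
      res <- tryCatch({
        tr <- simulateHybrid(params, fc, proto)
        classifyPattern(tr, opts = opts)
      }, frachh_divergence = function(e)
        structure(list(label = "UNST",
                       evidence = list(message = conditionMessage(e)),
                       warning = character(0)),
                  class = "pattern_label"))
      labels[i, j] <- res$label
      evidence[[i, j]] <- res$evidence
    }
  }
  structure(list(gate = gate, I = I_values, eta = eta_values,
                 labels = labels, evidence = evidence, duration = duration,
                 dt = dt),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Spiking-pattern phase diagram, fractional %s gate (%g ms, dt = %g ms)\n",
              x$gate, x$duration, x$dt))
  print(x$labels)
  invisible(x)
}
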