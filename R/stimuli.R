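# Stimulation protocols and forcing terms --------------------------------

#' Build an STDP pairing protocol
#'
#' Generates the pre- and postsynaptic event times of a pairing protocol.
#' The spike timing follows the convention
#' `dt_stdp = t_post + delta - t_pre` (in ms), where `delta` is the delay
#' from the onset of the somatic depolarization step to the peak of the
#' back-propagating action potential: negative timings mean the
#' postsynaptic event precedes the presynaptic one (post-pre pairing).
#'
#' @param n_pairings number of pairings (>= 1).
#' @param dt_stdp spike timing in ms (ignored for non-paired protocols).
#' @param frequency pairing frequency in Hz.
#' @param kind `"paired"`, `"pre-only"` or `"post-only"`.
#' @param delta bAP delay in seconds (taken from the parameter set).
#' @param start time of the first presynaptic anchor event (s).
#' @return object of class `stdp_protocol` with fields `pre_times`,
#'   `post_times` (s), `dt_stdp`, `n_pairings`, `frequency`, `kind`.
#' @export
#' @examples
#' pr <- build_stdp_protocol(10, -15, 1)
#' diff(pr$pre_times)[1]                        # 1 s spacing at 1 Hz
#' (pr$post_times[1] + 0.003 - pr$pre_times[1]) * 1000  # -15 ms
build_stdp_protocol <- function(n_pairings, dt_stdp = 0, frequency = 1,
                                kind = c("paired", "pre-only", "post-only"),
                                delta = default_parameters()$delta,
                                start = 1) {
  kind <- match.arg(kind)
  if (n_pairings < 1) stop("n_pairings must be >= 1")
  if (frequency <= 0) stop("frequency must be positive")
  if (kind == "paired" && abs(dt_stdp) >= 1000 / frequency / 2)
    stop("|dt_stdp| = ", abs(dt_stdp),
         " ms is too large for the pairing period at ", frequency, " Hz")
  anchors <- start + (seq_len(n_pairings) - 1) / frequency
  pre <- post <- numeric(0)
  if (kind != "post-only") pre <- anchors
  if (kind != "pre-only") {
    if (kind == "post-only") post <- anchors
    else post <- anchors + dt_stdp / 1000 - delta
  }
  shift <- min(c(pre, post))
  if (shift < 0.1) { pre <- pre + (0.1 - shift); post <- post + (0.1 - shift) }
  structure(list(pre_times = pre, post_times = post,
                 dt_stdp = if (kind == "paired") dt_stdp else NA_real_,
                 n_pairings = n_pairings, frequency = frequency, kind = kind),
            class = "stdp_protocol")
}

#' Cleft glutamate concentration
#'
#' Sum over presynaptic spikes of single-exponential transients with peak
#' `G_max` and clearance time `tau_G`.
#'
#' @param t time(s) in seconds (vectorised).
#' @param protocol an `stdp_protocol`.
#' @param ps parameter set.
#' @return glutamate concentration (mM).
#' @export
glutamate_concentration <- function(t, protocol, ps) {
  vapply(t, function(tt) {
    dt <- tt - protocol$pre_times
    ps$G_max * sum(exp(-dt[dt >= 0] / ps$tau_G))
  }, numeric(1))
}

#' Postsynaptic action current
#'
#' Sum of the box-shaped step-depolarization current (amplitude `DC_max`,
#' duration `DC_dur`) and the bAP transient (amplitude `AP_max`, onset
#' `delta` after the step onset, exponential decay `tau_bAP`). Negative
#' values depolarize, mirroring the sign convention of the membrane
#' equation.
#'
#' @inheritParams glutamate_concentration
#' @return current in pA (vectorised over `t`).
#' @export
action_current <- function(t, protocol, ps) {
  vapply(t, function(tt) {
    d1 <- tt - protocol$post_times
    dc <- sum(d1 >= 0 & d1 < ps$DC_dur)
    d2 <- d1 - ps$delta
    ap <- sum(exp(-d2[d2 >= 0] / ps$tau_bAP))
    -ps$DC_max * dc - ps$AP_max * ap
  }, numeric(1))
}

# boundary times at which the forcing terms are non-smooth
.protocol_breaks <- function(protocol, ps) {
  sort(unique(c(protocol$pre_times,
                protocol$post_times,
                protocol$post_times + ps$delta,
                protocol$post_times + ps$DC_dur)))
}

#' @export
print.stdp_protocol <- function(x, ...) {
  cat("<stdp_protocol> ", x$kind, ", N = ", x$n_pairings,
      if (!is.na(x$dt_stdp)) paste0(", dt = ", x$dt_stdp, " ms"),
      ", f = ", x$frequency, " Hz\n", sep = "")
  invisible(x)
}
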