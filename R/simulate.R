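# Simulation engine -------------------------------------------------------

.sim_env <- new.env(parent = emptyenv())

# pack parameters, CaMKII ring matrices and event times for the C side
.pack_parms <- function(ps, protocol = NULL) {
  reg <- .param_registry()
  vals <- unlist(ps[reg$name], use.names = FALSE)
  m <- camkii_transition_matrices()
  pre <- if (is.null(protocol)) numeric(0) else protocol$pre_times
  post <- if (is.null(protocol)) numeric(0) else protocol$post_times
  v <- c(length(vals), vals,
         as.numeric(m$A6), as.numeric(m$A7), as.numeric(m$A12), m$nphos,
         length(pre), pre, length(post), post)
  # the C side copies a fixed-size parameter block
  if (length(v) > 8192) stop("protocol too long for the compiled model")
  c(v, numeric(8192 - length(v)))
}

.initial_guess <- function(ps) {
  rest <- .camkii_rest_i1(ps, ps$Ca_b)
  # approximate resting IP3 (PLCdelta production vs IP-5P) and the ER level
  # that balances SERCA against IP3R + leak at basal calcium
  ip3 <- tryCatch(stats::uniroot(function(x)
    plc_production(ps$Ca_b, x, 0, ps) - ps$r_5P * x, c(0, 50))$root,
    error = function(e) 0.05)
  m_inf <- ip3 / (ip3 + ps$d1_IP3R)
  n_inf <- ps$Ca_b / (ps$Ca_b + ps$d5_IP3R)
  Q2 <- ps$d2_IP3R * (ip3 + ps$d1_IP3R) / (ip3 + ps$d3_IP3R)
  h_inf <- Q2 / (Q2 + ps$Ca_b)
  gate <- (m_inf * n_inf * h_inf)^3
  j_ser <- ps$v_SERCA * ps$Ca_b^2 / (ps$Ca_b^2 + ps$K_SERCA^2)
  er <- ps$Ca_b + j_ser / (ps$r_IP3R * gate + ps$r_leak)
  y <- c(V = ps$V_L, r_AMPA = 0, r_NMDA = 0,
         m_VSCC = 1 / (1 + exp(-(ps$V_L - ps$V_m_VSCC) / ps$k_m_VSCC)),
         h_VSCC = 1 / (1 + exp((ps$V_L - ps$V_h_VSCC) / ps$k_h_VSCC)),
         Ca = ps$Ca_b, Ca_ER = er, h_IP3R = h_inf, IP3 = ip3,
         DAG = 0.001, AG2 = 0.001, AEA = 0.02, phi_DAGL = 1e-4,
         x_CB1R = 0, d_CB1R = 0, W_pre = 1,
         I1P = rest$I1P, PP1 = rest$PP1)
  c(y, setNames(rep(0, 13), paste0("B", 1:13)))
}

.lsoda_c <- function(y, times, parms, ps) {
  out <- deSolve::lsoda(y, times, func = "ecbstdp_derivs", parms = parms,
                        dllname = "ecbstdp", initfunc = "ecbstdp_init",
                        nout = 1, rtol = ps$rtol, atol = ps$atol,
                        maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("integration failure near t = ", times[length(times)], " s",
         call. = FALSE)
  out
}

#' Resting state of the full model
#'
#' Finds the steady state of every variable in the absence of stimulation
#' by long stiff integration from a physiological initial guess, followed
#' by a residual check on the full right-hand side. With CaMKII in the
#' down state and `W_pre = 1` the resulting total weight is 1.
#'
#' @param ps parameter set.
#' @param t_relax relaxation horizon in s.
#' @param tol relative residual tolerance.
#' @return named state vector at rest.
#' @export
steady_state <- function(ps, t_relax = 5000, tol = 1e-9) {
  key <- paste(format(unlist(ps, use.names = FALSE), digits = 17),
               collapse = ",")
  cached <- .sim_env$steady[[key]]
  if (!is.null(cached)) return(cached)
  parms <- .pack_parms(ps, NULL)
  y <- .initial_guess(ps)
  yss <- y
  horizon <- t_relax
  for (pass in 1:4) {
    out <- .lsoda_c(yss, c(0, horizon / 4, horizon / 2, horizon), parms, ps)
    yss <- out[nrow(out), 1 + seq_along(y)]
    names(yss) <- .state_names
    dy <- model_rhs(horizon, yss, ps, NULL)
    rel <- abs(dy) / pmax(abs(yss), 1e-3)
    if (max(rel) <= tol) break
    horizon <- horizon * 4
  }
  if (max(rel) > tol)
    stop("steady state did not converge; largest residual on '",
         .state_names[which.max(rel)], "' (", signif(max(rel), 3), ")")
  if (is.null(.sim_env$steady)) .sim_env$steady <- list()
  .sim_env$steady[[key]] <- yss
  yss
}

#' Run a stimulation protocol
#'
#' Initializes the model at its unstimulated steady state, integrates the
#' stiff ODE system across the protocol with integrator restarts at every
#' stimulus discontinuity, continues for a settling horizon after the last
#' event, and reads out the final weights. Per-pairing peak amplitudes of
#' calcium, CB1R plasticity drive and active calmodulin are recorded along
#' the way.
#'
#' @param ps parameter set.
#' @param protocol an `stdp_protocol` (or `NULL` for no stimulation).
#' @param settle_time seconds simulated after the protocol before weights
#'   are read (default from `ps`).
#' @param record_dt trajectory sampling interval during the protocol (s);
#'   the settling phase is sampled at 0.25 s.
#' @param keep_trajectory set `FALSE` to drop the trajectory and keep only
#'   scalars and per-pairing peaks.
#' @param init_state optional named state vector used instead of the
#'   unstimulated steady state; used for acute enzyme manipulations that
#'   abolish the rest state (protocol applied right after the manipulation).
#' @return object of class `stdp_sim` with the trajectory (`data.frame`),
#'   per-pairing peak records, final `W_pre`, `W_post`, `W_total`, and the
#'   protocol/parameter provenance.
#' @export
#' @examples
#' \donttest{
#' ps <- default_parameters()
#' sim <- run_protocol(ps, build_stdp_protocol(2, -15, 1), settle_time = 5)
#' sim$W_total
#' }
run_protocol <- function(ps, protocol = NULL, settle_time = ps$settle_time,
                         record_dt = 0.002, keep_trajectory = TRUE,
                         init_state = NULL) {
  validate_parameters(ps)
  # acute manipulations (e.g. full MAGL block) may abolish the rest state;
  # such runs start from a supplied state, normally the control rest state
  y0 <- if (is.null(init_state)) steady_state(ps) else init_state[.state_names]
  parms <- .pack_parms(ps, protocol)
  if (is.null(protocol)) {
    t_end <- max(settle_time, 1)
    grid <- unique(c(seq(0, t_end, by = 0.25), t_end))
    out <- .lsoda_c(y0, grid, parms, ps)
    traj <- out[, 1 + c(0, seq_along(y0)), drop = FALSE]
  } else {
    breaks <- .protocol_breaks(protocol, ps)
    proto_end <- max(breaks) + 0.2
    t_end <- proto_end + settle_time
    dense <- seq(0, proto_end, by = record_dt)
    coarse <- seq(proto_end, t_end, by = 0.25)
    grid <- sort(unique(c(0, dense, breaks, coarse, t_end)))
    segs <- c(0, breaks[breaks > 0 & breaks < t_end], t_end)
    rows <- vector("list", length(segs) - 1)
    y <- y0
    for (k in seq_len(length(segs) - 1)) {
      tt <- grid[grid >= segs[k] & grid <= segs[k + 1]]
      tt <- unique(c(segs[k], tt, segs[k + 1]))
      tt <- tt[c(TRUE, diff(tt) > 1e-7)]          # collapse near-duplicates
      if (length(tt) < 2) tt <- c(segs[k], segs[k + 1])
      out <- .lsoda_c(y, tt, parms, ps)
      y <- out[nrow(out), 1 + seq_along(y0)]
      rows[[k]] <- out[-nrow(out), 1 + c(0, seq_along(y0)), drop = FALSE]
    }
    traj <- rbind(do.call(rbind, rows),
                  c(t_end, y))
  }
  colnames(traj) <- c("time", .state_names)
  traj <- as.data.frame(traj)
  yss <- as.numeric(traj[nrow(traj), -1]); names(yss) <- .state_names

  m <- camkii_transition_matrices()
  act_of <- function(df) as.matrix(df[paste0("B", 1:13)]) %*% m$nphos[-1]
  camkii_act <- drop(act_of(traj[nrow(traj), , drop = FALSE]))
  W_pre <- min(yss[["W_pre"]], ps$W_pre_max)
  W_post <- w_post(min(camkii_act, 6 * ps$CaMKII_T), ps)

  peaks <- NULL
  if (!is.null(protocol) && protocol$n_pairings >= 1) {
    anchors <- if (length(protocol$pre_times)) protocol$pre_times
               else protocol$post_times
    period <- 1 / protocol$frequency
    idx <- findInterval(traj$time, c(anchors, max(anchors) + period))
    keep <- idx >= 1 & idx <= length(anchors)
    yv <- ps$k_CB1R * traj$x_CB1R + ps$D_1
    cam <- vapply(traj$Ca, .cam_active, numeric(1), ps = ps)
    peaks <- data.frame(
      pairing = seq_along(anchors),
      Ca_peak = tapply(traj$Ca[keep], idx[keep], max),
      y_CB1R_peak = tapply(yv[keep], idx[keep], max),
      CaM_peak = tapply(cam[keep], idx[keep], max))
  }

  res <- structure(list(
    trajectory = if (keep_trajectory) traj else NULL,
    peaks = peaks,
    W_pre = unname(W_pre), W_post = unname(W_post),
    W_total = unname(W_pre * W_post),
    CaMKII_act = unname(camkii_act),
    settled = TRUE,
    protocol = protocol, parameters = ps,
    settle_time = settle_time), class = "stdp_sim")
  res
}

#' Relative weight changes of a settled simulation
#'
#' Expresses the final weights as percent of baseline (100 = no change),
#' mirroring the EPSC-amplitude convention of slice electrophysiology.
#'
#' @param result an `stdp_sim`.
#' @return named vector `dW_pre`, `dW_post`, `dW_total` in percent.
#' @export
weight_change <- function(result) {
  stopifnot(inherits(result, "stdp_sim"))
  if (!isTRUE(result$settled)) stop("simulation has not settled")
  c(dW_pre = 100 * result$W_pre,
    dW_post = 100 * result$W_post,
    dW_total = 100 * result$W_total)
}

#' @export
print.stdp_sim <- function(x, ...) {
  cat("<stdp_sim> ")
  if (!is.null(x$protocol))
    cat(x$protocol$kind, " N=", x$protocol$n_pairings,
        " dt=", x$protocol$dt_stdp, " ms f=", x$protocol$frequency, " Hz; ",
        sep = "")
  cat(sprintf("W_pre=%.3f W_post=%.3f W_total=%.3f (%.0f%%)\n",
              x$W_pre, x$W_post, x$W_total, 100 * x$W_total))
  invisible(x)
}

#' Export a simulation to CSV / JSON
#'
#' Writes the trajectory as CSV (one column per state variable, time in s)
#' and the scalar results plus resolved parameters as a JSON sidecar.
#'
#' @param result an `stdp_sim`.
#' @param basename output path without extension.
#' @return invisibly, the two file paths.
#' @export
export_simulation <- function(result, basename) {
  stopifnot(inherits(result, "stdp_sim"))
  csv <- paste0(basename, ".csv"); js <- paste0(basename, ".json")
  if (!is.null(result$trajectory))
    write.csv(result$trajectory, csv, row.names = FALSE)
  payload <- list(W_pre = result$W_pre, W_post = result$W_post,
                  W_total = result$W_total,
                  CaMKII_act = result$CaMKII_act,
                  protocol = if (!is.null(result$protocol))
                    unclass(result$protocol) else NULL,
                  parameters = unclass(result$parameters))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), js)
  invisible(c(csv, js))
}
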