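# Plasticity maps, knockout / inhibition experiments ----------------------

# steady state of the varied model, falling back to the control rest state
# when an acute manipulation (e.g. a full MAGL block) abolishes it
.variant_init <- function(ps_varied, ps_base) {
  tryCatch(steady_state(ps_varied), error = function(e) steady_state(ps_base))
}

#' Compute a (spike timing x number of pairings) plasticity map
#'
#' Runs one full protocol simulation per grid point and collects the final
#' pre-, post- and total synaptic weights. The experimental jitter of the
#' spike timing is emulated by convolving the `W_pre` and `W_post` layers
#' along the timing axis with a normalized Gaussian (s.d. `blur_sd` ms)
#' before recomposing their product.
#'
#' @param ps parameter set (the control model).
#' @param variant optional `ecb_variant` applied on top of `ps`.
#' @param dt_grid spike timings in ms (uniformly spaced for blurring).
#' @param n_grid numbers of pairings.
#' @param frequency pairing frequency (Hz).
#' @param settle_time settling horizon per run (s).
#' @param blur apply the Gaussian timing blur (default `TRUE`).
#' @return object of class `stdp_map` with raw and blurred weight layers
#'   (matrices `dt x n`).
#' @export
compute_map <- function(ps, variant = NULL, dt_grid, n_grid, frequency = 1,
                        settle_time = ps$settle_time, blur = TRUE) {
  if (!length(dt_grid) || !length(n_grid)) stop("grids must be non-empty")
  psv <- if (is.null(variant)) ps else apply_variant(ps, variant)
  init <- .variant_init(psv, ps)
  dims <- c(length(dt_grid), length(n_grid))
  Wpre <- Wpost <- matrix(NA_real_, dims[1], dims[2],
                          dimnames = list(dt_grid, n_grid))
  for (j in seq_along(n_grid)) for (i in seq_along(dt_grid)) {
    sim <- tryCatch(
      run_protocol(psv, build_stdp_protocol(n_grid[j], dt_grid[i], frequency,
                                            delta = psv$delta),
                   settle_time = settle_time, keep_trajectory = FALSE,
                   init_state = init),
      error = function(e) stop("solver failure at dt = ", dt_grid[i],
                               " ms, N = ", n_grid[j], ": ",
                               conditionMessage(e), call. = FALSE))
    Wpre[i, j] <- sim$W_pre; Wpost[i, j] <- sim$W_post
  }
  .finish_map(Wpre, Wpost, dt_grid, n_grid, axis2 = "n_pairings",
              frequency = frequency, variant = variant, ps = ps, blur = blur)
}

#' Compute a (spike timing x pairing frequency) plasticity map
#'
#' As [compute_map()] with the pairing frequency as second axis and a fixed
#' number of pairings.
#'
#' @inheritParams compute_map
#' @param f_grid pairing frequencies (Hz).
#' @param n_pairings number of pairings for every run.
#' @return an `stdp_map`.
#' @export
compute_frequency_map <- function(ps, variant = NULL, dt_grid, f_grid,
                                  n_pairings = 10,
                                  settle_time = ps$settle_time, blur = TRUE) {
  if (!length(dt_grid) || !length(f_grid)) stop("grids must be non-empty")
  psv <- if (is.null(variant)) ps else apply_variant(ps, variant)
  init <- .variant_init(psv, ps)
  Wpre <- Wpost <- matrix(NA_real_, length(dt_grid), length(f_grid),
                          dimnames = list(dt_grid, f_grid))
  for (j in seq_along(f_grid)) for (i in seq_along(dt_grid)) {
    sim <- run_protocol(psv,
                        build_stdp_protocol(n_pairings, dt_grid[i], f_grid[j],
                                            delta = psv$delta),
                        settle_time = settle_time, keep_trajectory = FALSE,
                        init_state = init)
    Wpre[i, j] <- sim$W_pre; Wpost[i, j] <- sim$W_post
  }
  .finish_map(Wpre, Wpost, dt_grid, f_grid, axis2 = "frequency",
              frequency = NA, variant = variant, ps = ps, blur = blur)
}

.finish_map <- function(Wpre, Wpost, dt_grid, ax2, axis2, frequency,
                        variant, ps, blur) {
  if (blur && length(dt_grid) > 1) {
    Wpre_b <- apply(Wpre, 2, gaussian_blur, dt_grid = dt_grid,
                    sd_ms = ps$blur_sd)
    Wpost_b <- apply(Wpost, 2, gaussian_blur, dt_grid = dt_grid,
                     sd_ms = ps$blur_sd)
    dim(Wpre_b) <- dim(Wpost_b) <- dim(Wpre)
    dimnames(Wpre_b) <- dimnames(Wpost_b) <- dimnames(Wpre)
  } else {
    Wpre_b <- Wpre; Wpost_b <- Wpost
  }
  structure(list(dt_grid = dt_grid, axis2 = axis2, axis2_values = ax2,
                 frequency = frequency,
                 W_pre = Wpre, W_post = Wpost, W_total = Wpre * Wpost,
                 W_pre_blur = Wpre_b, W_post_blur = Wpost_b,
                 W_total_blur = Wpre_b * Wpost_b,
                 blur_sd = ps$blur_sd, blurred = blur,
                 variant = variant), class = "stdp_map")
}

#' Gaussian blur along the spike-timing axis
#'
#' Discrete convolution of a vector sampled on a uniform timing grid with a
#' normalized Gaussian kernel (truncated at 4 s.d., edges reflected). A
#' constant vector is returned unchanged, and the kernel mass sums to one.
#'
#' @param w numeric vector of weights along the timing axis.
#' @param dt_grid timing grid (ms), uniformly spaced.
#' @param sd_ms kernel standard deviation in ms.
#' @return blurred vector of the same length.
#' @export
gaussian_blur <- function(w, dt_grid, sd_ms = 3) {
  if (length(w) != length(dt_grid)) stop("w and dt_grid lengths differ")
  if (length(w) == 1 || sd_ms <= 0) return(w)
  h <- diff(dt_grid)
  if (max(abs(h - h[1])) > 1e-8 * max(abs(h)))
    stop("dt_grid must be uniformly spaced for blurring")
  half <- max(1L, ceiling(4 * sd_ms / h[1]))
  kern <- exp(-0.5 * ((-half:half) * h[1] / sd_ms)^2)
  kern <- kern / sum(kern)
  n <- length(w)
  idx <- function(i) {                      # fold (reflect) at both edges
    j <- (i - 1) %% (2 * (n - 1))
    ifelse(j >= n - 1, 2 * (n - 1) - j, j) + 1
  }
  vapply(seq_len(n), function(i)
    sum(kern * w[idx(i + (-half:half))]), numeric(1))
}

#' Extract LTP / LTD domains from a plasticity map
#'
#' Thresholds the (blurred) total-weight layer at the given percent levels
#' and reports the connected regions (4-neighbour connectivity) with their
#' bounding boxes on both axes.
#'
#' @param map an `stdp_map`.
#' @param ltp_threshold percent level above which a point is potentiated.
#' @param ltd_threshold percent level below which a point is depressed.
#' @param blurred use the blurred layer (default) or the raw one.
#' @return data.frame with one row per domain: label, type, axis bounds and
#'   size; zero rows if the map is entirely within thresholds.
#' @export
extract_domain_boundaries <- function(map, ltp_threshold = 110,
                                      ltd_threshold = 90, blurred = TRUE) {
  stopifnot(inherits(map, "stdp_map"))
  if (!(ltd_threshold < 100 && ltp_threshold > 100))
    stop("thresholds must straddle 100 percent")
  W <- if (blurred) map$W_total_blur else map$W_total
  if (!length(W)) stop("empty map")
  lab <- matrix(0L, nrow(W), ncol(W))
  lab[100 * W > ltp_threshold] <- 1L
  lab[100 * W < ltd_threshold] <- -1L
  comp <- matrix(0L, nrow(W), ncol(W)); ncomp <- 0L
  out <- list()
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
    if (lab[i, j] == 0L || comp[i, j] != 0L) next
    ncomp <- ncomp + 1L
    queue <- list(c(i, j)); comp[i, j] <- ncomp
    cells <- matrix(c(i, j), 1)
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- cur[1] + d[1]; jj <- cur[2] + d[2]
        if (ii < 1 || jj < 1 || ii > nrow(W) || jj > ncol(W)) next
        if (comp[ii, jj] == 0L && lab[ii, jj] == lab[i, j]) {
          comp[ii, jj] <- ncomp
          queue <- c(queue, list(c(ii, jj)))
          cells <- rbind(cells, c(ii, jj))
        }
      }
    }
    out[[ncomp]] <- data.frame(
      domain = ncomp,
      type = if (lab[i, j] > 0) "LTP" else "LTD",
      dt_min = min(map$dt_grid[cells[, 1]]),
      dt_max = max(map$dt_grid[cells[, 1]]),
      axis2_min = min(map$axis2_values[cells[, 2]]),
      axis2_max = max(map$axis2_values[cells[, 2]]),
      n_points = nrow(cells))
  }
  if (!length(out))
    return(data.frame(domain = integer(), type = character(),
                      dt_min = numeric(), dt_max = numeric(),
                      axis2_min = numeric(), axis2_max = numeric(),
                      n_points = integer()))
  do.call(rbind, out)
}

#' Model-guided MAGL / DAG-kinase inhibition scenarios
#'
#' Reproduces the three in-silico enzyme-inhibition experiments: (i) 5
#' post-pre pairings, control versus MAGL fully blocked with DAG kinase at
#' 5 percent (amplification of endocannabinoid LTP); (ii) 50 post-pre
#' pairings, control versus MAGL at 40 percent (LTP uncovered inside the
#' no-plasticity gap); (iii) 100 presynaptic-only stimulations, control
#' versus MAGL 0 / DAGK 5 percent (LTP without postsynaptic activity).
#' Inhibited runs start from the control resting state (acute drug
#' application).
#'
#' @param ps parameter set.
#' @param dt_stdp spike timing for the paired scenarios (ms).
#' @param settle_time settling horizon per run (s).
#' @return data.frame with one row per scenario arm (percent weights).
#' @export
scenario_suite <- function(ps, dt_stdp = -15, settle_time = ps$settle_time) {
  init <- steady_state(ps)
  strong <- apply_variant(ps, model_variant(
    enzyme_scales = c(MAGL = 0, DAGK = 0.05)))
  mild <- apply_variant(ps, model_variant(enzyme_scales = c(MAGL = 0.4)))
  arms <- list(
    list("5 post-pre pairings", "control", ps, 5, "paired"),
    list("5 post-pre pairings", "MAGL 0% + DAGK 5%", strong, 5, "paired"),
    list("50 post-pre pairings", "control", ps, 50, "paired"),
    list("50 post-pre pairings", "MAGL 40%", mild, 50, "paired"),
    list("100 presynaptic only", "control", ps, 100, "pre-only"),
    list("100 presynaptic only", "MAGL 0% + DAGK 5%", strong, 100, "pre-only"))
  rows <- lapply(arms, function(a) {
    pr <- build_stdp_protocol(a[[4]], dt_stdp, 1, kind = a[[5]],
                              delta = a[[3]]$delta)
    sim <- run_protocol(a[[3]], pr, settle_time = settle_time,
                        keep_trajectory = FALSE, init_state = init)
    data.frame(scenario = a[[1]], condition = a[[2]],
               W_pre_pct = 100 * sim$W_pre, W_post_pct = 100 * sim$W_post,
               W_total_pct = 100 * sim$W_total)
  })
  do.call(rbind, rows)
}

#' Export a plasticity map to CSV (+ JSON sidecar)
#'
#' @param map an `stdp_map`.
#' @param basename output path without extension.
#' @return invisibly, the written file paths.
#' @export
export_map <- function(map, basename) {
  stopifnot(inherits(map, "stdp_map"))
  paths <- character(0)
  for (layer in c("W_total", "W_total_blur", "W_pre", "W_post")) {
    f <- paste0(basename, "_", tolower(layer), ".csv")
    write.csv(map[[layer]], f)
    paths <- c(paths, f)
  }
  side <- paste0(basename, ".json")
  meta <- list(axis1 = "dt_stdp_ms", dt_grid = map$dt_grid,
               axis2 = map$axis2, axis2_values = map$axis2_values,
               blur_sd_ms = map$blur_sd, blurred = map$blurred,
               variant = if (!is.null(map$variant)) unclass(map$variant))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), side)
  invisible(c(paths, side))
}

#' @export
print.stdp_map <- function(x, ...) {
  cat("<stdp_map> ", length(x$dt_grid), " timings x ",
      length(x$axis2_values), " ", x$axis2, " values; W_total in [",
      sprintf("%.2f", min(x$W_total)), ", ",
      sprintf("%.2f", max(x$W_total)), "]\n", sep = "")
  invisible(x)
}
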