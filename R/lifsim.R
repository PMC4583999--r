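#' Leaky integrate-and-fire neuron parameters
#'
#' @param tau membrane time constant, ms.
#' @param theta spike threshold, mV.
#' @param v_reset reset potential, mV.
#' @param t_ref absolute refractory period, ms. The default of 2 ms is the
#'   standard NEST integrate-and-fire value; it is irrelevant at the low
#'   (few-Hz) rates of the balanced regime but bounds the rate of a
#'   winner-take-all population at strong within-coupling. Set 0 to disable.
#' @param C_m assumed membrane capacitance, pF; used only to convert the
#'   external DC current into an equivalent mean drive in mV.
#' @return An object of class \code{neuron_params}.
#' @export
neuron_params <- function(tau = 20, theta = 20, v_reset = 10,
                          t_ref = 2, C_m = 250) {
  stopifnot(tau > 0, theta > v_reset, t_ref >= 0, C_m > 0)
  structure(list(tau = tau, theta = theta, v_reset = v_reset,
                 t_ref = t_ref, C_m = C_m), class = "neuron_params")
}

#' Convert a DC current into the equivalent membrane drive and Poisson rate
#'
#' A constant current \code{I_DC} (pA) shifts the membrane equilibrium by
#' \code{I_DC * tau / C_m} millivolts. The equivalent external Poisson rate
#' \code{r0} is the rate at which delta synapses of amplitude \code{J} would
#' produce the same mean drive, \code{r0 = drive / (tau * J)} (spikes/ms); it
#' enters the mean-input equations but not the input variance.
#'
#' @param I_DC external current, pA.
#' @param params a \code{\link{neuron_params}}.
#' @param J EPSP amplitude, mV.
#' @return List with \code{drive} (mV) and \code{r0} (spikes/ms).
#' @export
dc_to_drive <- function(I_DC, params = neuron_params(), J = 0.1) {
  stopifnot(I_DC >= 0)
  drive <- I_DC * params$tau / params$C_m
  list(drive = drive, r0 = drive / (params$tau * J))
}

#' Simulate the spiking network
#'
#' Integrates the leaky integrate-and-fire dynamics
#' \deqn{\tau \dot v_i = -v_i + drive + \tau \sum_j J_{ij} S_j(t - t_d)}
#' with exact exponential propagation over each step \code{dt}, delta
#' synapses that add their weight (mV) after the fixed delay \code{t_d}, and
#' threshold/reset. Initial potentials are drawn uniformly on
#' \code{[0, theta)} (seed-controlled); the simulation is otherwise
#' fully deterministic, so all variability is intrinsic network noise.
#'
#' @param graph a \code{\link{assemble_network}} result (or any
#'   \code{weighted_graph}).
#' @param T duration, ms.
#' @param params \code{\link{neuron_params}}.
#' @param dt integration step, ms.
#' @param drive constant membrane drive, mV; defaults to the DC current of
#'   the network spec converted via \code{\link{dc_to_drive}}.
#' @param t_d synaptic delay, ms (multiple of \code{dt}); defaults to the
#'   spec's delay.
#' @param seed seed for the initial potentials.
#' @param v_init optional vector of initial potentials (overrides seed draw).
#' @return An object of class \code{spike_raster}: \code{times} (ms, in
#'   \code{[0, T)}), \code{ids} (1-based neuron ids), \code{membership},
#'   \code{T}, \code{dt}, and the final membrane potentials \code{v_final}
#'   (mV).
#' @export
simulate_lif <- function(graph, T, params = neuron_params(), dt = 0.1,
                         drive = NULL, t_d = NULL, seed = 1L, v_init = NULL) {
  stopifnot(inherits(graph, "weighted_graph"), T > 0, dt > 0)
  if (is.null(drive)) {
    if (is.null(graph$spec)) stop("graph has no spec; supply `drive` explicitly")
    drive <- dc_to_drive(graph$spec$I_DC, params, graph$spec$J)$drive
  }
  if (is.null(t_d)) t_d <- if (!is.null(graph$spec)) graph$spec$t_d else dt
  delay_steps <- round(t_d / dt)
  if (abs(delay_steps * dt - t_d) > 1e-9 || delay_steps < 1)
    stop("t_d must be a positive integer multiple of dt")
  N <- nrow(graph$W)
  if (is.null(v_init)) {
    set.seed(seed)
    v_init <- stats::runif(N, 0, params$theta)
  }
  stopifnot(length(v_init) == N)
  Wt <- Matrix::t(graph$W)  # dgCMatrix: columns are presynaptic neurons
  if (!inherits(Wt, "dgCMatrix")) Wt <- as(Wt, "CsparseMatrix")
  res <- cpp_simulate_lif(Wt@p, Wt@i, Wt@x, N, dt, params$tau, params$theta,
                          params$v_reset, drive, n_steps = round(T / dt),
                          delay_steps = delay_steps,
                          ref_steps = round(params$t_ref / dt),
                          v0 = v_init)
  structure(list(times = res$times, ids = res$ids,
                 membership = graph$membership, T = T, dt = dt,
                 drive = drive, seed = seed, v_final = res$v_final),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("spike_raster: %d spikes from %d neurons over %g ms (%.3f spikes/ms network rate)\n",
              n, length(x$membership), x$T, n / x$T))
  invisible(x)
}

#' Write / read a spike raster as plain text
#'
#' Two-column tab-separated table: spike time (ms) and 0-based neuron id,
#' plus the membership table as written by \code{\link{write_network}}.
#'
#' @param raster a \code{spike_raster}.
#' @param file base path; \code{<file>.spikes.tsv} and \code{<file>.pops.tsv}
#'   are written.
#' @export
write_raster <- function(raster, file) {
  stopifnot(inherits(raster, "spike_raster"))
  sp <- data.frame(time = raster$times, neuron = raster$ids - 1L)
  pops <- data.frame(neuron = seq_along(raster$membership) - 1L,
                     population = as.character(raster$membership))
  f1 <- paste0(file, ".spikes.tsv"); f2 <- paste0(file, ".pops.tsv")
  utils::write.table(sp, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(pops, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(spikes = f1, pops = f2))
}

#' @rdname write_raster
#' @param T duration in ms; defaults to the last spike time rounded up.
#' @export
read_raster <- function(file, T = NULL) {
  sp <- utils::read.table(paste0(file, ".spikes.tsv"), header = TRUE, sep = "\t")
  pops <- utils::read.table(paste0(file, ".pops.tsv"), header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (is.null(T)) T <- if (nrow(sp)) ceiling(max(sp$time)) else 0
  structure(list(times = sp$time, ids = sp$neuron + 1L,
                 membership = factor(pops$population,
                                     levels = unique(pops$population)),
                 T = T, dt = NA, drive = NA, seed = NA),
            class = "spike_raster")
}
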