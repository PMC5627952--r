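#' Synaptic configuration: release sites, active zones, depression
#'
#' A fixed pool of `N` single-vesicle release sites is split equally between
#' `M` active zones (`N_M = N / M` sites per zone), each zone driven by one
#' presynaptic neuron. An occupied site releases its vesicle with constant
#' probability `P_v` at each presynaptic spike of its zone; after a release
#' the site refills after an exponentially distributed delay with mean
#' `tau_rec`. `M = 1` is the "giant" (calyx-like) pathway, `M = N` the
#' "cortical" pathway of independent single-site inputs.
#'
#' @param N total number of release sites (default 512).
#' @param M number of active zones; must divide `N` exactly.
#' @param P_v release probability per available vesicle, in `[0, 1]`.
#' @param tau_rec replenishment time constant (s).
#' @return an object of class `synaptic_config` with the additional field
#'   `N_M = N / M`.
#' @export
#' @examples
#' synaptic_config(M = 4)
synaptic_config <- function(N = 512, M = 1, P_v = 0.25, tau_rec = 0.5) {
  stopifnot(N >= 1, M >= 1)
  if (N %% M != 0) stop("M must divide N exactly (equal-sized active zones)")
  if (P_v < 0 || P_v > 1) stop("P_v must lie in [0, 1]")
  if (tau_rec <= 0) stop("tau_rec must be > 0")
  structure(list(N = as.integer(N), M = as.integer(M),
                 N_M = as.integer(N / M), P_v = P_v, tau_rec = tau_rec),
            class = "synaptic_config")
}

#' @export
print.synaptic_config <- function(x, ...) {
  cat(sprintf(
    "Synaptic pathway: N = %d sites in M = %d active zones (N_M = %d), P_v = %g, tau_rec = %g s\n",
    x$N, x$M, x$N_M, x$P_v, x$tau_rec))
  invisible(x)
}

#' Simulate stochastic vesicle release at all active zones
#'
#' Event-driven implementation: per-site next-availability times start at 0
#' (all sites filled), and at each presynaptic spike every available site of
#' that zone releases independently with probability `P_v`, scheduling its
#' refill `Exp(tau_rec)` later. This is distribution-equivalent to the
#' small-time-step automaton in which an empty site refills with probability
#' `dt / tau_rec` per step, but costs one draw per available site per spike.
#'
#' @param trains a `spike_population` or list of `spike_train` objects; its
#'   length must equal `cfg$M`.
#' @param cfg a [synaptic_config()].
#' @param seed optional integer seed for the release RNG stream (separate
#'   from spike generation, so the same input spikes can be re-released).
#' @return an object of class `release_train`: a list with `events` (a
#'   data.frame with one row per presynaptic spike: `time`, `zone`, `count`
#'   of vesicles released, and the `avail` fraction of that zone's sites
#'   occupied immediately before release sampling) and `config`.
#' @export
#' @examples
#' pop <- generate_population(2, stimulus_params(duration = 2), seed = 1)
#' rel <- simulate_release(pop, synaptic_config(N = 8, M = 2), seed = 2)
#' head(rel$events)
simulate_release <- function(trains, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synaptic_config"))
  if (inherits(trains, "spike_population")) trains <- trains$trains
  if (inherits(trains, "spike_train")) trains <- list(trains)
  if (length(trains) != cfg$M)
    stop(sprintf("configuration mismatch: %d spike trains for M = %d zones",
                 length(trains), cfg$M))
  if (!is.null(seed)) set.seed(seed)
  times <- lapply(trains, function(tr) as.numeric(tr$times))
  events <- release_sim_cpp(times, cfg$N_M, cfg$P_v, cfg$tau_rec)
  structure(list(events = events, config = cfg), class = "release_train")
}

#' @export
print.release_train <- function(x, ...) {
  cat(sprintf(
    "Release train: %d presynaptic spikes, %d vesicles released (mean availability %.3f)\n",
    nrow(x$events), sum(x$events$count), mean(x$events$avail)))
  invisible(x)
}

#' Per-spike vesicle availability fraction
#'
#' Diagnostic recorded during [simulate_release()]: for each presynaptic
#' spike, the fraction of that zone's sites holding a vesicle immediately
#' before release sampling. Its modulation-phase profile is the Monte-Carlo
#' counterpart of the availability ODE solved by [solve_availability_ode()].
#'
#' @param release a `release_train`.
#' @return a data.frame with columns `time`, `zone`, `avail`.
#' @export
availability_at_spikes <- function(release) {
  stopifnot(inherits(release, "release_train"))
  release$events[c("time", "zone", "avail")]
}

#' Write / read a release train as tab-separated text
#'
#' Columns `time_s`, `count`, `zone`, with a `#`-comment header recording
#' the synaptic configuration.
#'
#' @param release a `release_train`.
#' @param file path.
#' @return `read_release_train()` returns a `release_train` (the `avail`
#'   diagnostic is not round-tripped).
#' @export
write_release_train <- function(release, file) {
  cfg <- release$config
  hdr <- sprintf("# N=%d M=%d P_v=%g tau_rec=%g", cfg$N, cfg$M, cfg$P_v,
                 cfg$tau_rec)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(hdr, "time_s\tcount\tzone"), con)
  write.table(release$events[c("time", "count", "zone")], con, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_release_train
#' @export
read_release_train <- function(file) {
  lines <- readLines(file, n = 1)
  kv <- regmatches(lines, gregexpr("[A-Za-z_]+=[-0-9.eE]+", lines))[[1]]
  vals <- as.list(as.numeric(sub(".*=", "", kv)))
  names(vals) <- sub("=.*", "", kv)
  cfg <- synaptic_config(N = vals$N, M = vals$M, P_v = vals$P_v,
                         tau_rec = vals$tau_rec)
  df <- read.table(file, header = TRUE, sep = "\t", comment.char = "#")
  names(df)[names(df) == "time_s"] <- "time"
  df$avail <- NA_real_
  structure(list(events = df[c("time", "zone", "count", "avail")],
                 config = cfg), class = "release_train")
}
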