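#' Parameters of the sinusoidally modulated presynaptic drive
#'
#' The presynaptic population fires as independent inhomogeneous Poisson
#' processes with common rate \deqn{\lambda_S(t) = A + B \sin(2\pi f t),}
#' where `A` is the mean rate, `B` the peak modulation depth and `f` the
#' modulation frequency. With the defaults (`A = 30`, `B = 20` Hz) the
#' instantaneous rate swings between 10 and 50 Hz. Each generated spike is
#' followed by a dead time (`refractory`, default 2 ms) during which no
#' further spikes can occur.
#'
#' @param A mean input rate (Hz).
#' @param B peak modulation (Hz); must satisfy `A - B > 0` so the rate stays
#'   positive.
#' @param f modulation frequency (Hz).
#' @param refractory dead time after each spike (s).
#' @param duration total simulated time (s).
#' @return an object of class `stimulus_params`.
#' @export
#' @examples
#' p <- stimulus_params(duration = 5)
#' modulated_rate(c(0, 0.25, 0.75), p)
stimulus_params <- function(A = 30, B = 20, f = 1, refractory = 0.002,
                            duration = 1) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(f))
  if (A - B <= 0) stop("require A - B > 0 so the instantaneous rate is positive")
  if (f <= 0) stop("modulation frequency f must be > 0")
  if (refractory < 0) stop("refractory must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(A = A, B = B, f = f, refractory = refractory,
                 duration = duration),
            class = "stimulus_params")
}

#' @export
print.stimulus_params <- function(x, ...) {
  cat(sprintf(
    "Sinusoidal Poisson drive: rate = %g + %g sin(2*pi*%g*t) Hz, %g s, refractory %g ms\n",
    x$A, x$B, x$f, x$duration, 1000 * x$refractory))
  invisible(x)
}

#' Instantaneous presynaptic rate
#'
#' @param t time(s) in seconds (vectorised).
#' @param p a [stimulus_params()] object.
#' @return rate(s) in Hz.
#' @export
modulated_rate <- function(t, p) {
  p$A + p$B * sin(2 * pi * p$f * t)
}

#' Integrated presynaptic rate
#'
#' The cumulative intensity \eqn{\Lambda(t) = \int_0^t \lambda_S(u)\,du}
#' \eqn{= A t + B (1 - \cos(2\pi f t)) / (2\pi f)}. Used for time-rescaling
#' diagnostics of generated spike trains.
#'
#' @inheritParams modulated_rate
#' @return expected spike count on `[0, t]`.
#' @export
rate_integral <- function(t, p) {
  w <- 2 * pi * p$f
  p$A * t + p$B * (1 - cos(w * t)) / w
}

#' Generate one presynaptic spike train by thinning
#'
#' Candidate events are drawn from a homogeneous Poisson process at the
#' tight dominating rate `A + B` and accepted with probability
#' \eqn{\lambda_S(t)/(A+B)}; accepted candidates falling within the
#' refractory dead time of the previously retained spike are then deleted.
#'
#' @param p a [stimulus_params()] object.
#' @param neuron_id integer identifier stored with the train.
#' @param seed optional integer seed for this train; if `NULL` the current
#'   RNG state is used.
#' @return an object of class `spike_train` with elements `neuron_id`,
#'   `times` (strictly increasing, seconds) and `params`.
#' @export
#' @examples
#' tr <- generate_spike_train(stimulus_params(duration = 2), seed = 1)
#' length(tr$times)
generate_spike_train <- function(p, neuron_id = 1L, seed = NULL) {
  stopifnot(inherits(p, "stimulus_params"))
  if (!is.null(seed)) set.seed(seed)
  lmax <- p$A + p$B
  n_cand <- rpois(1L, lmax * p$duration)
  cand <- sort(runif(n_cand, 0, p$duration))
  keep <- runif(n_cand) < modulated_rate(cand, p) / lmax
  times <- cand[keep]
  if (p$refractory > 0) times <- enforce_refractory_cpp(times, p$refractory)
  structure(list(neuron_id = as.integer(neuron_id), times = times, params = p),
            class = "spike_train")
}

#' Generate a population of independent presynaptic spike trains
#'
#' Each of the `M` trains uses its own RNG sub-stream derived from the
#' master seed and the neuron id, so a given neuron's train does not depend
#' on `M` and relabelling neuron ids permutes the trains exactly.
#'
#' @param M number of presynaptic neurons (one per active zone).
#' @param p a [stimulus_params()] object shared by all trains.
#' @param seed optional master seed.
#' @return an object of class `spike_population`: a list with `trains`
#'   (list of `spike_train`), `params` and `M`.
#' @export
#' @examples
#' pop <- generate_population(4, stimulus_params(duration = 2), seed = 1)
#' sapply(pop$trains, function(tr) length(tr$times))
generate_population <- function(M, p, seed = NULL) {
  if (!is.numeric(M) || M < 1 || M != round(M))
    stop("M must be a positive integer")
  M <- as.integer(M)
  trains <- lapply(seq_len(M), function(id) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, "train", id)
    generate_spike_train(p, neuron_id = id, seed = s)
  })
  structure(list(trains = trains, params = p, M = M),
            class = "spike_population")
}

#' @export
print.spike_population <- function(x, ...) {
  n <- vapply(x$trains, function(tr) length(tr$times), integer(1))
  cat(sprintf("Population of %d spike trains, %d spikes total (%.1f Hz mean)\n",
              x$M, sum(n), mean(n) / x$params$duration))
  invisible(x)
}

#' Write / read spike trains as tab-separated text
#'
#' Two columns, `neuron_id` and `time_s`, preceded by `#`-comment header
#' lines recording the stimulus parameters.
#'
#' @param pop a `spike_population` (or single `spike_train`).
#' @param file path to write to / read from.
#' @return `read_spike_trains()` returns a `spike_population`.
#' @export
write_spike_trains <- function(pop, file) {
  if (inherits(pop, "spike_train"))
    pop <- structure(list(trains = list(pop), params = pop$params, M = 1L),
                     class = "spike_population")
  p <- pop$params
  hdr <- sprintf("# A=%g B=%g f=%g refractory=%g duration=%g M=%d",
                 p$A, p$B, p$f, p$refractory, p$duration, pop$M)
  df <- do.call(rbind, lapply(pop$trains, function(tr)
    data.frame(neuron_id = tr$neuron_id, time_s = tr$times)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(hdr, "neuron_id\ttime_s"), con)
  write.table(df, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(file)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")][1]
  kv <- regmatches(hdr, gregexpr("[A-Za-z_]+=[-0-9.eE]+", hdr))[[1]]
  vals <- as.list(as.numeric(sub(".*=", "", kv)))
  names(vals) <- sub("=.*", "", kv)
  p <- stimulus_params(A = vals$A, B = vals$B, f = vals$f,
                       refractory = vals$refractory, duration = vals$duration)
  df <- read.table(file, header = TRUE, sep = "\t", comment.char = "#")
  ids <- sort(unique(df$neuron_id))
  trains <- lapply(ids, function(id)
    structure(list(neuron_id = as.integer(id),
                   times = sort(df$time_s[df$neuron_id == id]), params = p),
              class = "spike_train"))
  structure(list(trains = trains, params = p, M = length(ids)),
            class = "spike_population")
}
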