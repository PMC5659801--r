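# Stimulus protocols. Times are minutes throughout; concentrations nM.

#' Imaging time grid
#'
#' Default sampling grid of the live-cell recordings: every 5 minutes within
#' the first 30 minutes, every 10 minutes afterwards up to 300 minutes.
#'
#' @param t_end End of the recording in minutes.
#' @return Numeric vector of sample times (minutes).
#' @export
default_grid <- function(t_end = 300)
  c(seq(0, 30, by = 5), seq(40, t_end, by = 10))

new_protocol <- function(condition, sample_times, ...) {
  stopifnot(is.numeric(sample_times), length(sample_times) >= 2)
  if (any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing")
  if (any(sample_times < 0)) stop("sample_times must be nonnegative")
  structure(c(list(condition = condition,
                   sample_times = as.numeric(sample_times)), list(...)),
            class = "epor_protocol")
}

#' Stimulus protocols
#'
#' Constructors for the three experimental protocols: Epo stimulation at
#' constant ligand concentration, a photobleaching pulse, and cycloheximide
#' (CHX) treatment switching off receptor synthesis.
#'
#' @param epo_conc Epo concentration in nM after addition (constant; the
#'   medium reservoir is not depleted).
#' @param add_time Time of Epo addition (min). Samples taken exactly at
#'   `add_time` are pre-addition.
#' @param sample_times Strictly increasing sample times (min).
#' @param start,duration Start and length (min) of the bleach pulse during
#'   which the first-order bleaching reaction is active.
#' @param chx_time Time (min) from which synthesis is set to zero.
#' @return An object of class `epor_protocol`.
#' @export
epo_protocol <- function(epo_conc = 4.2, add_time = 0,
                         sample_times = default_grid()) {
  stopifnot(epo_conc > 0, add_time >= 0)
  new_protocol("epo", sample_times, epo_conc = epo_conc, add_time = add_time)
}

#' @rdname epo_protocol
#' @export
bleach_protocol <- function(start = 5, duration = 0.5,
                            sample_times = default_grid()) {
  stopifnot(start >= 0, duration > 0)
  new_protocol("bleach", sample_times, epo_conc = 0,
               bleach_start = start, bleach_end = start + duration)
}

#' @rdname epo_protocol
#' @export
chx_protocol <- function(chx_time = 0, sample_times = default_grid()) {
  stopifnot(chx_time >= 0)
  new_protocol("chx", sample_times, epo_conc = 0, chx_time = chx_time)
}

#' @export
print.epor_protocol <- function(x, ...) {
  cat("Protocol:", x$condition, "|",
      length(x$sample_times), "samples in [",
      min(x$sample_times), ",", max(x$sample_times), "] min\n")
  if (x$condition == "epo")
    cat("  Epo:", x$epo_conc, "nM added at t =", x$add_time, "min\n")
  if (x$condition == "bleach")
    cat("  bleach pulse: [", x$bleach_start, ",", x$bleach_end, "] min\n")
  if (x$condition == "chx")
    cat("  synthesis off from t =", x$chx_time, "min\n")
  invisible(x)
}

default_protocol <- function(condition, t_end = 300) {
  switch(condition,
         epo = epo_protocol(sample_times = default_grid(t_end)),
         bleach = bleach_protocol(sample_times = default_grid(t_end)),
         chx = chx_protocol(sample_times = default_grid(t_end)),
         stop("unknown condition: ", condition))
}
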