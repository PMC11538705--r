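# Generics shared across containers.

#' Sampling rate of a time-series container
#' @param x a container with a sampling rate.
#' @return rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Duration in seconds
#' @param x a container with a time axis.
#' @return duration in seconds.
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))

#' Azimuth series of a trajectory
#' @param x a [Trajectory-class].
#' @return numeric vector of azimuths in degrees.
#' @export
setGeneric("azimuth", function(x) standardGeneric("azimuth"))

#' Azimuth at given times (linear interpolation)
#' @param x a [Trajectory-class].
#' @param timesS times in seconds.
#' @return numeric azimuths in degrees.
#' @export
setGeneric("azimuthAt", function(x, timesS) standardGeneric("azimuthAt"))
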