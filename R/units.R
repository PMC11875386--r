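#' Convert rates between per-day and per-second
#'
#' Biological rates and the DOM diffusion coefficient are configured in
#' day^-1 (resp. voxel^2 day^-1), while simulation time steps are usually
#' given in seconds. All conversions in the package go through these two
#' helpers so the factor 1/86400 lives in exactly one place.
#'
#' @param x numeric rate(s), in day^-1 for `per_second()` or in s^-1 for
#'   `per_day()`.
#' @return the converted rate(s).
#' @examples
#' per_second(86400)  # 1 per second
#' per_day(per_second(100950))
#' @export
per_second <- function(x) x / 86400

#' @rdname per_second
#' @export
per_day <- function(x) x * 86400
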