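# Frequency-band definitions used throughout the pipeline.

#' Canonical EEG frequency bands
#'
#' The five bands analysed by the pipeline: theta 4--7 Hz, alpha 7--13 Hz,
#' beta1 13--20 Hz, beta2 20--30 Hz and gamma 31--45 Hz. All bands lie
#' inside the 4--45 Hz range the preprocessed recordings are filtered to.
#'
#' @param name optional band name; with no argument all five are returned.
#' @return a `band_definition` (list with `name`, `lo`, `hi`) or, with no
#'   argument, a named list of all five.
#' @examples
#' eeg_bands("gamma")
#' names(eeg_bands())
#' @export
eeg_bands <- function(name = NULL) {
  defs <- list(
    theta = band_definition("theta", 4, 7),
    alpha = band_definition("alpha", 7, 13),
    beta1 = band_definition("beta1", 13, 20),
    beta2 = band_definition("beta2", 20, 30),
    gamma = band_definition("gamma", 31, 45)
  )
  if (is.null(name)) return(defs)
  name <- match.arg(name, names(defs))
  defs[[name]]
}

#' Construct a band definition
#'
#' @param name band label.
#' @param lo,hi band edges in Hz, `0 < lo < hi`.
#' @return a `band_definition` object.
#' @export
band_definition <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lo), is.numeric(hi), length(lo) == 1L,
            length(hi) == 1L)
  if (!(lo > 0 && hi > lo)) stop("band edges must satisfy 0 < lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

as_band <- function(band) {
  if (inherits(band, "band_definition")) return(band)
  if (is.character(band) && length(band) == 1L) return(eeg_bands(band))
  stop("'band' must be a band name or a band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}
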