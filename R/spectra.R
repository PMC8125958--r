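#' @title NIR spectral preprocessing
#' @description Savitzky--Golay smoothing followed by the standard normal
#'   variate (SNV) transform, the scatter-correction pair applied to every
#'   spectrum before chemometric modelling.
#' @name spectra-prep
NULL

as_spectrum <- function(s) {
  if (is.numeric(s) && is.null(dim(s)))
    s <- data.frame(wavelength_nm = seq_along(s), intensity = as.numeric(s))
  if (!is.data.frame(s) ||
      !all(c("wavelength_nm", "intensity") %in% names(s)))
    stop("a spectrum is a data.frame with wavelength_nm and intensity",
         call. = FALSE)
  if (any(diff(s$wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  s
}

#' Savitzky--Golay smoothing
#'
#' Sliding-window local least-squares polynomial smoothing: each point is
#' replaced by the window-center value of the polynomial of order `polyorder`
#' fitted to its `window` neighbours; the first and last half-windows take
#' their values from the terminal window fits (polynomial edge handling).
#' Wavelengths are unchanged. Delegates to [signal::sgolayfilt()].
#'
#' @param s a spectrum data.frame (`wavelength_nm`, `intensity`) or a bare
#'   intensity vector.
#' @param window odd window length (default 11).
#' @param polyorder polynomial order (default 2), `< window`.
#' @return a spectrum of the same form as the input.
#' @export
sg_smooth <- function(s, window = 11L, polyorder = 2L) {
  vec_in <- is.numeric(s) && is.null(dim(s))
  s <- as_spectrum(s)
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window < 3L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  if (polyorder < 0L || polyorder >= window)
    stop("polyorder must satisfy 0 <= polyorder < window", call. = FALSE)
  if (window > nrow(s)) stop("window exceeds spectrum length", call. = FALSE)
  s$intensity <- signal::sgolayfilt(s$intensity, p = polyorder, n = window)
  if (vec_in) s$intensity else s
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum to mean 0 and (sample, n-1) standard
#' deviation 1 across its own wavelengths. Removes additive offsets and
#' multiplicative scatter exactly: `snv(a*x + b) == snv(x)` for `a > 0`.
#'
#' @param s a spectrum data.frame or intensity vector.
#' @return spectrum of the same form; errors on zero-variance input.
#' @export
snv <- function(s) {
  vec_in <- is.numeric(s) && is.null(dim(s))
  s <- as_spectrum(s)
  sdev <- sd(s$intensity)
  # numerically constant counts as degenerate: smoothing an exactly flat
  # spectrum leaves O(1e-16) jitter that must not be amplified to unit scale
  if (!is.finite(sdev) || sdev <= 1e-10 * max(1, max(abs(s$intensity))))
    stop("SNV undefined for a constant (zero-variance) spectrum",
         call. = FALSE)
  s$intensity <- (s$intensity - mean(s$intensity)) / sdev
  if (vec_in) s$intensity else s
}

#' Savitzky--Golay + SNV preprocessing
#'
#' The standard chain, in that order: smooth, then scatter-correct.
#'
#' @inheritParams sg_smooth
#' @return preprocessed spectrum of the same form as the input.
#' @export
preprocess_spectrum <- function(s, window = 11L, polyorder = 2L) {
  snv(sg_smooth(s, window, polyorder))
}

#' Preprocess a matrix of spectra
#'
#' Applies [preprocess_spectrum()] to each row of an n x p intensity matrix
#' (one spectrum per sample).
#'
#' @param M numeric matrix, rows = samples.
#' @inheritParams sg_smooth
#' @return matrix of the same shape; each row has mean 0 and sd 1.
#' @export
preprocess_spectra <- function(M, window = 11L, polyorder = 2L) {
  M <- as.matrix(M)
  out <- t(apply(M, 1, function(x) {
    snv(sg_smooth(x, window, polyorder))
  }))
  dimnames(out) <- dimnames(M)
  out
}
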