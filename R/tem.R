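#' Quantize a follow-up interval into monthly bins
#'
#' Intervals are truncated at 600 days and binned into 30-day months:
#' \code{floor(min(days, 600) / 30)}, giving a working range of 0--20 months.
#' Month 0 is admitted (it drives the baseline-consistency regularizers) even
#' though the clinical prediction range starts at 1 month.
#'
#' @param delta_days Non-negative integer number of days.
#' @param truncate_days Truncation point (default 600).
#' @param bin_days Bin width in days (default 30).
#' @return Integer month index in [0, 20] under the defaults.
#' @export
quantize_interval <- function(delta_days, truncate_days = 600, bin_days = 30) {
  if (any(!is.finite(delta_days)) || any(delta_days < 0))
    stop("delta_days must be non-negative")
  as.integer(floor(pmin(delta_days, truncate_days) / bin_days))
}

#' Sinusoidal temporal encoding
#'
#' Encodes a month index as a fixed vector of sines and cosines with
#' geometrically increasing wavelengths: component \code{2i} is
#' \code{sin(t / 100^(2i/d_fm))} and component \code{2i+1} is
#' \code{cos(t / 100^(2i/d_fm))} for \code{i = 0 ... d_fm/2 - 1}. The
#' embedding is deterministic, bounded in [-1, 1], and injective over the
#' working range 0--20 months.
#'
#' @param t_itv Non-negative integer month index.
#' @param d_fm Even positive embedding dimension.
#' @return Numeric vector of length \code{d_fm}.
#' @export
tem_encode <- function(t_itv, d_fm) {
  if (d_fm <= 0 || d_fm %% 2 != 0) stop("d_fm must be an even positive integer")
  if (!is.finite(t_itv) || t_itv < 0) stop("t_itv must be non-negative")
  i <- seq_len(d_fm / 2) - 1
  freq <- 1 / 100^(2 * i / d_fm)
  emb <- numeric(d_fm)
  emb[2 * i + 1] <- sin(t_itv * freq)
  emb[2 * i + 2] <- cos(t_itv * freq)
  emb
}
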