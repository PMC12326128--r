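#' Sigmoidal unit activation
#'
#' Static input/output relationship of every neural unit: a logistic function
#' with lower threshold and saturation at 1, so all activities are normalized
#' to the maximum firing rate.
#'
#' @param u net input (any numeric array); must be finite.
#' @param theta central abscissa (input at which activation is 0.5).
#' @param slope slope parameter.
#' @return Activation values in (0, 1), same shape as `u`.
#' @examples
#' sigmoid(25, 25, 0.3)                   # 0.5 at the midpoint
#' sigmoid(25 + log(9) / 0.3, 25, 0.3)    # 0.9
#' @export
sigmoid <- function(u, theta = 25, slope = 0.3) {
  if (!is.numeric(u) || any(!is.finite(u))) {
    stop("sigmoid: net input 'u' must be finite numeric")
  }
  1 / (1 + exp(-slope * (u - theta)))
}

# inter-unit distance matrix in degrees; plain |difference|, no wraparound
# (experiments live within +/-20 degrees of centre, edge effects negligible)
.distance_matrix <- function(positions) {
  abs(outer(positions, positions, "-"))
}

#' Gaussian connectivity kernel
#'
#' Weight from source unit k to target unit j is
#' `w0 * exp(-d(j,k)^2 / (2 * sd_deg^2))` with `d` the inter-unit distance in
#' degrees. Rows index targets, columns sources.
#'
#' @param w0 peak effectiveness (at distance 0); `w0 >= 0`.
#' @param sd_deg spatial spread in degrees; strictly positive.
#' @param positions unit azimuths (degrees), e.g. [unit_positions()].
#' @return `length(positions)` square weight matrix.
#' @export
gaussian_kernel <- function(w0, sd_deg, positions) {
  if (!is.numeric(w0) || length(w0) != 1L || w0 < 0) {
    stop("gaussian_kernel: 'w0' must be a single non-negative number")
  }
  if (!is.numeric(sd_deg) || length(sd_deg) != 1L || sd_deg <= 0) {
    stop("gaussian_kernel: 'sd_deg' must be strictly positive")
  }
  d <- .distance_matrix(positions)
  w0 * exp(-d^2 / (2 * sd_deg^2))
}

#' Mexican-hat (difference of Gaussians) connectivity kernel
#'
#' Short-range excitation minus longer-range inhibition:
#' `lex0 * exp(-d^2/(2 sd_ex^2)) - lin0 * exp(-d^2/(2 sd_in^2))`.
#' The self-connection (distance 0) is retained, so the diagonal equals
#' `lex0 - lin0`.
#'
#' @param lex0,sd_ex excitatory peak and spread (degrees).
#' @param lin0,sd_in inhibitory peak and spread (degrees).
#' @param positions unit azimuths (degrees).
#' @return Square weight matrix (rows targets, columns sources).
#' @export
mexican_hat_kernel <- function(lex0, sd_ex, lin0, sd_in, positions) {
  for (v in list(lex0 = lex0, sd_ex = sd_ex, lin0 = lin0, sd_in = sd_in)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop("mexican_hat_kernel: all four parameters must be strictly positive")
    }
  }
  d <- .distance_matrix(positions)
  lex0 * exp(-d^2 / (2 * sd_ex^2)) - lin0 * exp(-d^2 / (2 * sd_in^2))
}

#' Build every connectivity kernel of the network
#'
#' Constructs one weight matrix per connection family (rows targets, columns
#' sources; subscript convention is target-source, so `cross_av` carries
#' visual activity into the auditory area):
#' \describe{
#'   \item{cross_av, cross_va}{excitatory cross-modal kernels between the
#'     input areas (A <- V with peak `wav0`, V <- A with peak `wva0`).}
#'   \item{ff_ma, ff_mv}{feedforward kernels input areas -> multisensory.}
#'   \item{ff_ia, ff_iv}{feedforward kernels input areas -> same-modality
#'     interneurons.}
#'   \item{fb_laiv, fb_lvia}{inhibitory feedback kernels interneurons ->
#'     opposite input area (A <- Iv, V <- Ia).}
#'   \item{lat_a, lat_v, lat_m}{within-area Mexican-hat kernels.}
#'   \item{wta}{interneuron reciprocal inhibition, `wta0` times identity.}
#'   \item{pm}{multisensory -> premotor, `wpmm0` times identity.}
#' }
#'
#' @param params an `av_params` record.
#' @return A list of class `av_kernels` holding the matrices plus the unit
#'   `positions`.
#' @export
build_kernels <- function(params) {
  validate_av_params(params)
  p <- params
  x <- unit_positions(p$n_units)
  k <- list(
    cross_av = gaussian_kernel(p$wav0, p$wav_sd, x),
    cross_va = gaussian_kernel(p$wva0, p$wva_sd, x),
    ff_ma    = gaussian_kernel(p$wma0, p$wma_sd, x),
    ff_mv    = gaussian_kernel(p$wmv0, p$wmv_sd, x),
    ff_ia    = gaussian_kernel(p$wia0, p$wia_sd, x),
    ff_iv    = gaussian_kernel(p$wiv0, p$wiv_sd, x),
    fb_laiv  = gaussian_kernel(p$laiv0, p$laiv_sd, x),
    fb_lvia  = gaussian_kernel(p$lvia0, p$lvia_sd, x),
    lat_a    = mexican_hat_kernel(p$la_ex0, p$la_ex_sd, p$la_in0, p$la_in_sd, x),
    lat_v    = mexican_hat_kernel(p$lv_ex0, p$lv_ex_sd, p$lv_in0, p$lv_in_sd, x),
    lat_m    = mexican_hat_kernel(p$lm_ex0, p$lm_ex_sd, p$lm_in0, p$lm_in_sd, x),
    wta      = diag(p$wta0, p$n_units),
    pm       = diag(p$wpmm0, p$n_units),
    positions = x
  )
  class(k) <- "av_kernels"
  k
}
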