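# Synthetic time-correlated single-photon-counting stacks: per-pixel
# mono-exponential decays with Poisson shot noise, two lifetime populations
# (donor-only and FRET-quenched) for efficiency-recovery tests.

#' Parameters of the synthetic TCSPC generator
#'
#' Each pixel carries a photon-count histogram over `n_bins` time bins of
#' width `bin_width` ns; counts are Poisson draws around
#' `A * exp(-t / tau) + background_rate` with `tau` equal to `tau_donor` or
#' `tau_quenched` according to a random `fraction_quenched` assignment. The
#' amplitude `A` is set so that the expected decay photons per pixel equal
#' `photons_per_pixel`.
#'
#' @param shape image height and width, px
#' @param n_bins number of time bins
#' @param bin_width ns per bin; the span `n_bins * bin_width` must cover at
#'   least `3 * tau_donor` or the tail is unfittable
#' @param tau_donor donor-only lifetime, ns
#' @param tau_quenched lifetime of FRET-quenched pixels, ns
#'   (`<= tau_donor`)
#' @param fraction_quenched fraction of pixels drawn from the quenched
#'   population, in `[0, 1]`
#' @param photons_per_pixel expected decay photons per pixel
#' @param background_rate expected background counts per bin
#' @param seed integer RNG seed
#' @export
tcspc_params <- function(shape = c(32L, 32L), n_bins = 128L, bin_width = 0.2,
                         tau_donor = 4.0, tau_quenched = 3.0,
                         fraction_quenched = 0.3, photons_per_pixel = 1e4,
                         background_rate = 0, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 1))
  check_scalar(n_bins, "n_bins", lower = 4, integer = TRUE)
  check_scalar(bin_width, "bin_width", lower = 0, allow_equal_lower = FALSE)
  check_scalar(tau_donor, "tau_donor", lower = 0, allow_equal_lower = FALSE)
  check_scalar(tau_quenched, "tau_quenched", lower = 0,
               allow_equal_lower = FALSE)
  if (tau_quenched > tau_donor)
    stop_bad("tau_quenched (%g) must not exceed tau_donor (%g)",
             tau_quenched, tau_donor)
  check_scalar(fraction_quenched, "fraction_quenched", lower = 0, upper = 1)
  check_scalar(photons_per_pixel, "photons_per_pixel", lower = 0,
               allow_equal_lower = FALSE)
  check_scalar(background_rate, "background_rate", lower = 0)
  if (n_bins * bin_width < 3 * tau_donor)
    stop_bad("time span %g ns is below 3 * tau_donor = %g ns: tail unfittable",
             n_bins * bin_width, 3 * tau_donor)
  structure(list(shape = as.integer(shape), n_bins = as.integer(n_bins),
                 bin_width = bin_width, tau_donor = tau_donor,
                 tau_quenched = tau_quenched,
                 fraction_quenched = fraction_quenched,
                 photons_per_pixel = photons_per_pixel,
                 background_rate = background_rate, seed = as.integer(seed)),
            class = "tcspc_params")
}

#' Expected mono-exponential decay over the bin grid
#'
#' Amplitude is chosen so the decay component sums to `photons` over the
#' bins; background adds `background_rate` per bin. Shared by the generator
#' and the noiseless-fit oracle.
#' @param tau lifetime, ns
#' @param n_bins,bin_width time-bin grid
#' @param photons expected total decay photons
#' @param background_rate counts per bin
#' @return list with `t` (bin centres, ns) and `mu` (expected counts)
#' @export
tcspc_expected_decay <- function(tau, n_bins, bin_width, photons,
                                 background_rate = 0) {
  t <- (seq_len(n_bins) - 0.5) * bin_width
  shape_ <- exp(-t / tau)
  list(t = t, mu = photons * shape_ / sum(shape_) + background_rate)
}

#' Synthesize a TCSPC photon-count stack
#'
#' @param params a [tcspc_params()]
#' @return integer array `[row, col, bin]` with attributes `bin_width` and
#'   `n_bins`; [ground_truth()] carries the per-pixel true lifetime map, the
#'   quenched mask and the implied true FRET efficiency
#'   `1 - tau_quenched / tau_donor`
#' @export
synth_tcspc <- function(params) {
  stopifnot(inherits(params, "tcspc_params"))
  set.seed(params$seed)
  h <- params$shape[1]; w <- params$shape[2]
  quenched <- matrix(stats::runif(h * w) < params$fraction_quenched, h, w)
  tau_map <- matrix(params$tau_donor, h, w)
  tau_map[quenched] <- params$tau_quenched
  stack <- array(0L, c(h, w, params$n_bins))
  for (tau in unique(as.vector(tau_map))) {
    idx <- which(tau_map == tau)
    mu <- tcspc_expected_decay(tau, params$n_bins, params$bin_width,
                               params$photons_per_pixel,
                               params$background_rate)$mu
    counts <- matrix(stats::rpois(length(idx) * params$n_bins,
                                  rep(mu, each = length(idx))),
                     length(idx), params$n_bins)
    for (b in seq_len(params$n_bins)) {
      plane <- stack[, , b]
      plane[idx] <- counts[, b]
      stack[, , b] <- plane
    }
  }
  attr(stack, "bin_width") <- params$bin_width
  attr(stack, "n_bins") <- params$n_bins
  set_ground_truth(stack, "synth_tcspc", params, tau_map = tau_map,
                   quenched = quenched,
                   true_efficiency = 1 - params$tau_quenched / params$tau_donor)
}
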