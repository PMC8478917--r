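# Per-pixel fluorescence-lifetime analysis: Levenberg-Marquardt tail fits of
# mono-exponential TCSPC decays (A * exp(-t/tau) + B, Poisson-motivated
# model-based weights, no IRF deconvolution) and FRET efficiency maps via
# E = 1 - tau_DA / tau_D.

#' Fit one pixel's TCSPC decay
#'
#' Fits `A * exp(-t/tau) + B` to the photon-count histogram from the peak
#' bin onward (tail fit). `B` is initialised from the pre-peak bins, `tau`
#' from the background-corrected mean arrival time. Weighted least squares
#' with Poisson-motivated weights `1/max(mu, 1)` — `mu` the current model
#' prediction, re-evaluated each iteration (iteratively reweighted, which
#' avoids the downward tau bias of observed-count weights) — is minimised by
#' Levenberg-Marquardt (iteration cap 200, convergence on relative parameter
#' change < 1e-6).
#'
#' @param counts photon counts per time bin
#' @param bin_width ns per bin
#' @param min_photons validity threshold on the total photon count
#' @return list: `tau` (ns), `amplitude`, `background`, `photons`,
#'   `chi2_red`, `valid`, `reason` (`"ok"`, `"low_photons"`,
#'   `"no_convergence"`, `"empty"`)
#' @export
fit_pixel_decay <- function(counts, bin_width, min_photons = 100) {
  n <- length(counts)
  total <- sum(counts)
  fail <- function(reason) list(tau = NA_real_, amplitude = NA_real_,
                                background = NA_real_, photons = total,
                                chi2_red = NA_real_, valid = FALSE,
                                reason = reason)
  if (total == 0) return(fail("empty"))
  if (total < min_photons) return(fail("low_photons"))
  t_all <- (seq_len(n) - 0.5) * bin_width
  pk <- which.max(counts)
  B0 <- if (pk > 1) mean(counts[seq_len(pk - 1L)]) else 0
  tail_idx <- pk:n
  tt <- t_all[tail_idx]
  cc <- counts[tail_idx]
  if (length(cc) < 4L) return(fail("no_convergence"))
  cpos <- pmax(cc - B0, 0)
  tau0 <- sum(cpos * (tt - tt[1])) / max(sum(cpos), 1)
  tau0 <- max(tau0, bin_width)
  A0 <- max(cc[1] - B0, 1e-6)
  p <- c(A = A0, tau = tau0, B = max(B0, 0))
  resid_of <- function(p) cc - (p[1] * exp(-tt / p[2]) + p[3])
  cost_of <- function(p) sum(w * resid_of(p)^2)
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(200L)) {
    w <- 1 / pmax(p[1] * exp(-tt / p[2]) + p[3], 1)   # model-based weights
    cost <- cost_of(p)
    e <- exp(-tt / p[2])
    J <- cbind(e, p[1] * e * tt / p[2]^2, 1)
    r <- resid_of(p)
    JtWJ <- crossprod(J, w * J)
    JtWr <- crossprod(J, w * r)
    step_ok <- FALSE
    for (try_ in 1:30) {
      H <- JtWJ + lambda * diag(diag(JtWJ), 3)
      delta <- tryCatch(solve(H, JtWr), error = function(e2) NULL)
      if (!is.null(delta)) {
        p_new <- p + as.vector(delta)
        if (p_new[2] > 0 && p_new[1] > 0) {
          cost_new <- cost_of(p_new)
          if (is.finite(cost_new) && cost_new <= cost) {
            # relative change with scale floors so a background pinned at
            # machine zero cannot block convergence
            scale0 <- c(A0, tau0, A0 * 1e-3)
            rel <- max(abs(p_new - p) / pmax(abs(p), scale0))
            p <- p_new
            cost <- cost_new
            lambda <- max(lambda / 10, 1e-12)
            step_ok <- TRUE
            if (rel < 1e-6) converged <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!step_ok) converged <- TRUE   # stalled: no improving step exists
    if (converged) break
  }
  if (!converged) return(fail("no_convergence"))
  list(tau = unname(p[2]), amplitude = unname(p[1]),
       background = unname(p[3]), photons = total,
       chi2_red = cost / max(length(cc) - 3, 1),
       valid = TRUE, reason = "ok")
}

#' Fit lifetimes for every pixel of a TCSPC stack
#'
#' @param stack integer array `[row, col, bin]` (e.g. from [synth_tcspc()]
#'   or [read_stack()]); must carry a `bin_width` attribute unless given
#' @param bin_width ns per bin (default: the stack attribute)
#' @param mask optional logical matrix restricting the fit
#' @param min_photons validity threshold per pixel
#' @return object of class `lifetime_image`: matrices `tau`, `amplitude`,
#'   `background`, `photons`, `chi2_red`, logical `valid`, character
#'   `reason`
#' @export
lifetime_image <- function(stack, bin_width = attr(stack, "bin_width"),
                           mask = NULL, min_photons = 100) {
  stopifnot(length(dim(stack)) == 3L)
  if (is.null(bin_width)) stop_bad("bin_width missing")
  h <- dim(stack)[1]; w <- dim(stack)[2]
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  shell <- matrix(NA_real_, h, w)
  out <- list(tau = shell, amplitude = shell, background = shell,
              photons = shell, chi2_red = shell,
              valid = matrix(FALSE, h, w),
              reason = matrix(NA_character_, h, w))
  for (i in which(mask)) {
    f <- fit_pixel_decay(stack[((i - 1) %% h) + 1, ((i - 1) %/% h) + 1, ],
                         bin_width, min_photons)
    out$tau[i] <- f$tau; out$amplitude[i] <- f$amplitude
    out$background[i] <- f$background; out$photons[i] <- f$photons
    out$chi2_red[i] <- f$chi2_red; out$valid[i] <- f$valid
    out$reason[i] <- f$reason
  }
  if (!any(out$valid)) stop_bad("no valid pixel fits")
  structure(c(out, list(bin_width = bin_width, mask = mask)),
            class = "lifetime_image")
}

#' @export
print.lifetime_image <- function(x, ...) {
  cat(sprintf("<lifetime_image %dx%d: %d valid fits, median tau %.3g ns>\n",
              nrow(x$tau), ncol(x$tau), sum(x$valid),
              stats::median(x$tau[x$valid])))
  invisible(x)
}

# mode of the valid-lifetime histogram (robust donor reference even with a
# quenched subpopulation present)
tau_histogram_mode <- function(lifetimes, bin = 0.05) {
  v <- lifetimes$tau[lifetimes$valid]
  br <- seq(floor(min(v) / bin) * bin, ceiling(max(v) / bin) * bin + bin,
            by = bin)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' FRET efficiency map
#'
#' `E = 1 - tau / tau_D` per valid pixel. The donor reference `tau_D` is a
#' fixed value or, with `"auto"`, the mode of a donor-only control image's
#' lifetime histogram. Negative E from noise is kept (never clipped for
#' statistics).
#'
#' @param lifetimes a [lifetime_image()]
#' @param tau_donor_ref donor-only lifetime in ns, or `"auto"`
#' @param donor_image donor-only control [lifetime_image()] (for `"auto"`)
#' @param hist_binwidth efficiency histogram bin width
#' @return object of class `efficiency_map`: matrix `E`, `photons` weights,
#'   `tau_donor`, histogram (`breaks`, `counts`)
#' @export
efficiency_map <- function(lifetimes, tau_donor_ref = "auto",
                           donor_image = NULL, hist_binwidth = 0.01) {
  tau_d <- if (identical(tau_donor_ref, "auto")) {
    if (is.null(donor_image))
      stop_bad("tau_donor_ref = 'auto' needs a donor-only control image")
    tau_histogram_mode(donor_image)
  } else {
    check_scalar(tau_donor_ref, "tau_donor_ref", lower = 0,
                 allow_equal_lower = FALSE)
    tau_donor_ref
  }
  E <- 1 - lifetimes$tau / tau_d
  E[!lifetimes$valid] <- NA_real_
  ev <- E[is.finite(E)]
  br <- seq(floor(min(ev) / hist_binwidth) * hist_binwidth,
            ceiling(max(ev) / hist_binwidth) * hist_binwidth + hist_binwidth,
            by = hist_binwidth)
  hs <- graphics::hist(ev, breaks = br, plot = FALSE)
  structure(list(E = E, photons = lifetimes$photons, valid = lifetimes$valid,
                 tau_donor = tau_d,
                 histogram = list(breaks = hs$breaks, counts = hs$counts)),
            class = "efficiency_map")
}

#' Weighted mean FRET efficiency of a cell
#'
#' The per-cell summary is the weighted average of per-pixel efficiencies;
#' the default weights are the pixel photon counts (information-
#' proportional); the unweighted mean is always co-reported.
#'
#' @param map an [efficiency_map()]
#' @param weight_mode `"photons"` or `"uniform"`
#' @return list: `weighted`, `unweighted`, `weight_mode`, `n_pixels`
#' @export
weighted_mean_efficiency <- function(map, weight_mode = c("photons", "uniform")) {
  weight_mode <- match.arg(weight_mode)
  sel <- is.finite(map$E) & map$valid
  if (!any(sel)) stop_bad("no valid efficiency pixels")
  wgt <- if (weight_mode == "photons") map$photons[sel] else rep(1, sum(sel))
  if (sum(wgt) == 0) stop_bad("zero total weight")
  list(weighted = sum(wgt * map$E[sel]) / sum(wgt),
       unweighted = mean(map$E[sel]),
       weight_mode = weight_mode, n_pixels = sum(sel))
}

#' FRET efficiency statistics within a region
#'
#' @param map an [efficiency_map()]
#' @param region logical matrix (e.g. a lamellipodium mask)
#' @return list: `weighted_mean`, `median`, `n_pixels`
#' @export
region_efficiency <- function(map, region) {
  if (!any(region)) stop_bad("empty region")
  sel <- region & is.finite(map$E) & map$valid
  if (!any(sel)) stop_bad("region contains no valid pixels")
  wgt <- map$photons[sel]
  list(weighted_mean = sum(wgt * map$E[sel]) / sum(wgt),
       median = stats::median(map$E[sel]), n_pixels = sum(sel))
}
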