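#' Structural similarity index (SSIM)
#'
#' Mean structural similarity between two equally sized images over an
#' 11x11 Gaussian-weighted sliding window (sigma 1.5) with the conventional
#' stabilization constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`. The window
#' mean is taken over the valid (fully overlapping) region. The dynamic
#' range `L` defaults to the permittivity design range 80 - 10 = 70, fixed
#' across cases so scores are comparable over a dataset.
#'
#' @param image,reference Numeric matrices of equal shape.
#' @param dynamic_range Dynamic range `L` of the data.
#' @param window Window side length (odd).
#' @param sigma Gaussian window standard deviation, pixels.
#' @return SSIM in \[-1, 1\]; 1 iff the images are identical.
#' @export
ssim <- function(image, reference, dynamic_range = 70, window = 11,
                 sigma = 1.5) {
  if (!all(dim(image) == dim(reference)))
    stop("image and reference must have identical shape", call. = FALSE)
  if (min(dim(image)) < window)
    stop("images smaller than the SSIM window", call. = FALSE)
  g <- exp(-((seq_len(window) - (window + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  # separable Gaussian filtering via banded matrices: valid region only
  band <- function(n) {
    K <- matrix(0, n, n - window + 1)
    for (q in seq_len(ncol(K))) K[q + seq_len(window) - 1, q] <- g
    K
  }
  Kr <- band(nrow(image)); Kc <- band(ncol(image))
  filt <- function(m) crossprod(Kr, m) %*% Kc
  mu1 <- filt(image); mu2 <- filt(reference)
  s11 <- filt(image^2) - mu1^2
  s22 <- filt(reference^2) - mu2^2
  s12 <- filt(image * reference) - mu1 * mu2
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  smap <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(smap)
}

#' Normalized root-mean-square error (NRMSE)
#'
#' RMSE between the images divided by the reference's value range
#' (max - min).
#'
#' @param image,reference Numeric matrices of equal shape; the reference
#'   must not be constant.
#' @return Nonnegative scalar.
#' @export
nrmse <- function(image, reference) {
  if (!all(dim(image) == dim(reference)))
    stop("image and reference must have identical shape", call. = FALSE)
  rng <- max(reference) - min(reference)
  if (rng == 0)
    stop("degenerate input: constant reference has zero value range",
         call. = FALSE)
  sqrt(mean((image - reference)^2)) / rng
}

#' Peak signal-to-noise ratio (PSNR)
#'
#' `20 log10(peak / RMSE)` in dB, with the peak taken as the reference's
#' value range. Identical images (zero RMSE) return a finite cap.
#'
#' @param image,reference Numeric matrices of equal shape.
#' @param cap Value returned for zero error, dB.
#' @return PSNR in dB.
#' @export
psnr <- function(image, reference, cap = 100) {
  if (!all(dim(image) == dim(reference)))
    stop("image and reference must have identical shape", call. = FALSE)
  rmse <- sqrt(mean((image - reference)^2))
  if (rmse == 0) return(cap)
  peak <- max(reference) - min(reference)
  min(20 * log10(peak / rmse), cap)
}

#' Evaluate reconstructions against ground truth
#'
#' @param predictions,references Lists of permittivity images (matrices),
#'   pairwise equal shapes.
#' @param case_ids Optional identifiers.
#' @param dynamic_range SSIM dynamic range, see [ssim()].
#' @return Data frame with columns `case_id`, `ssim`, `nrmse`, `psnr`.
#' @export
evaluate_cases <- function(predictions, references, case_ids = NULL,
                           dynamic_range = 70) {
  if (length(predictions) != length(references))
    stop("prediction and reference lists differ in length", call. = FALSE)
  if (is.null(case_ids)) case_ids <- sprintf("case_%05d",
                                             seq_along(predictions))
  data.frame(
    case_id = case_ids,
    ssim = mapply(ssim, predictions, references,
                  MoreArgs = list(dynamic_range = dynamic_range)),
    nrmse = mapply(nrmse, predictions, references),
    psnr = mapply(psnr, predictions, references))
}

#' Summarize per-case metrics
#'
#' Means, sample standard deviations, and the proportions meeting the
#' conventional acceptability thresholds (SSIM > 0.9, NRMSE < 0.2,
#' PSNR > 30 dB).
#'
#' @param records Data frame with columns `ssim`, `nrmse`, `psnr` (as from
#'   [evaluate_cases()]).
#' @return Object of class `eval_summary` (a list).
#' @export
summarize_metrics <- function(records) {
  if (NROW(records) == 0) stop("empty metric record list", call. = FALSE)
  one_sd <- function(x) if (length(x) > 1) sd(x) else 0
  s <- list(n_cases = nrow(records),
            ssim_mean = mean(records$ssim), ssim_sd = one_sd(records$ssim),
            ssim_gt_0.9 = mean(records$ssim > 0.9),
            nrmse_mean = mean(records$nrmse), nrmse_sd = one_sd(records$nrmse),
            nrmse_lt_0.2 = mean(records$nrmse < 0.2),
            psnr_mean = mean(records$psnr), psnr_sd = one_sd(records$psnr),
            psnr_gt_30 = mean(records$psnr > 30))
  class(s) <- "eval_summary"
  s
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("Evaluation over %d cases\n", x$n_cases))
  cat(sprintf("  SSIM : mean %.4f, sd %.4f, %5.1f%% > 0.9\n",
              x$ssim_mean, x$ssim_sd, 100 * x$ssim_gt_0.9))
  cat(sprintf("  NRMSE: mean %.4f, sd %.4f, %5.1f%% < 0.2\n",
              x$nrmse_mean, x$nrmse_sd, 100 * x$nrmse_lt_0.2))
  cat(sprintf("  PSNR : mean %.3f dB, sd %.3f, %5.1f%% > 30 dB\n",
              x$psnr_mean, x$psnr_sd, 100 * x$psnr_gt_30))
  invisible(x)
}
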