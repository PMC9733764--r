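#' Root-mean-square error between two images
#'
#' @param reference,test Numeric matrices (or [image_grid()]s) of identical
#'   shape.
#' @return `rmse`: the root mean squared difference; `psnr`: peak
#'   signal-to-noise ratio in dB with the reference dynamic range as peak;
#'   `ssim`: mean structural similarity (Gaussian 11x11 window, sigma 1.5,
#'   evaluated over the interior where the window fits).
#' @export
rmse <- function(reference, test) {
  a <- .as_values(reference); b <- .as_values(test)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean((a - b)^2))
}

.as_values <- function(x) if (inherits(x, "image_grid")) x$values else as.matrix(x)

#' @rdname rmse
#' @export
psnr <- function(reference, test) {
  a <- .as_values(reference); b <- .as_values(test)
  stopifnot(all(dim(a) == dim(b)))
  peak <- diff(range(a))
  if (peak == 0) peak <- 1
  m <- mean((a - b)^2)
  10 * log10(peak^2 / m)
}

# local Gaussian-weighted moments by separable convolution, valid region
.ssim_stats <- function(x, w) {
  half <- (length(w) - 1L) / 2L
  sm <- function(m) {
    m <- apply(m, 2, function(col) stats::filter(col, w, sides = 2))
    t(apply(t(m), 2, function(row) stats::filter(row, w, sides = 2)))
  }
  full <- sm(x)
  rows <- (half + 1):(nrow(x) - half)
  cols <- (half + 1):(ncol(x) - half)
  full[rows, cols]
}

#' @rdname rmse
#' @param dynamic_range Value range `L` entering the SSIM stabilizers
#'   (default: range of the reference).
#' @export
ssim <- function(reference, test, dynamic_range = NULL) {
  a <- .as_values(reference); b <- .as_values(test)
  stopifnot(all(dim(a) == dim(b)))
  if (min(dim(a)) < 11) stop("ssim: images must be at least 11 x 11")
  L <- if (is.null(dynamic_range)) diff(range(a)) else dynamic_range
  if (L == 0) L <- 1
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  g <- exp(-((-5:5)^2) / (2 * 1.5^2)); g <- g / sum(g)
  mu_a <- .ssim_stats(a, g); mu_b <- .ssim_stats(b, g)
  saa <- .ssim_stats(a * a, g) - mu_a^2
  sbb <- .ssim_stats(b * b, g) - mu_b^2
  sab <- .ssim_stats(a * b, g) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * sab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (saa + sbb + c2))
  mean(s)
}

#' Image-quality report
#'
#' Standard full-reference metrics of a reconstruction against its ground
#' truth, plus the noise level (standard deviation) inside an optional flat
#' region of interest.
#'
#' @param reference,test Numeric matrices or [image_grid()]s of equal shape.
#' @param roi Optional logical mask (same shape) selecting a flat region;
#'   the report then includes the test and reference standard deviations
#'   inside it.
#' @return An object of class `metrics_report`: a list with `rmse`, `psnr`,
#'   `ssim`, and (with `roi`) `noise_sd` and `noise_sd_ref`.
#' @export
metrics <- function(reference, test, roi = NULL) {
  a <- .as_values(reference); b <- .as_values(test)
  if (!all(dim(a) == dim(b))) stop("metrics: shape mismatch")
  rep <- list(rmse = rmse(a, b), psnr = psnr(a, b),
              ssim = if (min(dim(a)) >= 11) ssim(a, b) else NA_real_)
  if (!is.null(roi)) {
    roi <- as.logical(roi)
    rep$noise_sd <- sd(b[roi])
    rep$noise_sd_ref <- sd(a[roi])
  }
  structure(rep, class = "metrics_report")
}

#' @rawNamespace S3method(print, metrics_report)
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> RMSE %.4g | PSNR %.2f dB | SSIM %.4f",
              x$rmse, x$psnr, x$ssim))
  if (!is.null(x$noise_sd)) cat(sprintf(" | ROI sd %.4g", x$noise_sd))
  cat("\n")
  invisible(x)
}

#' Aggregate several metric reports
#'
#' @param reports A list of [metrics()] results.
#' @return A data frame with one row per report plus a `mean` row.
#' @export
metrics_table <- function(reports) {
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(rmse = r$rmse, psnr = r$psnr, ssim = r$ssim,
               noise_sd = if (is.null(r$noise_sd)) NA_real_ else r$noise_sd)
  }))
  rbind(df, data.frame(rmse = mean(df$rmse), psnr = mean(df$psnr),
                       ssim = mean(df$ssim),
                       noise_sd = mean(df$noise_sd),
                       row.names = "mean"))
}
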