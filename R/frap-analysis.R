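#' Translation drift correction by phase correlation
#'
#' Registers every frame of a stack to a reference frame by the integer
#' translation maximizing their circular cross-correlation (computed via
#' FFT), and shifts frames back accordingly. Rigid translation is an
#' adequate drift model for axon terminals at these timescales.
#'
#' @param stack numeric array (rows x cols x frames).
#' @param reference reference frame index.
#' @return list with `stack` (registered array) and `shifts` (data.frame
#'   frame, dy, dx: the translation applied to each frame to register it
#'   onto the reference).
#' @export
driftCorrect <- function(stack, reference = 1L) {
  d <- dim(stack)
  if (length(d) != 3L || d[3] < 2L)
    stop("driftCorrect needs a stack with >= 2 frames", call. = FALSE)
  ref <- stack[, , reference]
  Fref <- stats::fft(ref)
  shifts <- data.frame(frame = seq_len(d[3]), dy = 0L, dx = 0L)
  out <- stack
  for (k in seq_len(d[3])) {
    if (k == reference) next
    fr <- stack[, , k]
    if (stats::sd(fr) == 0 || stats::sd(ref) == 0) {
      warning(sprintf("frame %d is featureless; zero shift assumed", k))
      next
    }
    cc <- Re(stats::fft(Fref * Conj(stats::fft(fr)), inverse = TRUE))
    idx <- which.max(cc)
    dy <- (idx - 1L) %% d[1]; dx <- (idx - 1L) %/% d[1]
    if (dy > d[1] / 2) dy <- dy - d[1]
    if (dx > d[2] / 2) dx <- dx - d[2]
    shifts$dy[k] <- dy; shifts$dx[k] <- dx
    ## undo the drift (circular shift)
    out[, , k] <- fr[((seq_len(d[1]) - 1L - dy) %% d[1]) + 1L,
                     ((seq_len(d[2]) - 1L - dx) %% d[2]) + 1L]
  }
  list(stack = out, shifts = shifts)
}

#' Photobleaching correction by histogram matching
#'
#' Monotonically maps each frame's intensity histogram onto the reference
#' frame's histogram (rank-based exact specification), the standard
#' bleach-correction scheme for a channel whose underlying signal
#' distribution is stationary. Frames with zero variance are returned
#' unchanged (identity mapping).
#'
#' @param stack numeric array (rows x cols x frames).
#' @param reference reference frame index.
#' @return corrected array; corrected frame means equal the reference mean.
#' @export
bleachCorrect <- function(stack, reference = 1L) {
  d <- dim(stack)
  stopifnot(length(d) == 3L)
  refSorted <- sort(as.vector(stack[, , reference]))
  out <- stack
  for (k in seq_len(d[3])) {
    fr <- as.vector(stack[, , k])
    if (stats::sd(fr) == 0) next
    out[, , k] <- matrix(refSorted[rank(fr, ties.method = "first")],
                         d[1], d[2])
  }
  out
}

#' Normalize FRAP recovery
#'
#' Computes the background-corrected normalized recovery curve
#' R(t) = (F(t) - F0) / Fp, where F(t) is the mean post-bleach roi
#' intensity, F0 the mean intensity of the first post-bleach frame, and Fp
#' the mean pre-bleach roi intensity, each after subtracting the per-frame
#' mean over the background region. R(0) = 0 by construction, and R is
#' invariant to affine rescaling of the raw intensities.
#'
#' @param x a [FrapSeries-class].
#' @param ... unused.
#' @return data.frame with columns t_s and R, with attributes `Fp` and `F0`.
#' @rdname normalizeRecovery
#' @export
setMethod("normalizeRecovery", "FrapSeries", function(x, ...) {
  bgPre <- apply(x@preBleach, 3, function(f) mean(f[x@backgroundMask]))
  bgPost <- apply(x@postBleach, 3, function(f) mean(f[x@backgroundMask]))
  Fp <- mean(vapply(seq_len(dim(x@preBleach)[3]), function(k)
    mean(x@preBleach[, , k][x@roiMask]) - bgPre[k], numeric(1)))
  if (!is.finite(Fp) || Fp <= 0)
    stop("pre-bleach roi intensity must exceed the background", call. = FALSE)
  Ft <- vapply(seq_len(dim(x@postBleach)[3]), function(k)
    mean(x@postBleach[, , k][x@roiMask]) - bgPost[k], numeric(1))
  R <- (Ft - Ft[1]) / Fp
  structure(data.frame(t_s = x@tS, R = R), Fp = Fp, F0 = Ft[1])
})

#' Fit a single-exponential recovery
#'
#' Least-squares fit of R(t) = A (1 - exp(-t / tau)) with A in (0, 1] and
#' tau > 0, anchored at R(0) = 0. Initialization is multi-start over a tau
#' grid (tau profiles out to a linear amplitude fit); the best converged
#' start is returned.
#'
#' @param curve data.frame with t_s and R (see [normalizeRecovery()]).
#' @return list with model, parameters A and tau, sse, df, n, fitted values,
#'   and a `boundary` flag when A collapsed to ~0.
#' @export
fitRecoveryExponential <- function(curve) {
  t <- curve$t_s; y <- curve$R
  if (length(t) < 4L) stop("need >= 4 points to fit", call. = FALSE)
  span <- max(t) - min(t)
  tauGrid <- span * c(0.05, 0.15, 0.4, 1, 3)
  best <- NULL; tried <- character()
  for (tau0 in tauGrid) {
    A0 <- max(min(max(y), 1), 1e-3)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * (1 - exp(-t / tau)),
                        start = list(A = A0, tau = tau0),
                        lower = c(A = 1e-8, tau = 1e-6),
                        upper = c(A = 1, tau = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    tried <- c(tried, sprintf("(A=%.3g, tau=%.3g)", A0, tau0))
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) {
        cf <- stats::coef(fit)
        best <- list(model = "single_exponential", A = unname(cf["A"]),
                     tau = unname(cf["tau"]), sse = sse,
                     df = length(y) - 2L, n = length(y),
                     fitted = stats::fitted(fit))
      }
    }
  }
  if (is.null(best))
    stop("single-exponential fit did not converge; starts tried: ",
         paste(tried, collapse = ", "), call. = FALSE)
  best$boundary <- best$A <= 1e-6
  best
}

#' Fit a quadratic trend (for FVI time courses)
#'
#' Ordinary least squares of y = c0 + c1 t + c2 t^2.
#'
#' @param curve data.frame with t_s and either fvi or R as response.
#' @return list with model, coefficients c0, c1, c2, sse, df, n, fitted.
#' @export
fitFviQuadratic <- function(curve) {
  y <- if ("fvi" %in% names(curve)) curve$fvi else curve$R
  t <- curve$t_s
  ok <- is.finite(y)
  fit <- stats::lm(y[ok] ~ t[ok] + I(t[ok]^2))
  cf <- unname(stats::coef(fit))
  list(model = "quadratic", c0 = cf[1], c1 = cf[2], c2 = cf[3],
       sse = sum(stats::resid(fit)^2), df = sum(ok) - 3L, n = sum(ok),
       fitted = stats::fitted(fit))
}

#' Extra sum-of-squares F test between nested fits
#'
#' Compares a shared fit (one parameter set for all datasets) against
#' separate fits (parameters per dataset):
#' F = ((SSE_shared - SSE_sep) / (df_shared - df_sep)) / (SSE_sep / df_sep),
#' with the p value from the F distribution. The shared model must be nested
#' in the separate model.
#'
#' @param fitShared fit list (with sse and df) of the pooled fit.
#' @param fitsSeparate list of fit lists, one per dataset.
#' @return list with F, df1, df2, p.
#' @examples
#' # identical SSEs give F = 0, p = 1
#' extraSSFTest(list(sse = 2, df = 10),
#'              list(list(sse = 1, df = 4), list(sse = 1, df = 4)))
#' @export
extraSSFTest <- function(fitShared, fitsSeparate) {
  sseSep <- sum(vapply(fitsSeparate, `[[`, numeric(1), "sse"))
  dfSep <- sum(vapply(fitsSeparate, `[[`, numeric(1), "df"))
  sseSh <- fitShared$sse; dfSh <- fitShared$df
  if (dfSh <= dfSep)
    stop("shared fit must have more residual df than the separate fits",
         call. = FALSE)
  if (sseSep > sseSh * (1 + 1e-8))
    stop("separate fits have larger SSE than the shared fit; models are not nested",
         call. = FALSE)
  Fstat <- ((sseSh - sseSep) / (dfSh - dfSep)) / (sseSep / dfSep)
  list(F = Fstat, df1 = dfSh - dfSep, df2 = dfSep,
       p = stats::pf(Fstat, dfSh - dfSep, dfSep, lower.tail = FALSE))
}

popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Fluorescence variation index (FVI)
#'
#' FVI = SD(branch-mask pixels) / SD(shaft-mask pixels), with population
#' (n-denominator) standard deviations and branch pixels pooled across all
#' branches of the axon. Spatially uniform recovery yields FVI ~ 1; focal
#' recovery hotspots in branches yield FVI > 1.
#'
#' @param frame numeric matrix.
#' @param branchMask,shaftMask logical matrices (non-empty, disjoint).
#' @return the FVI value (NA with a warning when SD(shaft) = 0).
#' @examples
#' f <- rbind(c(0, 10), c(0, 5))
#' m1 <- rbind(c(TRUE, TRUE), c(FALSE, FALSE))
#' m2 <- !m1
#' computeFvi(f, m1, m2)  # SD 5 / SD 2.5 = 2
#' @export
computeFvi <- function(frame, branchMask, shaftMask) {
  stopifnot(any(branchMask), any(shaftMask))
  sdS <- popSd(frame[shaftMask])
  if (sdS == 0) { warning("SD over the shaft mask is 0; FVI undefined"); return(NA_real_) }
  popSd(frame[branchMask]) / sdS
}

#' FVI time course of a FRAP series
#'
#' Computes [computeFvi()] on every post-bleach frame. Acquisition-bleaching
#' correction by histogram matching can be applied first; it defaults to off
#' because remapping a recovering FRAP series onto the first post-bleach
#' frame's histogram would rescale the recovery signal itself (the histogram
#' method is intended for channels with a stationary intensity
#' distribution, such as the RNA channel).
#'
#' @param x a [FrapSeries-class].
#' @param bleachCorrect logical; match post-bleach histograms to the first
#'   post-bleach frame before computing FVI.
#' @param ... unused.
#' @return data.frame with t_s and fvi.
#' @rdname fviSeries
#' @export
setMethod("fviSeries", "FrapSeries", function(x, bleachCorrect = FALSE, ...) {
  stack <- x@postBleach
  if (bleachCorrect) stack <- axodyn::bleachCorrect(stack)
  fvi <- vapply(seq_len(dim(stack)[3]), function(k)
    computeFvi(stack[, , k], x@branchMask, x@shaftMask), numeric(1))
  data.frame(t_s = x@tS, fvi = fvi)
})
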