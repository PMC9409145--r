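# Quantitative pharmacology of the beta-arrestin recruitment assay:
# saturation binding with Hill slope, operational model of partial agonism
# (Black-Leff), Hill inhibition curves, and Bmax normalization.
#
# All fitters are deterministic: damped least squares (Levenberg-Marquardt)
# started from a fixed 5x5x3 grid in log-parameter space; the best SSE wins.

#' Dose-response table
#'
#' @param concentration_M positive agonist/antagonist concentrations (M).
#' @param response_RLU responses (relative luminescence units).
#' @param replicate_id optional replicate labels.
#' @return object of class \code{dose_response}.
#' @export
dose_response <- function(concentration_M, response_RLU, replicate_id = NULL) {
  if (length(concentration_M) != length(response_RLU))
    stop("concentration and response differ in length")
  if (any(concentration_M <= 0)) stop("concentrations must be positive")
  structure(list(concentration_M = as.numeric(concentration_M),
                 response_RLU = as.numeric(response_RLU),
                 replicate_id = replicate_id),
            class = "dose_response")
}

#' Read a delimited dose-response table
#'
#' Expects columns \code{concentration_M} and \code{response} (plus optional
#' \code{group} / \code{replicate}).
#'
#' @param path delimited file (tab or comma separated, sniffed).
#' @return data.frame with at least concentration_M and response.
#' @export
read_dose_response <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep)
  if (!all(c("concentration_M", "response") %in% names(df)))
    stop("table must have columns concentration_M and response")
  df
}

# model curves ---------------------------------------------------------------

#' Saturation-binding (Hill) model curve
#' @param x concentration (M).
#' @param Bmax,Kd,h parameters (Kd in M).
#' @return predicted specific binding.
#' @export
hill_binding_curve <- function(x, Bmax, Kd, h) {
  lx <- h * (log(x) - log(Kd))      # (x/Kd)^h, stable for tiny x
  r <- exp(lx)
  Bmax * r / (1 + r)
}

#' Operational-model (Black-Leff) response curve
#'
#' E(A) = Em tau^n A^n / ((KA + A)^n + tau^n A^n): response is a hyperbolic
#' function of occupancy with transducer slope n, efficacy tau and
#' functional affinity KA.
#'
#' @param A agonist concentration.
#' @param Em system maximal response.
#' @param tau efficacy.
#' @param KA functional affinity (same units as A).
#' @param n transducer slope.
#' @return predicted response.
#' @export
operational_curve <- function(A, Em, tau, KA, n) {
  num <- (tau * A)^n
  Em * num / ((KA + A)^n + num)
}

#' Hill inhibition curve
#' @param x antagonist concentration.
#' @param top,bottom plateau responses.
#' @param IC50 half-maximal inhibitory concentration.
#' @param s Hill slope of inhibition (> 0).
#' @return predicted response (monotone decreasing in x).
#' @export
inhibition_curve <- function(x, top, bottom, IC50, s = 1) {
  bottom + (top - bottom) / (1 + (x / IC50)^s)
}

# fitting machinery ----------------------------------------------------------

.check_fit_data <- function(x, y, min_doses) {
  if (length(unique(x)) < min_doses)
    stop("need >= ", min_doses, " distinct concentrations")
  if (diff(range(y)) == 0)
    stop("degenerate fit: all responses equal")
}

# Run Levenberg-Marquardt from every start; return the best parameter vector.
.multistart_lm <- function(resid_fn, starts) {
  best <- NULL; best_sse <- Inf
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                     ptol = 1e-14)
  for (p0 in starts) {
    fit <- tryCatch(minpack.lm::nls.lm(par = p0, fn = resid_fn,
                                       control = ctrl),
                    error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fn(fit$par)^2)
    if (is.finite(sse) && sse < best_sse) { best_sse <- sse; best <- fit$par }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  list(par = best, sse = best_sse)
}

.as_xy <- function(data) {
  if (inherits(data, "dose_response"))
    list(x = data$concentration_M, y = data$response_RLU)
  else if (is.data.frame(data))
    list(x = data$concentration_M,
         y = if (!is.null(data$response)) data$response else data$response_RLU)
  else stop("data must be a dose_response or data.frame")
}

#' Fit the saturation-binding Hill model
#'
#' Least-squares fit of B(x) = Bmax x^h / (Kd^h + x^h). Positivity of all
#' three parameters is enforced by fitting log10(Bmax), log10(Kd), log10(h);
#' the optimizer is started from a deterministic 5x5x3 grid (log10 Kd across
#' the dose range x Hill slopes {0.2, 0.5, 1, 2, 3} x Bmax multipliers
#' {0.5, 1, 2} of the maximal response).
#'
#' @param data a \code{dose_response} or data.frame with concentration_M and
#'   response columns (>= 4 distinct concentrations).
#' @return object of class \code{binding_fit}: Bmax (RLU), Kd (M), h,
#'   residual_sse.
#' @export
fit_binding_hill <- function(data) {
  d <- .as_xy(data); x <- d$x; y <- d$y
  .check_fit_data(x, y, 4)
  resid_fn <- function(p)
    y - hill_binding_curve(x, 10^p[1], 10^p[2], 10^p[3])
  lkd <- seq(min(log10(x)), max(log10(x)), length.out = 5)
  starts <- list()
  for (b in c(0.5, 1, 2)) for (k in lkd) for (h in c(0.2, 0.5, 1, 2, 3))
    starts[[length(starts) + 1L]] <- c(log10(max(abs(y)) * b), k, log10(h))
  fit <- .multistart_lm(resid_fn, starts)
  structure(list(Bmax = 10^fit$par[1], Kd = 10^fit$par[2], h = 10^fit$par[3],
                 residual_sse = fit$sse, n_obs = length(y)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> Bmax = %.4g RLU, Kd = %.4g M, h = %.4g (SSE %.4g)\n",
              x$Bmax, x$Kd, x$h, x$residual_sse))
  invisible(x)
}

#' Fit the operational model of partial agonism
#'
#' Least-squares fit of E(A) = Em tau^n A^n / ((KA + A)^n + tau^n A^n), the
#' Black-Leff operational model with transducer slope. tau, KA and n are
#' fitted as log10 quantities; Em is either fitted freely
#' (\code{Em_policy = "free"}) or held at a supplied shared value
#' (\code{Em_policy = "shared"}, e.g. the reference full agonist's maximum).
#' Starts: 5 log10-KA values across the dose range x 5 log10-tau values
#' {-1, 0, 0.5, 1, 2} x slopes {0.3, 1, 2}.
#'
#' @param data a \code{dose_response} or data.frame (>= 5 distinct doses).
#' @param Em_policy "free" or "shared".
#' @param Em the shared Em value (required when Em_policy = "shared").
#' @return object of class \code{operational_fit}: Em, tau, KA, n,
#'   residual_sse.
#' @export
fit_operational <- function(data, Em_policy = c("free", "shared"), Em = NULL) {
  Em_policy <- match.arg(Em_policy)
  d <- .as_xy(data); x <- d$x; y <- d$y
  .check_fit_data(x, y, 5)
  if (Em_policy == "shared" && is.null(Em))
    stop("Em must be supplied when Em_policy = 'shared'")
  lka <- seq(min(log10(x)), max(log10(x)), length.out = 5)
  ltau <- c(-1, 0, 0.5, 1, 2)
  lns <- log10(c(0.3, 1, 2))
  starts <- list()
  if (Em_policy == "free") {
    resid_fn <- function(p)
      y - operational_curve(x, 10^p[1], 10^p[2], 10^p[3], 10^p[4])
    for (k in lka) for (tt in ltau) for (nn in lns)
      starts[[length(starts) + 1L]] <-
        c(log10(max(abs(y)) * 1.2), tt, k, nn)
    fit <- .multistart_lm(resid_fn, starts)
    out <- list(Em = 10^fit$par[1], tau = 10^fit$par[2], KA = 10^fit$par[3],
                n = 10^fit$par[4], residual_sse = fit$sse)
  } else {
    resid_fn <- function(p)
      y - operational_curve(x, Em, 10^p[1], 10^p[2], 10^p[3])
    for (k in lka) for (tt in ltau) for (nn in lns)
      starts[[length(starts) + 1L]] <- c(tt, k, nn)
    fit <- .multistart_lm(resid_fn, starts)
    out <- list(Em = Em, tau = 10^fit$par[1], KA = 10^fit$par[2],
                n = 10^fit$par[3], residual_sse = fit$sse)
  }
  out$Em_policy <- Em_policy
  structure(out, class = "operational_fit")
}

#' @export
print.operational_fit <- function(x, ...) {
  cat(sprintf("<operational_fit> Em = %.4g, tau = %.4g, KA = %.4g, n = %.4g (SSE %.4g)\n",
              x$Em, x$tau, x$KA, x$n, x$residual_sse))
  invisible(x)
}

#' Fit a Hill inhibition (displacement) curve
#'
#' Least-squares fit of R(x) = bottom + (top - bottom)/(1 + (x/IC50)^s).
#' IC50 and s are fitted as log10 quantities; top/bottom are free. Data whose
#' response trend is not decreasing with concentration are flagged
#' (\code{monotone = FALSE}); the best fit is still returned.
#'
#' @param data a \code{dose_response} or data.frame (>= 4 distinct doses).
#' @param normalized_to optional scale (e.g. 100 for percent); stored on the
#'   result for report context.
#' @return object of class \code{inhibition_fit}: top, bottom, IC50 (M),
#'   slope, residual_sse, monotone.
#' @export
fit_inhibition <- function(data, normalized_to = NULL) {
  d <- .as_xy(data); x <- d$x; y <- d$y
  .check_fit_data(x, y, 4)
  resid_fn <- function(p)
    y - inhibition_curve(x, p[1], p[2], 10^p[3], 10^p[4])
  lic <- seq(min(log10(x)), max(log10(x)), length.out = 5)
  tb <- list(c(max(y), min(y)), c(max(y), 0),
             c(quantile(y, 0.9), quantile(y, 0.1)))
  starts <- list()
  for (b in tb) for (k in lic) for (s in c(0.5, 1, 2, 3, 5))
    starts[[length(starts) + 1L]] <- c(b[1], b[2], k, log10(s))
  fit <- .multistart_lm(resid_fn, starts)
  mono <- suppressWarnings(
    cor(log10(x), y, method = "spearman")) <= 0
  if (is.na(mono)) mono <- FALSE
  top <- fit$par[1]; bottom <- fit$par[2]
  if (top < bottom) { tmp <- top; top <- bottom; bottom <- tmp }
  structure(list(top = top, bottom = bottom, IC50 = 10^fit$par[3],
                 slope = 10^fit$par[4], residual_sse = fit$sse,
                 monotone = mono, normalized_to = normalized_to),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("<inhibition_fit> IC50 = %.4g M, top = %.4g, bottom = %.4g, slope = %.4g%s\n",
              x$IC50, x$top, x$bottom, x$slope,
              if (!x$monotone) " [non-monotone data flagged]" else ""))
  invisible(x)
}

#' Normalize maximal binding against a reference ligand
#'
#' Each Bmax is expressed as a percentage of the reference ligand's Bmax
#' (reference = 100 percent); percentages are rounded to one decimal in the
#' report column.
#'
#' @param fits a named list of \code{binding_fit}s, a named numeric vector of
#'   Bmax values, or a data.frame with columns label and Bmax.
#' @param reference_label name of the reference ligand (e.g. "apelin-13").
#' @return data.frame with columns label, Bmax, percent (exact) and
#'   percent_report (rounded to 1 decimal).
#' @export
normalize_bmax <- function(fits, reference_label) {
  if (is.data.frame(fits)) {
    labels <- fits$label; bmax <- fits$Bmax
  } else if (is.list(fits)) {
    labels <- names(fits)
    bmax <- vapply(fits, function(f)
      if (inherits(f, "binding_fit")) f$Bmax else as.numeric(f), numeric(1))
  } else {
    labels <- names(fits); bmax <- as.numeric(fits)
  }
  if (is.null(labels) || !reference_label %in% labels)
    stop("reference label '", reference_label, "' not present")
  ref <- bmax[match(reference_label, labels)]
  pct <- bmax / ref * 100
  data.frame(label = labels, Bmax = bmax, percent = pct,
             percent_report = round(pct, 1), row.names = NULL)
}
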