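#' Fit Michaelis-Menten steady-state parameters
#'
#' Nonlinear least squares for `v = kcat * E0 * S / (Km + S)` on initial
#' rates.  Starting values come from a Hanes-Woolf linearisation
#' (`S/v ~ S`), which amplifies low-S noise less than the double-reciprocal
#' plot; the optimiser works on `log(kcat)` and `log(Km)` so positivity is
#' structural.  Standard errors are delta-method transforms of the
#' log-parameter covariance from the Jacobian at the optimum.  Unweighted
#' residuals by default (no error model is assumed); `weighting = "inv_v2"`
#' weights by `1/v^2` for relative-error data.
#'
#' @param data a `kinetics_dataset` (see [simulate_kinetics()]) or a list
#'   with `substrate_conc` (uM), `velocity` (uM min^-1) and `enzyme_conc`
#'   (uM); at least 4 distinct substrate concentrations.
#' @param weighting `"none"` (default) or `"inv_v2"`.
#' @return an `mm_fit`: `kcat` (min^-1), `km` (uM), `efficiency`
#'   (`kcat/km`, min^-1 uM^-1), standard errors `kcat_se`, `km_se`,
#'   `efficiency_se`, `rss`, and `converged`.
#' @examples
#' d <- simulate_kinetics(2, 5, 0.1, c(1, 2, 5, 10, 20, 50))
#' fit_mm(d)
#' @export
fit_mm <- function(data, weighting = c("none", "inv_v2")) {
  weighting <- match.arg(weighting)
  S <- data$substrate_conc
  v <- data$velocity
  E0 <- data$enzyme_conc
  stopifnot(length(S) == length(v), all(S > 0), all(v >= 0), E0 > 0)
  if (length(unique(S)) < 4L)
    stop("need at least 4 distinct substrate concentrations")

  # Hanes-Woolf initialisation: S/v = Km/Vmax + S/Vmax
  pos <- v > 0
  hw <- stats::lm(I(S[pos] / v[pos]) ~ S[pos])
  slope <- unname(stats::coef(hw)[2])
  intercept <- unname(stats::coef(hw)[1])
  if (is.finite(slope) && slope > 0 && intercept > 0) {
    vmax0 <- 1 / slope
    km0 <- intercept / slope
  } else {               # degenerate linearisation; fall back to heuristics
    vmax0 <- max(v) * 1.2
    km0 <- stats::median(S)
  }
  start <- c(lkcat = log(vmax0 / E0), lkm = log(km0))

  w <- if (weighting == "inv_v2") 1 / pmax(v, max(v) * 1e-6)^2 else rep(1, length(v))
  df <- data.frame(S = S, v = v, w = w)
  fit <- try(minpack.lm::nlsLM(
    v ~ exp(lkcat) * E0 * S / (exp(lkm) + S),
    data = df, start = as.list(start), weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)

  if (inherits(fit, "try-error")) {
    return(structure(list(kcat = NA_real_, km = NA_real_,
                          efficiency = NA_real_, kcat_se = NA_real_,
                          km_se = NA_real_, efficiency_se = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          message = as.character(fit)), class = "mm_fit"))
  }

  co <- stats::coef(fit)
  kcat <- exp(co[["lkcat"]])
  km <- exp(co[["lkm"]])
  vc <- try(stats::vcov(fit), silent = TRUE)
  if (inherits(vc, "try-error") || anyNA(vc)) {
    vc <- matrix(NA_real_, 2, 2)
  }
  kcat_se <- kcat * sqrt(vc[1, 1])
  km_se <- km * sqrt(vc[2, 2])
  eff <- kcat / km
  eff_se <- eff * sqrt(vc[1, 1] + vc[2, 2] - 2 * vc[1, 2])

  if (all(S < km / 5) || all(S > km * 5))
    warning("substrate range does not bracket the fitted Km; ",
            "expect wide standard errors")

  structure(list(kcat = unname(kcat), km = unname(km),
                 efficiency = unname(eff),
                 kcat_se = unname(kcat_se), km_se = unname(km_se),
                 efficiency_se = unname(eff_se),
                 rss = sum(w * stats::residuals(fit)^2),
                 converged = fit$convInfo$isConv,
                 message = fit$convInfo$stopMessage),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("mm_fit: did not converge (", x$message, ")\n")
    return(invisible(x))
  }
  cat(sprintf("mm_fit: kcat = %.4g +/- %.2g min^-1, Km = %.4g +/- %.2g uM, kcat/Km = %.4g +/- %.2g min^-1 uM^-1\n",
              x$kcat, x$kcat_se, x$km, x$km_se, x$efficiency, x$efficiency_se))
  invisible(x)
}

#' Compare catalytic efficiencies of two fits
#'
#' Ratio of `kcat/Km` values with a delta-method standard error (relative
#' errors add in quadrature), the quantity used to say one substrate is
#' handled more efficiently than another.
#'
#' @param fit_a,fit_b converged `mm_fit` objects (numerator / denominator).
#' @return list with `ratio`, `ratio_se` and the two efficiencies.
#' @export
compare_efficiency <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "mm_fit"), inherits(fit_b, "mm_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged))
    stop("both fits must have converged")
  ratio <- fit_a$efficiency / fit_b$efficiency
  rel <- sqrt((fit_a$efficiency_se / fit_a$efficiency)^2 +
              (fit_b$efficiency_se / fit_b$efficiency)^2)
  list(ratio = ratio, ratio_se = ratio * rel,
       efficiency_a = fit_a$efficiency, efficiency_b = fit_b$efficiency)
}

#' Read a three-column kinetics TSV
#'
#' Columns `S_uM`, `v_uM_per_min`, `E_uM` (the enzyme concentration must be
#' constant over rows).
#'
#' @param path TSV file.
#' @return a `kinetics_dataset`.
#' @export
read_kinetics <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("S_uM", "v_uM_per_min", "E_uM") %in% names(df)))
  if (length(unique(df$E_uM)) != 1L)
    stop("enzyme concentration must be constant within one dataset")
  structure(list(substrate_conc = df$S_uM, velocity = df$v_uM_per_min,
                 enzyme_conc = df$E_uM[1], truth = NULL),
            class = "kinetics_dataset")
}

#' Write a kinetics dataset as TSV
#'
#' @param data a `kinetics_dataset`.
#' @param path output file.
#' @export
write_kinetics <- function(data, path) {
  utils::write.table(
    data.frame(S_uM = data$substrate_conc,
               v_uM_per_min = data$velocity,
               E_uM = data$enzyme_conc),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
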