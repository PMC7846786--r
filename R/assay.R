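# Quantitative assay models: four-parameter logistic (4PL) dose-response
# fitting (IC50, Hill coefficient) and the DLS-bead viscosity conversion.

#' Fit a four-parameter logistic dose-response curve
#'
#' Model: y = bottom + (top - bottom) / (1 + (x / IC50)^nH). Fitting is
#' least-squares (Levenberg-Marquardt) in a log-dose parameterisation for
#' conditioning; IC50 is estimated on the natural scale. At x = IC50 the
#' fitted curve equals (top + bottom) / 2 by construction.
#'
#' Default initialisation: top/bottom from the response extrema, IC50 from
#' the dose bracketing the half-maximal signal, nH = 1.
#'
#' @param data Data frame with dose and response columns.
#' @param dose,response Column names (strings; defaults `"dose"`,
#'   `"response"`). Doses must be positive and span the transition (>= 5
#'   points).
#' @param init Optional named list/vector overriding starting values
#'   (`top`, `bottom`, `ic50`, `hill`).
#' @return A `fourpl_fit` object; see [tidy.fourpl_fit()],
#'   [glance.fourpl_fit()], [predict.fourpl_fit()], [autoplot.fourpl_fit()].
#'   On non-convergence a warning is raised and partial estimates are
#'   returned with `converged = FALSE`.
#' @export
fit_4pl <- function(data, dose = "dose", response = "response", init = NULL) {
  x <- data[[dose]]; y <- data[[response]]
  if (length(x) < 5) abort("need at least 5 dose points")
  if (any(x <= 0)) abort("doses must be positive")
  ord <- order(x); x <- x[ord]; y <- y[ord]
  lx <- log(x)

  top0 <- max(y); bot0 <- min(y)
  half <- (top0 + bot0) / 2
  # dose bracketing half-maximal signal (responses may run either direction)
  i <- which.min(abs(y - half))
  start <- list(top = top0, bottom = bot0, lic50 = lx[i], hill = 1)
  if (!is.null(init)) {
    init <- as.list(init)
    for (nm in intersect(names(init), c("top", "bottom", "hill"))) start[[nm]] <- init[[nm]]
    if (!is.null(init$ic50)) start$lic50 <- log(init$ic50)
  }

  df <- data.frame(lx = lx, y = y)
  run <- function(st) tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + exp(hill * (lx - lic50))),
      data = df, start = st,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  # unless the caller fixed the Hill start, try both slope signs and keep
  # the better least-squares solution (rising and falling curves)
  starts <- if (is.null(init$hill)) {
    list(start, utils::modifyList(start, list(hill = -1)))
  } else list(start)
  fits <- purrr::map(starts, run)
  ok <- purrr::map_lgl(fits, ~ !inherits(.x, "error"))
  fit <- if (any(ok)) {
    cand <- fits[ok]
    cand[[which.min(purrr::map_dbl(cand, ~ sum(stats::residuals(.x)^2)))]]
  } else fits[[1]]
  if (inherits(fit, "error")) {
    warn(sprintf("4PL fit did not converge (%s); returning initial estimates",
                 conditionMessage(fit)))
    est <- c(top = start$top, bottom = start$bottom,
             ic50 = exp(start$lic50), hill = start$hill)
    rss <- sum((y - .fourpl(x, est))^2)
    return(new_fourpl(est, rss, FALSE, tibble(dose = x, response = y), NULL))
  }
  cf <- coef(fit)
  # the logistic in log-dose with exp(hill*(lx - lic50)) equals
  # (x/ic50)^hill, so hill keeps its sign convention. The model is invariant
  # under (top, bottom, hill) -> (bottom, top, -hill); report the canonical
  # representation with top >= bottom (hill > 0 = falling curve).
  est <- c(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
           ic50 = exp(unname(cf["lic50"])), hill = unname(cf["hill"]))
  swapped <- est[["top"]] < est[["bottom"]]
  if (swapped) {
    est <- c(top = est[["bottom"]], bottom = est[["top"]],
             ic50 = est[["ic50"]], hill = -est[["hill"]])
  }
  rss <- sum(stats::residuals(fit)^2)
  new_fourpl(est, rss, TRUE, tibble(dose = x, response = y), fit, swapped)
}

.fourpl <- function(x, p) {
  p[["bottom"]] + (p[["top"]] - p[["bottom"]]) / (1 + (x / p[["ic50"]])^p[["hill"]])
}

new_fourpl <- function(est, rss, converged, data, fit, swapped = FALSE) {
  structure(list(coefficients = est, rss = rss, converged = converged,
                 data = data, fit = fit, swapped = swapped),
            class = "fourpl_fit")
}

#' @export
coef.fourpl_fit <- function(object, ...) object$coefficients

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<4PL fit%s: top %.4g, bottom %.4g, IC50 %.4g, Hill %.3f (rss %.3g)>\n",
    if (x$converged) "" else " [not converged]",
    x$coefficients["top"], x$coefficients["bottom"],
    x$coefficients["ic50"], x$coefficients["hill"], x$rss))
  invisible(x)
}

#' Predict from a 4PL fit
#'
#' @param object A `fourpl_fit`.
#' @param newdata Optional data frame with a `dose` column (or numeric vector
#'   of doses); defaults to the fitted doses.
#' @param ... Unused.
#' @return Numeric vector of fitted responses.
#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$dose
  else if (is.numeric(newdata)) newdata
  else newdata$dose
  .fourpl(x, object$coefficients)
}

#' Tidy a 4PL fit
#'
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (and `std.error` where the underlying
#'   least-squares fit converged; IC50's standard error is delta-method
#'   transformed from the log scale).
#' @export
tidy.fourpl_fit <- function(x, ...) {
  out <- tibble(term = names(x$coefficients),
                estimate = unname(x$coefficients))
  if (!is.null(x$fit)) {
    se <- summary(x$fit)$coefficients[, "Std. Error"]
    se_top <- unname(se[if (isTRUE(x$swapped)) "bottom" else "top"])
    se_bot <- unname(se[if (isTRUE(x$swapped)) "top" else "bottom"])
    se_nat <- c(top = se_top, bottom = se_bot,
                ic50 = unname(se["lic50"]) * x$coefficients[["ic50"]],
                hill = unname(se["hill"]))
    out$std.error <- unname(se_nat[out$term])
  }
  out
}

#' Glance at a 4PL fit
#'
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @return One-row tibble: `nobs`, `rss`, `sigma`, `converged`.
#' @export
glance.fourpl_fit <- function(x, ...) {
  n <- nrow(x$data)
  tibble(nobs = n, rss = x$rss,
         sigma = sqrt(x$rss / max(1, n - 4)), converged = x$converged)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Viscosity from DLS bead measurements
#'
#' Converts the apparent hydrodynamic radius of tracer beads measured by
#' dynamic light scattering into solution viscosity: eta = eta0 * (rh /
#' rh0), where eta0 is the solvent viscosity and rh0 the bead radius in
#' water.
#'
#' @param eta0 Solvent viscosity (cP).
#' @param rh Apparent bead hydrodynamic radius in the sample (nm).
#' @param rh0 Bead hydrodynamic radius in water (nm).
#' @return Tibble `eta0`, `rh`, `rh0`, `eta` (cP); vectorised.
#' @export
viscosity_from_dls <- function(eta0, rh, rh0) {
  if (any(eta0 <= 0) || any(rh <= 0) || any(rh0 <= 0)) {
    abort("all inputs must be positive")
  }
  tibble(eta0 = eta0, rh = rh, rh0 = rh0, eta = eta0 * (rh / rh0))
}
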