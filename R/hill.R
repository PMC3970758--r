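#' Hill model for EMSA free and bound fractions
#'
#' The two simultaneous band-fraction equations of a cooperative binding
#' isotherm: at protein concentration c,
#' `frac_free = K^h / (K^h + c^h)` and `frac_bound = c^h / (K^h + c^h)`,
#' where `K` is the half-binding concentration and `h` the Hill
#' coefficient. The two fractions sum to one exactly.
#'
#' @param conc Protein concentrations (uM), >= 0.
#' @param k_half Half-binding concentration (uM), > 0.
#' @param h Hill coefficient, > 0.
#' @return A tibble with columns `conc`, `frac_free`, `frac_bound`.
#' @examples
#' hill_model(6.8, k_half = 6.8, h = 2) # (0.5, 0.5) at c = K
#' @export
hill_model <- function(conc, k_half, h) {
  if (!is.finite(k_half) || k_half <= 0 || !is.finite(h) || h <= 0) {
    rlang::abort("k_half and h must be positive", class = "rg_domain_error")
  }
  conc <- as.numeric(conc)
  if (any(conc < 0)) {
    rlang::abort("concentrations must be >= 0", class = "rg_domain_error")
  }
  # compute in a ratio form that is stable for large c^h
  ratio <- (conc / k_half)^h
  bound <- ratio / (1 + ratio)
  bound[is.infinite(ratio)] <- 1
  tibble::tibble(conc = conc, frac_free = 1 - bound, frac_bound = bound)
}

#' Fit the Hill model to an EMSA titration
#'
#' Joint nonlinear least squares over the free and bound residuals
#' simultaneously (both bands weighted equally), via Levenberg-Marquardt
#' with box bounds. Initial values: `k_half` at the concentration whose
#' free fraction is nearest 0.5, `h = 1`; bounds keep `k_half > 0` and
#' `h` in (0.1, 10] (sparse ladders do not constrain larger exponents).
#'
#' @param series Data frame with columns `conc`, `frac_free`, `frac_bound`
#'   (fractions of the no-protein lane intensity), or `conc`, `i_free`,
#'   `i_bound` raw band intensities, which are normalized by the
#'   zero-concentration lane (required in that dialect).
#' @param h_bounds Allowed Hill coefficient range, default `c(0.1, 10)`.
#' @return A list of class `rg_hill_fit`: `k_half` (uM), `h`, `rss`,
#'   `converged`, `n`, `data` (the normalized series), `message`.
#' @export
fit_titration <- function(series, h_bounds = c(0.1, 10)) {
  series <- normalize_titration(series)
  pos <- series[series$conc > 0, , drop = FALSE]
  if (length(unique(pos$conc)) < 3) {
    rlang::abort("need >= 3 distinct positive concentrations",
      class = "rg_precondition_error"
    )
  }
  if (all(pos$frac_bound > 0.95) || all(pos$frac_bound < 0.05)) {
    rlang::abort("degenerate titration: no binding transition in range",
      class = "rg_precondition_error"
    )
  }
  k0 <- pos$conc[which.min(abs(pos$frac_free - 0.5))]
  resid_fun <- function(par) {
    m <- hill_model(series$conc, par[1], par[2])
    c(series$frac_free - m$frac_free, series$frac_bound - m$frac_bound)
  }
  fit <- minpack.lm::nls.lm(
    par = c(k_half = k0, h = 1),
    fn = resid_fun,
    lower = c(1e-6, h_bounds[1]),
    upper = c(1e6, h_bounds[2]),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  converged <- fit$info %in% 1:4
  structure(
    list(
      k_half = unname(fit$par[1]),
      h = unname(fit$par[2]),
      rss = sum(fit$fvec^2),
      converged = converged,
      n = nrow(series),
      data = series,
      message = fit$message
    ),
    class = "rg_hill_fit"
  )
}

normalize_titration <- function(series) {
  series <- tibble::as_tibble(series)
  if (all(c("frac_free", "frac_bound") %in% names(series))) {
    out <- series[, c("conc", "frac_free", "frac_bound")]
  } else if (all(c("i_free", "i_bound") %in% names(series))) {
    i0 <- series$i_free[series$conc == 0]
    if (length(i0) != 1 || !is.finite(i0) || i0 <= 0) {
      rlang::abort("raw-intensity tables need one zero-concentration lane",
        class = "rg_type_error"
      )
    }
    out <- tibble::tibble(
      conc = series$conc,
      frac_free = series$i_free / i0,
      frac_bound = series$i_bound / i0
    )
  } else {
    rlang::abort(
      "need columns conc + frac_free/frac_bound or conc + i_free/i_bound",
      class = "rg_type_error"
    )
  }
  if (any(out$conc < 0) || any(!is.finite(out$frac_free)) ||
    any(!is.finite(out$frac_bound))) {
    rlang::abort("invalid titration values", class = "rg_type_error")
  }
  out
}

#' K_half fold change between two fits
#'
#' Ratio of half-binding concentrations, mutant over wild type: a 25-fold
#' binding reduction reads as `k_half` 25 times the wild-type value.
#'
#' @param mutant,wildtype Converged `rg_hill_fit` objects.
#' @return Dimensionless ratio.
#' @export
fold_change <- function(mutant, wildtype) {
  for (f in list(mutant, wildtype)) {
    if (!inherits(f, "rg_hill_fit") || !isTRUE(f$converged)) {
      rlang::abort("fold_change needs two converged fits", class = "rg_type_error")
    }
  }
  mutant$k_half / wildtype$k_half
}

#' @export
print.rg_hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: K_half = %.3g uM, h = %.3g (rss %.3g, %s, n = %d)\n",
    x$k_half, x$h, x$rss,
    if (x$converged) "converged" else "NOT converged", x$n
  ))
  invisible(x)
}

#' Tidy a Hill fit
#' @param x An `rg_hill_fit`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`).
#' @method tidy rg_hill_fit
#' @export
tidy.rg_hill_fit <- function(x, ...) {
  tibble::tibble(term = c("k_half", "h"), estimate = c(x$k_half, x$h))
}

#' One-row summary of a Hill fit
#' @param x An `rg_hill_fit`.
#' @param ... Unused.
#' @return Tibble with `k_half`, `h`, `rss`, `converged`, `n`.
#' @method glance rg_hill_fit
#' @export
glance.rg_hill_fit <- function(x, ...) {
  tibble::tibble(
    k_half = x$k_half, h = x$h, rss = x$rss,
    converged = x$converged, n = x$n
  )
}

#' Plot a titration and its Hill fit
#'
#' @param object An `rg_hill_fit`.
#' @param ... Unused.
#' @return A ggplot of free/bound fractions vs concentration (log x) with
#'   the fitted curves.
#' @method autoplot rg_hill_fit
#' @export
autoplot.rg_hill_fit <- function(object, ...) {
  obs <- tidyr::pivot_longer(object$data, c("frac_free", "frac_bound"),
    names_to = "band", values_to = "fraction"
  )
  pos <- object$data$conc[object$data$conc > 0]
  grid <- exp(seq(log(min(pos) / 3), log(max(pos) * 3), length.out = 200))
  curve <- hill_model(grid, object$k_half, object$h) |>
    tidyr::pivot_longer(c("frac_free", "frac_bound"),
      names_to = "band", values_to = "fraction"
    )
  ggplot2::ggplot(
    obs[obs$conc > 0, ],
    ggplot2::aes(.data$conc, .data$fraction, color = .data$band)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "[protein] (µM)", y = "band fraction",
      title = sprintf(
        "Hill fit: K_half = %.3g µM, h = %.2g",
        object$k_half, object$h
      )
    )
}
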