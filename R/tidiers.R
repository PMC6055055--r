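# broom-style tidiers for the fitted objects.

#' Tidy and glance methods for canopy fits
#'
#' `tidy()` returns one row per parameter with estimate and standard
#' error; `glance()` returns one-row fit diagnostics (residual SD, n,
#' convergence).
#'
#' @param x A `respiration_fit`, `light_extinction_fit`,
#'   `nitrogen_profile_fit` or `kn_lai_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name canopyflux-tidiers
NULL

tidy_nls <- function(fit) {
  co <- summary(fit)$coefficients
  tibble(term = rownames(co), estimate = co[, "Estimate"],
         std.error = co[, "Std. Error"],
         statistic = co[, "t value"], p.value = co[, "Pr(>|t|)"])
}

glance_nls <- function(fit, n) {
  s <- summary(fit)
  tibble(sigma = s$sigma, df.residual = s$df[2], nobs = n,
         converged = fit$convInfo$isConv %||% TRUE)
}

#' @rdname canopyflux-tidiers
#' @export
tidy.respiration_fit <- function(x, ...) {
  out <- tidy_nls(x$fit)
  out$term <- c("rc25", "erc")
  out
}

#' @rdname canopyflux-tidiers
#' @export
glance.respiration_fit <- function(x, ...) glance_nls(x$fit, x$n)

#' @rdname canopyflux-tidiers
#' @export
tidy.light_extinction_fit <- function(x, ...) tidy_nls(x$fit)

#' @rdname canopyflux-tidiers
#' @export
glance.light_extinction_fit <- function(x, ...) glance_nls(x$fit, x$n)

#' @rdname canopyflux-tidiers
#' @export
tidy.nitrogen_profile_fit <- function(x, ...) {
  tibble(term = c("sln0", "kn"),
         estimate = c(x$sln0, x$kn),
         std.error = c(x$se_sln0, x$se_kn))
}

#' @rdname canopyflux-tidiers
#' @export
glance.nitrogen_profile_fit <- function(x, ...) {
  df_res <- x$n - 2
  tibble(sigma = sqrt(x$fit$deviance / max(df_res, 1)),
         df.residual = df_res, nobs = x$n,
         converged = x$fit$info %in% 1:4)
}

#' @rdname canopyflux-tidiers
#' @export
tidy.kn_lai_fit <- function(x, ...) {
  out <- tidy_nls(x$fit)
  out$term <- c("c", "d")
  out
}

#' @rdname canopyflux-tidiers
#' @export
glance.kn_lai_fit <- function(x, ...) glance_nls(x$fit, x$n)

#' @export
print.respiration_fit <- function(x, ...) {
  cat(sprintf("<respiration_fit> Rc25 %.3f umol m-2 s-1, ERc %.0f J mol-1 (n = %d)\n",
              x$params$rc25, x$params$erc, x$n))
  invisible(x)
}

#' @export
print.light_extinction_fit <- function(x, ...) {
  cat(sprintf("<light_extinction_fit> kL %.3f +/- %.3f m2 m-2 (n = %d)\n",
              x$kl, x$se, x$n))
  invisible(x)
}

#' @export
print.nitrogen_profile_fit <- function(x, ...) {
  cat(sprintf("<nitrogen_profile_fit> SLN0 %.3f +/- %.3f, kn %.3f +/- %.3f (on %s)\n",
              x$sln0, x$se_sln0, x$kn, x$se_kn, x$on))
  invisible(x)
}

#' @export
print.kn_lai_fit <- function(x, ...) {
  cat(sprintf("<kn_lai_fit> kn = %.3f exp(-%.3f LAI) (n = %d)\n",
              x$c, x$d, x$n))
  invisible(x)
}
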