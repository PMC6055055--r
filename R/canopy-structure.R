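# Canopy structure fits: Beer's-law light extinction, the exponential
# specific-leaf-nitrogen profile (via its cumulative-N integral), and the
# empirical decline of the nitrogen extinction coefficient with canopy
# size. All fits are ordinary least squares on untransformed values, so
# the error structure at low light / low N is preserved rather than being
# inflated by a log transform.

#' Fit the light extinction coefficient
#'
#' Nonlinear least-squares fit of Beer's law, `I_i/I_0 = exp(-kL LAI_i)`,
#' to layered (cumulative LAI, relative light) measurements. Because only
#' the ratio `I_i/I_0` enters, the estimate is invariant to any uniform
#' scaling of the light readings.
#'
#' @param profile A `profile_table` (or any data frame) with columns `lai`
#'   and `rel_light`; at least two layers with distinct `lai`.
#' @return A `light_extinction_fit` with `kl`, its standard error, and the
#'   underlying `nls` object.
#' @examples
#' pr <- generate_canopy_profile(sln0 = 2, kn = 0.4, kl = 0.96, lai_total = 3)
#' fit_kl(pr)$kl
#' @export
fit_kl <- function(profile) {
  if (!all(c("lai", "rel_light") %in% names(profile))) {
    abort("fit_kl: need columns lai and rel_light")
  }
  if (any(profile$rel_light <= 0)) {
    abort("fit_kl: relative light must be positive")
  }
  if (length(unique(profile$lai)) < 2) {
    abort("fit_kl: at least two distinct LAI depths are required")
  }
  start_kl <- -coef(stats::lm(log(rel_light) ~ 0 + lai, data = profile))[[1]]
  fit <- minpack.lm::nlsLM(rel_light ~ exp(-kl * lai), data = profile,
                           start = list(kl = max(start_kl, 0.1)),
                           lower = c(kl = 1e-4))
  structure(list(kl = coef(fit)[["kl"]],
                 se = summary(fit)$coefficients["kl", "Std. Error"],
                 fit = fit, n = nrow(profile)),
            class = "light_extinction_fit")
}

#' Fit the canopy nitrogen profile
#'
#' Fits the cumulative-nitrogen form of the exponential specific-leaf-
#' nitrogen profile, `N_i = SLN0 (1 - exp(-kn LAI_i)) / kn`, to layered
#' (cumulative LAI, cumulative N) measurements. The uniform-profile limit
#' is continuous: as kn -> 0 the model tends to `N_i = SLN0 LAI_i`, and
#' the implementation switches to that series expansion below kn = 1e-8.
#' Alternatively (`on = "sln"`) the per-layer form
#' `SLN_i = SLN0 exp(-kn LAI_i)` is fitted directly.
#'
#' @param profile Data frame with columns `lai` and `n_cum` (and `sln`
#'   when `on = "sln"`); at least three layers.
#' @param on Fit the cumulative integral (`"n_cum"`, default) or the
#'   per-layer SLN decline (`"sln"`).
#' @return A `nitrogen_profile_fit` with `sln0`, `kn`, standard errors and
#'   the `nls` object.
#' @export
fit_nitrogen_profile <- function(profile, on = c("n_cum", "sln")) {
  on <- match.arg(on)
  need <- c("lai", if (on == "n_cum") "n_cum" else "sln")
  if (!all(need %in% names(profile))) {
    abort(paste0("fit_nitrogen_profile: need columns ",
                 paste(need, collapse = ", ")))
  }
  if (nrow(profile) < 3) abort("fit_nitrogen_profile: need at least 3 layers")
  if (on == "n_cum" && any(diff(profile$n_cum[order(profile$lai)]) <= 0)) {
    abort("fit_nitrogen_profile: cumulative N must increase with depth")
  }
  # (1 - exp(-kn lai)) / kn written as lai * (-expm1(-x)/x), with the
  # series limit at x -> 0, so the model and its residuals stay smooth
  # through kn = 0 when a uniform profile puts the optimum on the
  # boundary. Levenberg-Marquardt on the raw residuals (nls.lm) handles
  # that boundary where the nls-object wrapper cannot.
  n_model <- function(lai, sln0, kn) {
    x <- kn * lai
    f <- ifelse(x < 1e-12, 1 - x / 2 + x^2 / 6, -expm1(-x) / pmax(x, 1e-300))
    sln0 * lai * f
  }
  y <- profile[[need[2]]]
  pred <- if (on == "n_cum") {
    function(p) n_model(profile$lai, p[1], p[2])
  } else {
    function(p) p[1] * exp(-p[2] * profile$lai)
  }
  start <- c(sln0 = max(y) / if (on == "n_cum") max(profile$lai) else 1,
             kn = 0.3)
  res <- minpack.lm::nls.lm(par = start,
                            fn = function(p) y - pred(p),
                            lower = c(1e-3, 0), upper = c(50, 10),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!res$info %in% 1:4) {
    abort(paste0("fit_nitrogen_profile: fit did not converge (",
                 res$message, ")"))
  }
  # standard errors from an absolute-step Jacobian: the relative-step one
  # inside the LM machinery degenerates when kn converges to the boundary
  se <- lm_std_errors(res$par, pred, y)
  structure(list(sln0 = res$par[["sln0"]], kn = res$par[["kn"]],
                 se_sln0 = se[[1]], se_kn = se[[2]],
                 on = on, fit = res, n = nrow(profile)),
            class = "nitrogen_profile_fit")
}

# Gauss-Newton standard errors with a fixed absolute finite-difference
# step; returns NA where the information matrix is numerically singular
lm_std_errors <- function(par, pred, y, h = 1e-6) {
  p <- as.numeric(par)
  f0 <- pred(p)
  jac <- vapply(seq_along(p), function(k) {
    pk <- p
    pk[k] <- pk[k] + h
    (pred(pk) - f0) / h
  }, numeric(length(y)))
  df_res <- max(length(y) - length(p), 1)
  s2 <- sum((y - f0)^2) / df_res
  cv <- tryCatch(s2 * solve(crossprod(jac)),
                 error = function(e) matrix(NA_real_, length(p), length(p)))
  sqrt(pmax(diag(cv), 0))
}

#' Empirical decline of the nitrogen extinction coefficient with LAI
#'
#' In closed, large canopies nitrogen is distributed more uniformly than
#' light, so the fitted nitrogen extinction coefficient kn falls towards
#' zero as LAI grows, approaching the (LAI-independent) light extinction
#' coefficient only in small canopies. `fit_kn_lai()` fits the
#' two-parameter decaying exponential `kn = c exp(-d LAI)` to (LAI, kn)
#' pairs; `kn_from_lai()` evaluates a fitted or configured relation,
#' clipping the result to `(0, kl_dif]`.
#'
#' @param pairs Data frame with columns `lai` and `kn` (>= 3 rows).
#' @return `fit_kn_lai()`: a `kn_lai_fit` with `c`, `d`, standard errors
#'   and the `nls` object.
#' @export
fit_kn_lai <- function(pairs) {
  if (!all(c("lai", "kn") %in% names(pairs))) {
    abort("fit_kn_lai: need columns lai and kn")
  }
  if (nrow(pairs) < 3) abort("fit_kn_lai: need at least 3 (LAI, kn) pairs")
  fit <- minpack.lm::nlsLM(kn ~ c0 * exp(-d0 * lai), data = pairs,
                           start = list(c0 = max(pairs$kn), d0 = 0.5),
                           lower = c(c0 = 1e-4, d0 = 0))
  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(c = est[["c0"]], d = est[["d0"]],
                 se_c = se[["c0"]], se_d = se[["d0"]], fit = fit,
                 n = nrow(pairs)),
            class = "kn_lai_fit")
}

#' @rdname fit_kn_lai
#' @param lai Leaf area index at which to evaluate kn (> 0).
#' @param relation A `kn_lai_fit`, or a list with elements `c` and `d`.
#' @param kl_dif Upper clip for kn: nitrogen cannot be distributed more
#'   steeply than light in this analysis.
#' @return `kn_from_lai()`: kn, m^2 m^-2, in `(0, kl_dif]`.
#' @export
kn_from_lai <- function(lai, relation, kl_dif = 0.96) {
  if (missing(relation) || is.null(relation$c) || is.null(relation$d)) {
    abort("kn_from_lai: no fitted or configured kn-LAI relation supplied")
  }
  stopifnot(all(lai > 0), kl_dif > 0)
  pmin(pmax(relation$c * exp(-relation$d * lai), 1e-9), kl_dif)
}

#' Normalize ceptometer light readings to an overhead sun
#'
#' Below-canopy light transmission read at solar zenith angle `zenith` is
#' converted to its zenith-0 equivalent assuming beam path length scales
#' with `1/cos(zenith)`: `tau_0 = tau^(cos(zenith))`. Inputs already
#' normalized (zenith = 0 or `NULL`) pass through unchanged.
#'
#' @param rel_light Measured relative light `I_i/I_0` in (0, 1].
#' @param zenith Solar zenith angle at measurement, degrees, or `NULL`.
#' @return Zenith-normalized relative light.
#' @export
normalize_zenith <- function(rel_light, zenith = NULL) {
  stopifnot(all(rel_light > 0), all(rel_light <= 1))
  if (is.null(zenith) || all(zenith == 0)) return(rel_light)
  stopifnot(all(zenith >= 0), all(zenith < 90))
  rel_light^cos(zenith * pi / 180)
}
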