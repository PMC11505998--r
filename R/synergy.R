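#' Fit the median-effect model to single-agent dose-response points
#'
#' Linearizes the median-effect equation `fa/(1-fa) = (D/Dm)^m` as
#' `log10(fa/(1-fa)) = m log10(D) - m log10(Dm)` and fits it by ordinary
#' least squares. Points with fa outside the clip window are excluded with a
#' warning (fa = 0 or 1 carries no information on the median-effect line).
#'
#' @param dose doses in nM (> 0).
#' @param fa fraction-affected values in \[0, 1\].
#' @param clip usable fa window; points outside are dropped with a warning.
#' @return object of class `median_effect_fit`: `dm` (median-effect dose,
#'   nM), `m` (shape), `r` (Pearson correlation of the linearized points),
#'   `n_points`.
#' @export
fit_median_effect <- function(dose, fa, clip = c(0.01, 0.99)) {
  stopifnot(length(dose) == length(fa))
  usable <- is.finite(dose) & dose > 0 & fa > clip[1] & fa < clip[2]
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with fa outside (", clip[1], ", ",
            clip[2], ") or dose <= 0 excluded from median-effect fit")
  }
  dose <- dose[usable]; fa <- fa[usable]
  if (length(dose) < 3) stop("at least 3 usable points with fa strictly inside (0, 1) required")
  if (stats::sd(fa) == 0) stop("all fa values identical; median-effect fit undefined")
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  ft <- stats::lm(y ~ x)
  m <- unname(stats::coef(ft)[2])
  if (!is.finite(m) || m <= 0) stop("median-effect slope not positive; check input orientation")
  dm <- 10^(-unname(stats::coef(ft)[1]) / m)
  structure(list(dm = dm, m = m, r = stats::cor(x, y),
                 n_points = length(dose)),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("Median-effect fit: Dm = %.4g nM, m = %.3f, r = %.4f (n = %d)\n",
              x$dm, x$m, x$r, x$n_points))
  invisible(x)
}

#' @export
coef.median_effect_fit <- function(object, ...) {
  c(dm = object$dm, m = object$m)
}

#' @export
predict.median_effect_fit <- function(object, dose, ...) {
  ifelse(dose <= 0, 0, 1 / (1 + (object$dm / dose)^object$m))
}

# dose of a single agent producing fraction-affected fa
dose_for_fa <- function(fit, fa) fit$dm * (fa / (1 - fa))^(1 / fit$m)

#' Chou-Talalay combination index at a combination dose point
#'
#' Two-term (mutually exclusive) form:
#' `CI = dose_a / Dx_a + dose_b / Dx_b`, where `Dx_i = Dm_i
#' (fa/(1-fa))^(1/m_i)` is the dose of drug i alone producing the observed
#' combination effect fa. CI < 1 indicates synergism, CI = 1 additivity
#' (labelled within a tolerance band), CI > 1 antagonism. CI is undefined at
#' fa = 0 (no inhibition) or fa = 1 (complete inhibition).
#'
#' @param dose_a,dose_b combination doses (nM).
#' @param fa observed fraction affected at the combination, in (0, 1).
#' @param fit_a,fit_b single-agent [fit_median_effect()] results.
#' @param additive_tol half-width of the CI band labelled `"additive"`.
#' @return data frame: `dose_a`, `dose_b`, `fa`, `ci`, `label` (one of
#'   `"synergism"`, `"additive"`, `"antagonism"`, `"undefined"`).
#' @export
combination_index <- function(dose_a, dose_b, fa, fit_a, fit_b,
                              additive_tol = 0.05) {
  stopifnot(inherits(fit_a, "median_effect_fit"),
            inherits(fit_b, "median_effect_fit"))
  n <- max(length(dose_a), length(dose_b), length(fa))
  dose_a <- rep_len(dose_a, n); dose_b <- rep_len(dose_b, n)
  fa <- rep_len(fa, n)
  ci <- rep(NA_real_, n)
  ok <- fa > 0 & fa < 1
  ci[ok] <- dose_a[ok] / dose_for_fa(fit_a, fa[ok]) +
    dose_b[ok] / dose_for_fa(fit_b, fa[ok])
  label <- rep("undefined", n)
  label[ok & abs(ci - 1) <= additive_tol] <- "additive"
  label[ok & ci < 1 - additive_tol] <- "synergism"
  label[ok & ci > 1 + additive_tol] <- "antagonism"
  data.frame(dose_a = dose_a, dose_b = dose_b, fa = fa, ci = ci,
             label = label, stringsAsFactors = FALSE)
}

#' Full synergy analysis of a combination table
#'
#' Splits a combination experiment into single-agent points (one dose zero)
#' and combination points, fits the median-effect model per agent, and
#' computes the combination index at every combination point.
#'
#' @param table data frame with columns `dose_a`, `dose_b`, `fa` (e.g. from
#'   [gen_combination()]).
#' @param additive_tol CI labelling tolerance, see [combination_index()].
#' @return list of class `synergy_analysis`: `fit_a`, `fit_b`
#'   (median-effect fits), `ci` (per-combination-point table).
#' @export
synergy_analysis <- function(table, additive_tol = 0.05) {
  req <- c("dose_a", "dose_b", "fa")
  if (!all(req %in% names(table))) {
    stop("table must have columns ", paste(req, collapse = ", "))
  }
  single_a <- table$dose_b == 0 & table$dose_a > 0
  single_b <- table$dose_a == 0 & table$dose_b > 0
  combo <- table$dose_a > 0 & table$dose_b > 0
  if (sum(single_a) < 3 || sum(single_b) < 3) {
    stop("need at least 3 single-agent points per drug")
  }
  fit_a <- fit_median_effect(table$dose_a[single_a], table$fa[single_a])
  fit_b <- fit_median_effect(table$dose_b[single_b], table$fa[single_b])
  ci <- combination_index(table$dose_a[combo], table$dose_b[combo],
                          table$fa[combo], fit_a, fit_b,
                          additive_tol = additive_tol)
  structure(list(fit_a = fit_a, fit_b = fit_b, ci = ci),
            class = "synergy_analysis")
}

#' @export
print.synergy_analysis <- function(x, ...) {
  cat("Synergy analysis (Chou-Talalay)\n  drug A: ")
  print(x$fit_a)
  cat("  drug B: ")
  print(x$fit_b)
  cat("  combination points:\n")
  print(x$ci, digits = 4)
  invisible(x)
}
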