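#' Compute growth-rate inhibition (GR) values from two-timepoint signals
#'
#' Converts paired t0/t viability signals into GR values,
#' `GR(c) = 2^(k(c)/k(0)) - 1`, where `k(c) = log2(x_t(c)/x_0(c)) / t` is the
#' growth rate under treatment and `k(0)` the vehicle growth rate. GR = 1
#' means no effect, GR = 0 complete cytostasis, GR < 0 cytotoxicity; by
#' construction GR is independent of the cell line's doubling time. Growth
#' rates are computed from replicate-averaged signals (stabilizes the log of
#' small signals). Relative viability (endpoint signal over vehicle endpoint
#' signal) is reported alongside.
#'
#' @param data data frame with columns `cell_line`, `drug`, `conc_nM`
#'   (0 = vehicle), `replicate`, `signal_t0`, `signal_t`, `duration_h`, e.g.
#'   from [gen_dose_response()]. Vehicle wells (conc 0) are required per cell
#'   line and are shared across drugs.
#' @param background per-plate background signal subtracted from every well
#'   before any ratio is formed.
#' @return data frame of class `gr_table`: one row per (cell_line, drug,
#'   conc_nM) with `gr_value`, `relative_viability`, `n_replicates`.
#' @export
compute_gr_table <- function(data, background = 0) {
  req <- c("cell_line", "drug", "conc_nM", "replicate", "signal_t0",
           "signal_t", "duration_h")
  missing <- setdiff(req, names(data))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  data$signal_t0 <- data$signal_t0 - background
  data$signal_t <- data$signal_t - background
  bad <- data$signal_t0 <= 0 | data$signal_t <= 0
  if (any(bad)) {
    warning(sum(bad), " well(s) non-positive after background subtraction; excluded")
    data <- data[!bad, , drop = FALSE]
  }
  out <- list()
  for (cl in unique(data$cell_line)) {
    d_cl <- data[data$cell_line == cl, , drop = FALSE]
    veh <- d_cl[d_cl$conc_nM == 0, , drop = FALSE]
    if (!nrow(veh)) stop("no vehicle (conc 0) wells for cell line ", cl)
    t_h <- veh$duration_h[1]
    k0 <- log2(mean(veh$signal_t) / mean(veh$signal_t0)) / t_h
    if (!is.finite(k0) || k0 == 0) stop("vehicle growth rate undefined for ", cl)
    veh_t <- mean(veh$signal_t)
    for (dr in unique(d_cl$drug)) {
      d <- d_cl[d_cl$drug == dr, , drop = FALSE]
      for (cc in sort(unique(d$conc_nM))) {
        w <- d[d$conc_nM == cc, , drop = FALSE]
        k <- log2(mean(w$signal_t) / mean(w$signal_t0)) / w$duration_h[1]
        out[[length(out) + 1L]] <- data.frame(
          cell_line = cl, drug = dr, conc_nM = cc,
          gr_value = 2^(k / k0) - 1,
          relative_viability = mean(w$signal_t) / veh_t,
          n_replicates = nrow(w), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("gr_table", "data.frame")
  out
}

#' Fit a sigmoidal GR dose-response curve
#'
#' Least-squares fit of `GR(c) = gr_inf + (1 - gr_inf) / (1 + (c/gec50)^hill)`
#' to GR values at nonzero concentrations, with box constraints
#' `gr_inf` in \[-1, 1\], `hill` in (0.1, 5\], and `gec50` within two decades
#' of the tested range. The sigmoid is compared to the constant-GR model by
#' an F-test: a non-significant fit (alpha = 0.05) is flagged `flat`; an
#' optimizer failure or a fit pinned at a parameter bound is flagged
#' `unstable`.
#'
#' @param gr a `gr_table` slice for one (cell line, drug) pair, or any data
#'   frame with columns `conc_nM` and `gr_value`.
#' @param alpha significance level of the flat-vs-sigmoid F-test.
#' @return object of class `gr_curve_fit` with elements `gr_inf`, `gec50`,
#'   `hill`, `rss`, `status` (one of `"ok"`, `"flat"`, `"not_reached"`,
#'   `"unstable"`), `n`, `conc_range`.
#' @export
fit_gr_curve <- function(gr, alpha = 0.05) {
  conc <- gr$conc_nM
  y <- gr$gr_value
  keep <- conc > 0
  conc <- conc[keep]; y <- y[keep]
  if (length(unique(conc)) < 4) stop("at least 4 distinct nonzero concentrations required")
  lo <- c(-1, log10(min(conc)) - 2, 0.1)
  hi <- c(1, log10(max(conc)) + 2, 5)
  obj <- function(p) sum((y - gr_from_params(conc, p[1], 10^p[2], p[3]))^2)
  rss0 <- sum((y - mean(y))^2)
  # multistart over candidate gec50 positions
  starts <- lapply(stats::quantile(log10(conc), c(0.25, 0.5, 0.75)),
                   function(lg) c(min(max(min(y), -1), 1), lg, 1))
  best <- NULL
  for (s in starts) {
    ft <- tryCatch(stats::optim(s, obj, method = "L-BFGS-B", lower = lo,
                                upper = hi,
                                control = list(factr = 1e4, maxit = 500)),
                   error = function(e) NULL)
    if (!is.null(ft) && (is.null(best) || ft$value < best$value)) best <- ft
  }
  n <- length(y)
  make_fit <- function(p, rss, status) {
    structure(list(gr_inf = p[1], gec50 = 10^p[2], hill = p[3], rss = rss,
                   status = status, n = n, conc_range = range(conc)),
              class = "gr_curve_fit")
  }
  if (is.null(best)) return(make_fit(c(NA, NA, NA), NA, "unstable"))
  rss1 <- best$value
  # flat when the sigmoid adds nothing over the constant model
  flat <- if (rss0 < 1e-12) TRUE else {
    fstat <- ((rss0 - rss1) / 2) / (rss1 / max(n - 3, 1))
    if (!is.finite(fstat)) FALSE
    else stats::pf(fstat, 2, max(n - 3, 1), lower.tail = FALSE) >= alpha
  }
  at_bound <- any(abs(best$par - lo) < 1e-6) || any(abs(best$par - hi) < 1e-6)
  status <- if (flat) "flat"
    else if (best$convergence != 0 || at_bound) "unstable"
    else "ok"
  make_fit(best$par, rss1, status)
}

#' @export
print.gr_curve_fit <- function(x, ...) {
  cat("GR dose-response fit (", x$status, ")\n", sep = "")
  cat(sprintf("  gr_inf = %.4f, gec50 = %.4g nM, hill = %.3f, rss = %.4g (n = %d)\n",
              x$gr_inf, x$gec50, x$hill, x$rss, x$n))
  invisible(x)
}

#' @export
coef.gr_curve_fit <- function(object, ...) {
  c(gr_inf = object$gr_inf, gec50 = object$gec50, hill = object$hill)
}

#' @export
predict.gr_curve_fit <- function(object, conc, ...) {
  gr_from_params(conc, object$gr_inf, object$gec50, object$hill)
}

#' Summarize GR metrics for one (cell line, drug) pair
#'
#' Derives the three headline GR metrics: `gr50` (potency), the concentration
#' at which the fitted curve crosses GR = 0.5, solved analytically and
#' reported only if the crossing lies within the tested range extended by one
#' decade (flag `">max_tested"` otherwise, `"unstable"` when the curve fit is
#' unreliable, in which case linear interpolation on the raw GR values is
#' reported separately); `gr_max` (efficacy), the mean raw GR at the highest
#' tested concentration; and `gr_aoc` (potency and efficacy combined), the
#' trapezoidal integral of `1 - GR` over log10 concentration computed from
#' the raw GR values without any curve-fitting constraint.
#'
#' @param fit a [fit_gr_curve()] result.
#' @param gr the matching `gr_table` slice (raw GR values).
#' @return data frame (one row): `gr50`, `gr50_flag`, `gr50_interp`,
#'   `gr_max`, `gr_aoc`, `fit_status`.
#' @export
gr_metrics_summary <- function(fit, gr) {
  conc <- gr$conc_nM[gr$conc_nM > 0]
  y <- gr$gr_value[gr$conc_nM > 0]
  o <- order(conc)
  conc <- conc[o]; y <- y[o]
  agg <- tapply(y, conc, mean)
  uc <- as.numeric(names(agg))
  gr_max <- unname(agg[length(agg)])
  gr_aoc <- trapz(log10(uc), 1 - as.numeric(agg))
  interp_gr50 <- function() {
    # first downward crossing of 0.5 on the raw curve, log-linear in dose
    v <- as.numeric(agg)
    for (i in seq_len(length(v) - 1)) {
      if ((v[i] - 0.5) * (v[i + 1] - 0.5) <= 0 && v[i] != v[i + 1]) {
        f <- (0.5 - v[i]) / (v[i + 1] - v[i])
        return(10^(log10(uc[i]) + f * (log10(uc[i + 1]) - log10(uc[i]))))
      }
    }
    NA_real_
  }
  gr50 <- NA_real_; flag <- ">max_tested"
  if (fit$status == "unstable") {
    flag <- "unstable"
  } else if (fit$status %in% c("ok", "flat") && is.finite(fit$gr_inf) &&
             fit$gr_inf < 0.5) {
    ratio <- (1 - fit$gr_inf) / (0.5 - fit$gr_inf) - 1
    if (ratio > 0) {
      cand <- fit$gec50 * ratio^(1 / fit$hill)
      if (cand >= min(conc) / 10 && cand <= max(conc) * 10) {
        gr50 <- cand; flag <- "ok"
      }
    }
  }
  data.frame(gr50 = gr50, gr50_flag = flag, gr50_interp = interp_gr50(),
             gr_max = gr_max, gr_aoc = gr_aoc, fit_status = fit$status,
             stringsAsFactors = FALSE)
}

#' Fit a four-parameter logistic viability curve and compute absolute IC50
#'
#' The absolute IC50 is the dose at which the fitted relative viability
#' crosses 0.5 — not the curve inflection. If the fitted curve never crosses
#' 0.5 within the tested range extended by one decade, the sentinel flag
#' `">max_tested"` is returned.
#'
#' @param conc nonzero concentrations (nM).
#' @param viability relative viability values (vehicle = 1).
#' @return data frame (one row): `ic50`, `ic50_flag`, plus fitted 4PL
#'   parameters `upper`, `lower`, `inflection`, `hill`.
#' @export
fit_viability_ic50 <- function(conc, viability) {
  keep <- conc > 0
  conc <- conc[keep]; viability <- viability[keep]
  if (length(unique(conc)) < 4) stop("at least 4 distinct nonzero concentrations required")
  lo <- c(0.5, -0.5, log10(min(conc)) - 2, 0.1)
  hi <- c(1.5, 0.99, log10(max(conc)) + 2, 5)
  f4pl <- function(c, p) p[2] + (p[1] - p[2]) / (1 + (c / 10^p[3])^p[4])
  obj <- function(p) sum((viability - f4pl(conc, p))^2)
  starts <- lapply(stats::quantile(log10(conc), c(0.25, 0.5, 0.75)),
                   function(lg) c(1, max(min(viability), -0.4), lg, 1))
  best <- NULL
  for (s in starts) {
    ft <- tryCatch(stats::optim(s, obj, method = "L-BFGS-B", lower = lo,
                                upper = hi,
                                control = list(factr = 1e4, maxit = 500)),
                   error = function(e) NULL)
    if (!is.null(ft) && (is.null(best) || ft$value < best$value)) best <- ft
  }
  if (is.null(best)) {
    return(data.frame(ic50 = NA_real_, ic50_flag = "unstable",
                      upper = NA, lower = NA, inflection = NA, hill = NA))
  }
  p <- best$par
  ic50 <- NA_real_; flag <- ">max_tested"
  if (p[2] < 0.5 && p[1] > 0.5) {
    ratio <- (p[1] - p[2]) / (0.5 - p[2]) - 1
    cand <- 10^p[3] * ratio^(1 / p[4])
    if (cand >= min(conc) / 10 && cand <= max(conc) * 10) {
      ic50 <- cand; flag <- "ok"
    }
  }
  data.frame(ic50 = ic50, ic50_flag = flag, upper = p[1], lower = p[2],
             inflection = 10^p[3], hill = p[4], stringsAsFactors = FALSE)
}

#' Default drug-sensitivity IC50 cutoffs (nM)
#'
#' Registered absolute-IC50 cutoffs below which a cell line is called
#' sensitive: gedatolisib 100 nM, alpelisib 3000 nM, capivasertib 3000 nM,
#' everolimus 50 nM.
#'
#' @return named numeric vector of cutoffs in nM.
#' @export
default_sensitivity_cutoffs <- function() {
  c(gedatolisib = 100, alpelisib = 3000, capivasertib = 3000, everolimus = 50)
}

#' Classify drug sensitivity from absolute IC50
#'
#' Strict less-than comparison against a per-drug cutoff; a sentinel
#' (non-finite) IC50 is never sensitive.
#'
#' @param drug drug identifier (must have a registered cutoff).
#' @param ic50 absolute IC50 in nM, or `NA` for a sentinel.
#' @param cutoffs named cutoff table; see [default_sensitivity_cutoffs()].
#' @return logical.
#' @export
classify_sensitivity <- function(drug, ic50,
                                 cutoffs = default_sensitivity_cutoffs()) {
  if (!drug %in% names(cutoffs)) stop("no sensitivity cutoff registered for drug: ", drug)
  if (is.na(ic50) || !is.finite(ic50)) return(FALSE)
  unname(ic50 < cutoffs[[drug]])
}

#' Full GR-metrics analysis of a dose-response dataset
#'
#' Convenience driver: computes the GR table, then per (cell line, drug) pair
#' fits the GR curve, summarizes GR50/GRmax/GRaoc, fits the viability 4PL for
#' absolute IC50, and (where a cutoff is registered) calls sensitivity.
#'
#' @param data a dose-response dataset (see [compute_gr_table()]).
#' @param background per-plate background signal.
#' @param cutoffs sensitivity cutoff table.
#' @return list of class `gr_analysis`: `gr_table` and `metrics` (one row per
#'   pair).
#' @export
gr_analysis <- function(data, background = 0,
                        cutoffs = default_sensitivity_cutoffs()) {
  grt <- compute_gr_table(data, background = background)
  rows <- list()
  pairs <- unique(grt[grt$conc_nM > 0, c("cell_line", "drug")])
  for (i in seq_len(nrow(pairs))) {
    cl <- pairs$cell_line[i]; dr <- pairs$drug[i]
    sl <- grt[grt$cell_line == cl & grt$drug == dr, , drop = FALSE]
    fit <- fit_gr_curve(sl)
    m <- gr_metrics_summary(fit, sl)
    ic <- fit_viability_ic50(sl$conc_nM, sl$relative_viability)
    sens <- if (dr %in% names(cutoffs))
      classify_sensitivity(dr, ic$ic50, cutoffs) else NA
    rows[[i]] <- cbind(data.frame(cell_line = cl, drug = dr,
                                  stringsAsFactors = FALSE),
                       m, ic50 = ic$ic50, ic50_flag = ic$ic50_flag,
                       sensitive = sens)
  }
  out <- list(gr_table = grt, metrics = do.call(rbind, rows))
  class(out) <- "gr_analysis"
  out
}

#' @export
print.gr_analysis <- function(x, ...) {
  cat("GR analysis:", nrow(x$metrics), "cell line x drug pair(s)\n")
  print(x$metrics, digits = 4)
  invisible(x)
}
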