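#' Tumor volume from caliper measurements
#'
#' `V = L * W^2 / 2` with L the longest dimension. If a width entry exceeds
#' its length the two are swapped (with a warning) before the formula is
#' applied, enforcing the measurement convention.
#'
#' @param length_mm,width_mm caliper dimensions in mm (> 0); vectorized.
#' @return tumor volumes in mm^3.
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0 | width_mm <= 0)) stop("tumor dimensions must be positive")
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning(sum(swap), " measurement(s) had width > length; dimensions swapped")
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  length_mm * width_mm^2 / 2
}

# per-animal volume at a requested day, carrying the nearest observation
# within +/- window days (exact day preferred)
volumes_at_day <- function(study, day, window = 2) {
  study$volume <- suppressWarnings(tumor_volume(study$length_mm, study$width_mm))
  out <- list()
  for (a in unique(study$animal)) {
    d <- study[study$animal == a, , drop = FALSE]
    gap <- abs(d$day - day)
    if (min(gap) > window) next
    i <- which.min(gap)
    out[[a]] <- data.frame(animal = a, arm = d$arm[1], volume = d$volume[i],
                           day_used = d$day[i], stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no measurements within +/-", window, " days of day ", day)
  do.call(rbind, out)
}

#' Tumor growth inhibition (TGI) at a study day
#'
#' Baseline-adjusted form: `TGI = 100 * (1 - dV_treated / dV_control)` with
#' `dV = mean V(day) - mean V(0)` per arm — the standard definition for
#' studies randomized at an established tumor volume. The simple endpoint
#' ratio `100 * (1 - mean V_t(day) / mean V_c(day))` is available via
#' `method = "ratio"`. Raw TGI is retained; a capped value (100 for
#' regressing tumors) is reported for display. Measurements are matched to
#' the requested day within a +/- `window`-day tolerance.
#'
#' @param study xenograft measurement table with columns `animal`, `arm`,
#'   `day`, `length_mm`, `width_mm` (e.g. from [gen_xenograft()]).
#' @param day study day at which TGI is evaluated.
#' @param control_arm name of the control arm.
#' @param method `"delta"` (baseline-adjusted, default) or `"ratio"`.
#' @param window day-matching tolerance.
#' @return data frame per treated arm (control included with TGI 0):
#'   `arm`, `tgi`, `tgi_capped`, `n`, `mean_volume`, `sem_volume`.
#' @export
tgi <- function(study, day, control_arm, method = c("delta", "ratio"),
                window = 2) {
  method <- match.arg(method)
  if (!control_arm %in% study$arm) stop("control arm '", control_arm, "' not present")
  v_day <- volumes_at_day(study, day, window)
  v_0 <- volumes_at_day(study, 0, window)
  arms <- unique(study$arm)
  arm_stats <- function(tab, a) {
    v <- tab$volume[tab$arm == a]
    if (!length(v)) stop("arm '", a, "' has no measurements at the requested day")
    list(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  }
  dv <- function(a) arm_stats(v_day, a)$mean -
    (if (method == "delta") arm_stats(v_0, a)$mean else 0)
  dvc <- dv(control_arm)
  if (dvc <= 0) stop("control arm did not grow (dV <= 0); TGI undefined")
  rows <- lapply(arms, function(a) {
    s <- arm_stats(v_day, a)
    t <- 100 * (1 - dv(a) / dvc)
    data.frame(arm = a, tgi = t, tgi_capped = min(t, 100), n = s$n,
               mean_volume = s$mean, sem_volume = s$sem,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$arm != control_arm, out$arm), , drop = FALSE]
}

#' Per-animal body-weight change and welfare flags
#'
#' Percent change relative to the day-0 weight; an animal losing strictly
#' more than 20 % of its randomization weight is flagged for euthanasia.
#'
#' @param study measurement table with columns `animal`, `day`,
#'   `body_weight_g`.
#' @param loss_threshold percent loss triggering the welfare flag (strict).
#' @return data frame: `animal`, `arm` (if present), `day`, `pct_change`,
#'   `flag_euthanize`.
#' @export
body_weight_change <- function(study, loss_threshold = 20) {
  out <- list()
  for (a in unique(study$animal)) {
    d <- study[study$animal == a, , drop = FALSE]
    d <- d[order(d$day), , drop = FALSE]
    w0 <- d$body_weight_g[d$day == 0]
    if (!length(w0)) stop("missing day-0 body weight for animal ", a)
    pct <- 100 * (d$body_weight_g - w0[1]) / w0[1]
    out[[a]] <- data.frame(animal = a,
                           arm = if ("arm" %in% names(d)) d$arm else NA,
                           day = d$day, pct_change = pct,
                           flag_euthanize = pct < -loss_threshold,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Between-arm comparison of tumor volumes at a study day
#'
#' One-way ANOVA on per-animal volumes at the requested day, followed by
#' pairwise two-sided t-tests of each treated arm against control with Holm
#' adjustment. Significance stars follow the 0.05 / 0.01 / 0.001 convention.
#'
#' @param study measurement table (see [tgi()]).
#' @param day study day.
#' @param control_arm control arm name.
#' @param window day-matching tolerance.
#' @return list of class `group_comparison`: `anova` (data frame with `F`,
#'   `p`, `stars`), `pairwise` (per treated arm: `t`, `p_raw`, `p_holm`,
#'   `stars`), `volumes` (per-animal table used).
#' @export
group_compare <- function(study, day, control_arm, window = 2) {
  v <- volumes_at_day(study, day, window)
  arms <- unique(v$arm)
  if (length(arms) < 2) stop("at least 2 arms required")
  n_per <- table(v$arm)
  if (any(n_per < 2)) {
    stop("arm(s) with fewer than 2 animals: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  }
  v$arm <- factor(v$arm)
  if (stats::var(v$volume) == 0) {
    an <- data.frame(F = 0, p = 1, stars = "ns", stringsAsFactors = FALSE)
  } else {
    ft <- stats::aov(volume ~ arm, data = v)
    s <- summary(ft)[[1]]
    an <- data.frame(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
                     stringsAsFactors = FALSE)
    an$stars <- significance_stars(an$p)
  }
  treated <- setdiff(levels(v$arm), control_arm)
  pw <- lapply(treated, function(a) {
    x <- v$volume[v$arm == a]
    y <- v$volume[v$arm == control_arm]
    if (stats::sd(c(x, y)) == 0) {
      data.frame(arm = a, t = 0, p_raw = 1, stringsAsFactors = FALSE)
    } else if (stats::var(x) == 0 && stats::var(y) == 0) {
      # degenerate noise-free arms: identical means handled above, so the
      # separation is exact
      data.frame(arm = a, t = Inf * sign(mean(x) - mean(y)), p_raw = 0,
                 stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(x, y)
      data.frame(arm = a, t = unname(tt$statistic), p_raw = tt$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  pw <- do.call(rbind, pw)
  if (!is.null(pw) && nrow(pw)) {
    pw$p_holm <- stats::p.adjust(pw$p_raw, method = "holm")
    pw$stars <- significance_stars(pw$p_holm)
  }
  structure(list(anova = an, pairwise = pw, volumes = v),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g %s\n",
              x$anova$F, x$anova$p, x$anova$stars))
  if (!is.null(x$pairwise) && nrow(x$pairwise)) {
    cat("Pairwise vs control (Holm-adjusted):\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}

#' Per-arm, per-day summary of a xenograft study
#'
#' Mean tumor volume, SEM and animal count per arm and day (the mean +/- SEM
#' series plotted in efficacy figures).
#'
#' @param study measurement table (see [tgi()]).
#' @return data frame: `arm`, `day`, `n`, `mean_volume`, `sem_volume`.
#' @export
efficacy_summary <- function(study) {
  study$volume <- suppressWarnings(tumor_volume(study$length_mm, study$width_mm))
  agg <- stats::aggregate(volume ~ arm + day, data = study,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sem = stats::sd(v) / sqrt(length(v))))
  out <- data.frame(arm = agg$arm, day = agg$day,
                    n = agg$volume[, "n"], mean_volume = agg$volume[, "mean"],
                    sem_volume = agg$volume[, "sem"], stringsAsFactors = FALSE)
  out[order(out$arm, out$day), , drop = FALSE]
}
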