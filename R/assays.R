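# threshold separating the two modes of a log-intensity mixture: the
# intensity at which the two fitted Gaussian components (on log scale) are
# equally likely. Falls back to the midpoint between 1-D k-means centers if
# the mixture fit degenerates.
mixture_threshold <- function(intensity) {
  lx <- log(intensity[intensity > 0])
  # fit on evenly spaced order statistics: keeps the fit O(n) and the
  # threshold deterministic (no RNG consumed) for large event tables
  lx_fit <- sort(lx)
  if (length(lx_fit) > 5000) {
    lx_fit <- lx_fit[unique(round(seq(1, length(lx_fit), length.out = 5000)))]
  }
  fit <- tryCatch(
    mclust::Mclust(lx_fit, G = 2, modelNames = c("E", "V"), verbose = FALSE),
    error = function(e) NULL)
  if (!is.null(fit) && fit$G == 2) {
    mu <- fit$parameters$mean
    sig <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sig) == 1) sig <- rep(sig, 2)
    pro <- fit$parameters$pro
    o <- order(mu)
    mu <- mu[o]; sig <- sig[o]; pro <- pro[o]
    f <- function(t) pro[1] * stats::dnorm(t, mu[1], sig[1]) -
      pro[2] * stats::dnorm(t, mu[2], sig[2])
    if (mu[2] - mu[1] > 1e-6 && sign(f(mu[1])) != sign(f(mu[2]))) {
      return(exp(stats::uniroot(f, lower = mu[1], upper = mu[2])$root))
    }
  }
  km <- stats::kmeans(lx_fit, centers = stats::quantile(lx_fit, c(0.25, 0.75)))
  exp(mean(range(km$centers)))
}

#' Summarize flow-cytometry readouts with live gating and control normalization
#'
#' Events are first gated to live cells: the viability (dead-cell) dye is
#' bright on dead cells, so live events fall below a threshold placed between
#' the two modes of the dye's log-intensity mixture (fitted on all events
#' pooled). Among live events, per-channel median fluorescence intensity
#' (MFI) is background-subtracted using the unstained-control medians
#' (floored at 0 with a warning), and the EdU-positive fraction is computed
#' with a threshold between the two modes of the live-cell EdU mixture.
#' All three readouts are finally divided by the control condition's values
#' (control set to 1).
#'
#' @param events per-event data frame with columns `condition`,
#'   `viability_dye`, `edu`, `prps6`, `p4ebp1` (e.g. `gen_assay_panel()$events`).
#' @param unstained named numeric of unstained-control medians per channel
#'   (`prps6`, `p4ebp1` required).
#' @param control name of the control condition (default `"DMSO"`).
#' @return data frame of class `flow_summary`, one row per condition:
#'   `n_live`, `edu_frac`, `mfi_prps6`, `mfi_p4ebp1`, and normalized
#'   `norm_edu`, `norm_prps6`, `norm_p4ebp1` (control = 1).
#' @export
flow_summarize <- function(events, unstained, control = "DMSO") {
  req <- c("condition", "viability_dye", "edu", "prps6", "p4ebp1")
  if (!all(req %in% names(events))) {
    stop("events must have columns ", paste(req, collapse = ", "))
  }
  if (!control %in% events$condition) stop("control condition '", control, "' not present")
  if (!all(c("prps6", "p4ebp1") %in% names(unstained))) {
    stop("unstained medians required for channels prps6 and p4ebp1")
  }
  live_thr <- mixture_threshold(events$viability_dye)
  live <- events[events$viability_dye < live_thr, , drop = FALSE]
  edu_thr <- mixture_threshold(live$edu)
  conds <- unique(events$condition)
  rows <- lapply(conds, function(cond) {
    ev <- live[live$condition == cond, , drop = FALSE]
    if (nrow(ev) < 100) stop("fewer than 100 live events in condition ", cond)
    mfi <- function(ch) {
      v <- stats::median(ev[[ch]]) - unstained[[ch]]
      if (v < 0) {
        warning("unstained background exceeds stained median for ", ch,
                " in ", cond, "; MFI floored at 0")
        v <- 0
      }
      v
    }
    data.frame(condition = cond, n_live = nrow(ev),
               edu_frac = mean(ev$edu > edu_thr),
               mfi_prps6 = mfi("prps6"), mfi_p4ebp1 = mfi("p4ebp1"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ctrl <- out[out$condition == control, , drop = FALSE]
  if (ctrl$mfi_prps6 <= 0 || ctrl$mfi_p4ebp1 <= 0) {
    stop("control MFI non-positive after background subtraction")
  }
  if (ctrl$edu_frac <= 0) stop("control EdU+ fraction is zero; cannot normalize")
  out$norm_edu <- out$edu_frac / ctrl$edu_frac
  out$norm_prps6 <- out$mfi_prps6 / ctrl$mfi_prps6
  out$norm_p4ebp1 <- out$mfi_p4ebp1 / ctrl$mfi_p4ebp1
  class(out) <- c("flow_summary", "data.frame")
  out
}

#' Percent inhibition relative to control
#'
#' `100 * (1 - normalized_value)`, floored at 0: a normalized readout above 1
#' (stimulation) reports 0 % inhibition and is flagged via the `stimulated`
#' attribute.
#'
#' @param normalized_value normalized readout(s), control = 1; must be >= 0.
#' @return numeric vector of percent inhibition in \[0, 100\], with a logical
#'   attribute `stimulated` marking inputs > 1.
#' @export
percent_inhibition <- function(normalized_value) {
  if (any(normalized_value < 0, na.rm = TRUE)) {
    stop("normalized values must be >= 0")
  }
  out <- pmax(0, 100 * (1 - normalized_value))
  attr(out, "stimulated") <- normalized_value > 1
  out
}

#' Relative expression by the delta-delta-Ct method with dual reference genes
#'
#' Per sample, `dCt = Ct_target - mean(Ct_ref)` over the reference genes
#' (arithmetic mean of Cts, i.e. geometric mean on the expression scale);
#' `ddCt = mean dCt(condition) - mean dCt(control)`; relative expression
#' `= 2^(-ddCt)`. A within-condition replicate dCt SD above 1 cycle is
#' flagged.
#'
#' @param ct Ct table with columns `sample`, `condition`, `gene`, `ct`.
#' @param target target gene name.
#' @param control_condition reference condition (relative expression 1).
#' @param reference_genes names of the reference genes; both must be measured
#'   in every sample.
#' @return data frame, one row per condition: `dct_mean`, `ddct`,
#'   `rel_expression`, `high_variance` flag.
#' @export
ddct_expression <- function(ct, target, control_condition = "control",
                            reference_genes = c("HPRT1", "ACTB")) {
  req <- c("sample", "condition", "gene", "ct")
  if (!all(req %in% names(ct))) stop("ct must have columns ", paste(req, collapse = ", "))
  if (!control_condition %in% ct$condition) {
    stop("control condition '", control_condition, "' not present")
  }
  dct <- vapply(unique(ct$sample), function(s) {
    d <- ct[ct$sample == s, , drop = FALSE]
    tgt <- d$ct[d$gene == target]
    refs <- vapply(reference_genes, function(g) {
      v <- d$ct[d$gene == g]
      if (!length(v)) stop("reference gene ", g, " missing in sample ", s)
      mean(v)
    }, numeric(1))
    if (!length(tgt)) stop("target gene ", target, " missing in sample ", s)
    mean(tgt) - mean(refs)
  }, numeric(1))
  cond_of <- ct$condition[match(names(dct), ct$sample)]
  conds <- unique(ct$condition)
  ctrl_mean <- mean(dct[cond_of == control_condition])
  rows <- lapply(conds, function(cond) {
    v <- dct[cond_of == cond]
    hv <- length(v) > 1 && stats::sd(v) > 1
    if (hv) warning("replicate dCt SD > 1 cycle in condition ", cond)
    ddct <- mean(v) - ctrl_mean
    data.frame(condition = cond, dct_mean = mean(v), ddct = ddct,
               rel_expression = 2^(-ddct), high_variance = hv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
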