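#' Default concentration ladder (nM)
#'
#' The half-log ten-point ladder used throughout the dose-response stages,
#' spanning 1.4 nM to 27 uM.
#'
#' @return numeric vector of concentrations in nM, strictly increasing.
#' @export
default_ladder <- function() {
  c(1.4, 4.1, 12, 37, 111, 333, 1000, 3000, 9000, 27000)
}

#' Specify a synthetic dose-response plate experiment
#'
#' Describes a viability plate study: which cell lines and drugs, the
#' concentration ladder, replicate count, per-cell-line doubling times and the
#' latent GR dose-response parameters per (cell line, drug) pair. The latent
#' parameters (`gr_inf`, `gec50`, `hill`) are the generating counterparts of
#' the fitted GR curve: at dose c the noise-free GR value equals
#' `gr_inf + (1 - gr_inf) / (1 + (c / gec50)^hill)`.
#'
#' @param cell_lines character vector of cell line identifiers.
#' @param drugs character vector of drug identifiers.
#' @param concentrations strictly increasing dose ladder in nM.
#' @param n_replicates replicate wells per condition.
#' @param doubling_time_h named numeric, hours per doubling per cell line.
#' @param gr_params named list keyed `"<cell_line>:<drug>"`, each a list or
#'   numeric vector with elements `gr_inf` (in \[-1, 1\]), `gec50` (nM > 0)
#'   and `hill` (> 0).
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   measurement noise on well signals (0 = noise-free).
#' @param seed integer seed; identical specs with identical seeds generate
#'   byte-identical plates.
#' @return object of class `plate_spec`.
#' @export
plate_spec <- function(cell_lines, drugs, concentrations = default_ladder(),
                       n_replicates = 2, doubling_time_h, gr_params,
                       noise_cv = 0.05, seed = 1) {
  if (any(diff(concentrations) <= 0)) {
    stop("concentrations must be strictly increasing")
  }
  if (any(concentrations <= 0)) stop("concentrations must be positive (0 is reserved for vehicle)")
  if (any(doubling_time_h <= 0)) stop("doubling times must be positive")
  if (!all(cell_lines %in% names(doubling_time_h))) {
    stop("doubling_time_h must name every cell line")
  }
  for (cl in cell_lines) for (dr in drugs) {
    key <- paste(cl, dr, sep = ":")
    p <- gr_params[[key]]
    if (is.null(p)) stop("gr_params missing entry ", key)
    p <- as.list(p)
    if (p$gr_inf < -1 || p$gr_inf > 1) stop("gr_inf out of [-1, 1] for ", key)
    if (p$gec50 <= 0) stop("gec50 must be > 0 for ", key)
    if (p$hill <= 0) stop("hill must be > 0 for ", key)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(cell_lines = cell_lines, drugs = drugs,
                 concentrations = concentrations,
                 n_replicates = as.integer(n_replicates),
                 doubling_time_h = doubling_time_h,
                 gr_params = gr_params, noise_cv = noise_cv,
                 seed = seed),
            class = "plate_spec")
}

# noise-free GR value implied by latent parameters at dose c
gr_from_params <- function(conc, gr_inf, gec50, hill) {
  gr_inf + (1 - gr_inf) / (1 + (conc / gec50)^hill)
}

#' Generate a synthetic dose-response plate dataset
#'
#' Simulates two-timepoint viability signals (relative light units) such that,
#' noise-free, recomputing GR values from the generated signals reproduces the
#' generating curve exactly. Vehicle (DMSO) control wells at concentration 0
#' are included per cell line. Noise is multiplicative log-normal on each well
#' signal, reflecting the scale-noise of luminescence assays.
#'
#' @param spec a [plate_spec()].
#' @param duration_h treatment duration in hours (default 72).
#' @param baseline_rlu seeding-time signal per well.
#' @return data frame of class `dose_response_dataset` with columns
#'   `cell_line`, `drug`, `conc_nM` (0 = vehicle), `replicate`, `signal_t0`,
#'   `signal_t`, `duration_h`.
#' @export
gen_dose_response <- function(spec, duration_h = 72, baseline_rlu = 1000) {
  stopifnot(inherits(spec, "plate_spec"))
  with_seed(spec$seed, {
    rows <- list()
    for (cl in spec$cell_lines) {
      k0 <- 1 / spec$doubling_time_h[[cl]]   # doublings per hour
      # vehicle wells, one set per cell line
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cl, drug = "DMSO", conc_nM = 0,
        replicate = seq_len(spec$n_replicates),
        signal_t0 = baseline_rlu,
        signal_t = baseline_rlu * 2^(k0 * duration_h),
        duration_h = duration_h, stringsAsFactors = FALSE)
      for (dr in spec$drugs) {
        p <- as.list(spec$gr_params[[paste(cl, dr, sep = ":")]])
        g <- gr_from_params(spec$concentrations, p$gr_inf, p$gec50, p$hill)
        g <- pmax(g, -1 + 1e-12)
        k <- k0 * log2(g + 1)
        for (r in seq_len(spec$n_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            cell_line = cl, drug = dr, conc_nM = spec$concentrations,
            replicate = r,
            signal_t0 = baseline_rlu,
            signal_t = baseline_rlu * 2^(k * duration_h),
            duration_h = duration_h, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    n <- nrow(out)
    out$signal_t0 <- out$signal_t0 * rlnorm_cv(n, spec$noise_cv)
    out$signal_t <- out$signal_t * rlnorm_cv(n, spec$noise_cv)
    rownames(out) <- NULL
    class(out) <- c("dose_response_dataset", "data.frame")
    out
  })
}

#' Generate a synthetic drug-combination experiment with a known combination index
#'
#' Single-agent fraction-affected (Fa) values follow the median-effect
#' equation `fa / (1 - fa) = (D / Dm)^m`. Combination Fa values are solved
#' numerically (bisection on the log-odds of fa) so that the two-term
#' (mutually exclusive) Chou-Talalay combination index at every combination
#' point equals `interaction` when noise-free: `interaction` < 1 plants
#' synergy, 1 additivity, > 1 antagonism.
#'
#' @param dm_a,dm_b median-effect doses of drugs A and B (nM, > 0).
#' @param m_a,m_b median-effect shape parameters (> 0).
#' @param interaction target combination index (> 0).
#' @param doses data frame or 2-column matrix of (dose_a, dose_b) points;
#'   rows with one dose equal to 0 are single-agent points.
#' @param noise_cv log-normal noise CV applied to the odds fa/(1-fa).
#' @param seed integer seed.
#' @return data frame of class `combination_experiment` with columns
#'   `dose_a`, `dose_b`, `fa`, `flag` (`"ok"` or `"clipped"`), and attributes
#'   `truth` holding the generating parameters.
#' @export
gen_combination <- function(dm_a, m_a, dm_b, m_b, interaction, doses,
                            noise_cv = 0, seed = 1) {
  stopifnot(dm_a > 0, dm_b > 0, m_a > 0, m_b > 0, interaction > 0)
  doses <- as.data.frame(doses)
  names(doses)[1:2] <- c("dose_a", "dose_b")
  with_seed(seed, {
    fa <- numeric(nrow(doses))
    flag <- rep("ok", nrow(doses))
    for (i in seq_len(nrow(doses))) {
      da <- doses$dose_a[i]; db <- doses$dose_b[i]
      if (da == 0 && db == 0) {
        fa[i] <- 0; flag[i] <- "clipped"
      } else if (db == 0) {
        fa[i] <- 1 / (1 + (dm_a / da)^m_a)
      } else if (da == 0) {
        fa[i] <- 1 / (1 + (dm_b / db)^m_b)
      } else {
        # CI(fa) = da/Dx_a(fa) + db/Dx_b(fa) decreases monotonically in fa;
        # solve CI(fa) = interaction on the log-odds scale
        ci_of <- function(lo) {
          odds <- exp(lo)
          da / (dm_a * odds^(1 / m_a)) + db / (dm_b * odds^(1 / m_b)) -
            interaction
        }
        root <- stats::uniroot(ci_of, lower = -50, upper = 50, tol = 1e-12)
        fa[i] <- 1 / (1 + exp(-root$root))
      }
    }
    if (noise_cv > 0) {
      inner <- fa > 0 & fa < 1
      odds <- fa[inner] / (1 - fa[inner])
      odds <- odds * exp(stats::rnorm(sum(inner), 0, noise_cv))
      fa[inner] <- odds / (1 + odds)
    }
    clip <- fa <= 0 | fa >= 1
    fa[clip] <- pmin(pmax(fa[clip], 0), 1)
    flag[clip & flag == "ok"] <- "clipped"
    out <- data.frame(dose_a = doses$dose_a, dose_b = doses$dose_b,
                      fa = fa, flag = flag, stringsAsFactors = FALSE)
    attr(out, "truth") <- list(dm_a = dm_a, m_a = m_a, dm_b = dm_b, m_b = m_b,
                               interaction = interaction)
    class(out) <- c("combination_experiment", "data.frame")
    out
  })
}

#' Generate a synthetic xenograft efficacy study
#'
#' Per-animal tumor volumes grow exponentially at an arm-specific net rate
#' (`growth_rate_per_day - treatment_effect`); volumes are converted to
#' caliper length/width measurements at a fixed prolate aspect ratio of 1.6
#' (V = L * W^2 / 2) before per-dimension measurement noise. Body weights
#' follow a small random drift around 20 g. Animals can drop out (welfare
#' removal) at a per-study rate.
#'
#' @param arms list of arms, each a list with `name`, `n_mice`,
#'   `growth_rate_per_day` (1/day), `treatment_effect` (1/day subtracted from
#'   the growth rate; 0 for vehicle).
#' @param v0_mm3 tumor volume at randomization (day 0).
#' @param days measurement days (increasing, first should be 0).
#' @param noise_cv measurement noise CV on each caliper dimension.
#' @param dropout_rate probability an animal exits the study early.
#' @param seed integer seed.
#' @return data frame of class `xenograft_study` with columns `animal`, `arm`,
#'   `day`, `length_mm`, `width_mm`, `body_weight_g`; attribute `truth` holds
#'   the arm net growth rates.
#' @export
gen_xenograft <- function(arms, v0_mm3 = 150, days = seq(0, 28, by = 3.5),
                          noise_cv = 0, dropout_rate = 0, seed = 1) {
  if (!length(arms)) stop("at least one arm is required")
  if (v0_mm3 <= 0) stop("v0_mm3 must be positive")
  if (any(diff(days) <= 0)) stop("days must be increasing")
  aspect <- 1.6
  with_seed(seed, {
    rows <- list()
    net_rates <- numeric(0)
    animal_id <- 0L
    for (arm in arms) {
      arm <- as.list(arm)
      if (arm$n_mice < 1) stop("empty arm: ", arm$name)
      net <- arm$growth_rate_per_day - arm$treatment_effect
      net_rates[arm$name] <- net
      for (m in seq_len(arm$n_mice)) {
        animal_id <- animal_id + 1L
        last_day <- max(days)
        if (dropout_rate > 0 && stats::runif(1) < dropout_rate) {
          last_day <- sample(days[-1], 1)
        }
        d <- days[days <= last_day]
        v <- v0_mm3 * exp(net * d)
        w <- (v / (aspect / 2))^(1 / 3)       # V = L W^2/2 with L = aspect * W
        l <- aspect * w
        l <- l * rlnorm_cv(length(d), noise_cv)
        w <- w * rlnorm_cv(length(d), noise_cv)
        bw <- 20 + cumsum(stats::rnorm(length(d), 0, 0.15))
        rows[[length(rows) + 1L]] <- data.frame(
          animal = sprintf("M%03d", animal_id), arm = arm$name, day = d,
          length_mm = l, width_mm = w, body_weight_g = bw,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(net_rates = net_rates, v0 = v0_mm3,
                               aspect = aspect)
    class(out) <- c("xenograft_study", "data.frame")
    out
  })
}

#' Specify a synthetic expression cohort with a latent progression axis
#'
#' Describes a bulk RNA-seq tumor cohort whose expression is organized along a
#' latent progression axis ("pseudotime"): per-gene log2 mean expression is
#' `baseline + loading * z` where `z` is the standardized latent pseudotime,
#' plus a per-gene-by-batch technical shift. Tumor grade is the latent axis
#' binned into ordered levels; survival is coupled to the axis through a
#' proportional-hazards link.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param n_batches number of technical batches.
#' @param grade_levels ordered grade labels, low to high.
#' @param pseudotime_range numeric length-2, range of the latent axis.
#' @param module_loadings per-gene loading on the latent axis (recycled to
#'   `n_genes`); 0 means a null gene.
#' @param batch_shift_sd SD (log2 units) of per-gene batch shifts.
#' @param survival_link log-hazard coefficient on standardized pseudotime.
#' @param censor_rate fraction of subjects censored.
#' @param dispersion negative-binomial dispersion of counts.
#' @param frac_noncoding fraction of genes annotated with a non-coding
#'   biotype (these carry no signal and are removed by preprocessing).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 300, n_genes = 2000, n_batches = 3,
                        grade_levels = c("G1", "G2", "G3"),
                        pseudotime_range = c(0, 100),
                        module_loadings = 0,
                        batch_shift_sd = 0, survival_link = 0,
                        censor_rate = 0.3, dispersion = 0.1,
                        frac_noncoding = 0.05, seed = 1) {
  if (!length(grade_levels)) stop("grade_levels must be non-empty")
  if (n_batches > n_samples) stop("n_batches cannot exceed n_samples")
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must be in [0, 1]")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_batches = n_batches, grade_levels = grade_levels,
                 pseudotime_range = pseudotime_range,
                 module_loadings = rep_len(module_loadings, n_genes),
                 batch_shift_sd = batch_shift_sd,
                 survival_link = survival_link, censor_rate = censor_rate,
                 dispersion = dispersion, frac_noncoding = frac_noncoding,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic expression cohort
#'
#' @param spec a [cohort_spec()].
#' @return list of class `expression_cohort` with elements `counts`
#'   (genes x samples integer matrix), `metadata` (sample data frame: grade,
#'   histology, batch, survival_time, event), `annotation` (gene data frame
#'   with biotype), and `truth` (latent pseudotime, loadings, batch shifts).
#' @export
gen_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples; g <- spec$n_genes
    pt <- sort(stats::runif(n, spec$pseudotime_range[1],
                            spec$pseudotime_range[2]))
    z <- as.numeric(scale(pt))
    batch <- sample(rep_len(paste0("B", seq_len(spec$n_batches)), n))
    baseline <- stats::runif(g, 3, 8)
    loadings <- spec$module_loadings
    shifts <- matrix(stats::rnorm(g * spec$n_batches, 0, spec$batch_shift_sd),
                     nrow = g, dimnames = list(NULL,
                       paste0("B", seq_len(spec$n_batches))))
    logmu <- outer(baseline, rep(1, n)) + outer(loadings, z) +
      shifts[, batch, drop = FALSE]
    mu <- 2^logmu
    counts <- matrix(stats::rnbinom(g * n, mu = mu, size = 1 / spec$dispersion),
                     nrow = g)
    rownames(counts) <- sprintf("gene%04d", seq_len(g))
    colnames(counts) <- sprintf("S%03d", seq_len(n))
    # grade = latent axis binned into equal-width ordered levels
    k <- length(spec$grade_levels)
    breaks <- seq(spec$pseudotime_range[1], spec$pseudotime_range[2],
                  length.out = k + 1)
    grade <- cut(pt, breaks = breaks, labels = spec$grade_levels,
                 include.lowest = TRUE)
    grade <- factor(grade, levels = spec$grade_levels, ordered = TRUE)
    histology <- ifelse(as.integer(grade) == k, "serous", "endometrioid")
    haz <- 0.002 * exp(spec$survival_link * z)
    true_time <- stats::rexp(n, rate = haz)
    event <- as.integer(stats::runif(n) >= spec$censor_rate)
    time <- ifelse(event == 1, true_time, stats::runif(n) * true_time)
    biotype <- rep("protein_coding", g)
    n_nc <- round(spec$frac_noncoding * g)
    if (n_nc > 0) {
      nc_idx <- sample.int(g, n_nc)
      biotype[nc_idx] <- "lncRNA"
      # non-coding genes carry no progression signal
      loadings[nc_idx] <- 0
    }
    metadata <- data.frame(sample = colnames(counts), grade = grade,
                           histology = histology, batch = batch,
                           survival_time = time, event = event,
                           stringsAsFactors = FALSE)
    annotation <- data.frame(gene = rownames(counts), biotype = biotype,
                             stringsAsFactors = FALSE)
    structure(list(counts = counts, metadata = metadata,
                   annotation = annotation,
                   truth = list(pseudotime = stats::setNames(pt, colnames(counts)),
                                loadings = stats::setNames(loadings,
                                                           rownames(counts)),
                                batch_shifts = shifts, baseline = baseline)),
              class = "expression_cohort")
  })
}

#' Generate a synthetic flow-cytometry and qPCR assay panel
#'
#' Event-level flow data are drawn from two-component log-normal mixtures per
#' channel: the viability dye separates live (dim) from dead (bright) events;
#' EdU separates replicating (EdU+) from non-replicating cells among live
#' events; pRPS6 and p4EBP1 intensities shift multiplicatively under
#' treatment. A matching qPCR Ct table (target gene plus HPRT1/ACTB reference
#' genes under control and treated conditions) is generated alongside.
#'
#' @param n_events events per condition (>= 100).
#' @param live_frac fraction of live events.
#' @param edu_frac_ctrl,edu_frac_treated EdU-positive fraction among live
#'   cells in the control and treated conditions.
#' @param mfi_shift multiplicative treated/control shift of the pRPS6 and
#'   p4EBP1 intensity distributions (1 = no effect).
#' @param ct_effects named numeric, Ct shift (cycles, treated minus control)
#'   per gene; genes default to 0.
#' @param ct_replicates qPCR replicates per condition.
#' @param seed integer seed.
#' @return list of class `assay_panel` with `events` (per-event data frame
#'   with a `condition` column; conditions `"DMSO"` and `"treated"`),
#'   `unstained` (named per-channel background medians), and `ct` (Ct table).
#' @export
gen_assay_panel <- function(n_events = 10000, live_frac = 0.9,
                            edu_frac_ctrl = 0.5, edu_frac_treated = 0.2,
                            mfi_shift = 0.4,
                            ct_effects = c(PGR = 0), ct_replicates = 3,
                            seed = 1) {
  if (n_events < 100) stop("n_events must be >= 100 for stable medians")
  fr <- c(live_frac, edu_frac_ctrl, edu_frac_treated)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  with_seed(seed, {
    sim_condition <- function(cond, edu_frac, shift) {
      live <- stats::runif(n_events) < live_frac
      viability <- ifelse(live,
                          stats::rlnorm(n_events, log(100), 0.4),
                          stats::rlnorm(n_events, log(5000), 0.4))
      edupos <- live & (stats::runif(n_events) < edu_frac)
      edu <- ifelse(edupos,
                    stats::rlnorm(n_events, log(8000), 0.45),
                    stats::rlnorm(n_events, log(150), 0.45))
      prps6 <- stats::rlnorm(n_events, log(2000 * shift), 0.4)
      p4ebp1 <- stats::rlnorm(n_events, log(1500 * shift), 0.4)
      data.frame(condition = cond, viability_dye = viability, edu = edu,
                 prps6 = prps6, p4ebp1 = p4ebp1, stringsAsFactors = FALSE)
    }
    events <- rbind(sim_condition("DMSO", edu_frac_ctrl, 1),
                    sim_condition("treated", edu_frac_treated, mfi_shift))
    unstained <- c(viability_dye = 10, edu = 50, prps6 = 50, p4ebp1 = 50)
    genes <- unique(c(names(ct_effects), "HPRT1", "ACTB"))
    base_ct <- stats::setNames(stats::runif(length(genes), 19, 26), genes)
    base_ct["HPRT1"] <- 20; base_ct["ACTB"] <- 18
    ct_rows <- list()
    for (cond in c("control", "treated")) {
      for (r in seq_len(ct_replicates)) {
        shift <- if (cond == "treated") {
          vapply(genes, function(g)
            if (g %in% names(ct_effects)) ct_effects[[g]] else 0, numeric(1))
        } else rep(0, length(genes))
        ct_rows[[length(ct_rows) + 1L]] <- data.frame(
          sample = paste0(cond, "_", r), condition = cond, gene = genes,
          ct = base_ct + shift + stats::rnorm(length(genes), 0, 0.05),
          stringsAsFactors = FALSE)
      }
    }
    structure(list(events = events, unstained = unstained,
                   ct = do.call(rbind, ct_rows)),
              class = "assay_panel")
  })
}
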