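# shared fixture builders for the test suite

# minimal single-pair plate spec with configurable latent GR parameters
make_plate_spec <- function(gr_inf = -0.5, gec50 = 20, hill = 1,
                            doubling_h = 24, noise_cv = 0, seed = 1,
                            concentrations = default_ladder()) {
  plate_spec(cell_lines = "A", drugs = "drugX",
             concentrations = concentrations,
             doubling_time_h = c(A = doubling_h),
             gr_params = list("A:drugX" = list(gr_inf = gr_inf, gec50 = gec50,
                                               hill = hill)),
             noise_cv = noise_cv, seed = seed)
}

# raw well table for hand-computed GR cases: one vehicle + one treated dose
make_gr_hand_table <- function(x0 = 1000, xt_treated = 4000,
                               xt_vehicle = 8000, conc = 100) {
  data.frame(
    cell_line = "X", drug = c("DMSO", "drugX"), conc_nM = c(0, conc),
    replicate = 1L, signal_t0 = x0, signal_t = c(xt_vehicle, xt_treated),
    duration_h = 72)
}

# single-agent + combination dose design used by synergy tests
make_combo_doses <- function() {
  rbind(data.frame(dose_a = c(25, 50, 100, 200, 400, 800), dose_b = 0),
        data.frame(dose_a = 0, dose_b = c(100, 200, 400, 800, 1600, 3200)),
        data.frame(dose_a = c(50, 100, 200, 400),
                   dose_b = c(200, 400, 800, 1600)))
}

# brute-force minimum spanning tree by Pruefer-sequence enumeration of all
# labeled trees on k nodes (k <= 6); independent oracle for Prim's algorithm
brute_force_mst_weight <- function(d) {
  k <- nrow(d)
  if (k == 2) return(d[1, 2])
  decode_pruefer <- function(seq) {
    k <- length(seq) + 2
    degree <- rep(1L, k)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, k - 1, 2)
    ptr <- 0
    for (i in seq_along(seq)) {
      leaf <- min(which(degree == 1L))
      ptr <- ptr + 1
      edges[ptr, ] <- c(leaf, seq[i])
      degree[leaf] <- 0L
      degree[seq[i]] <- degree[seq[i]] - 1L
    }
    edges[k - 1, ] <- which(degree == 1L)
    edges
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), k - 2)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- decode_pruefer(seqs[i, ])
    w <- sum(d[e])
    if (w < best) best <- w
  }
  best
}

mst_weight <- function(d, edges) sum(d[edges])

# textbook two-group log-rank statistic: loop over event times accumulating
# observed minus expected and the hypergeometric variance
logrank_chisq_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d_t * n1 / n
    if (n > 1) v <- v + d_t * (n1 / n) * (1 - n1 / n) * (n - d_t) / (n - 1)
  }
  o_minus_e^2 / v
}

# small expression cohort with a planted progression axis
make_signal_cohort <- function(seed, n_samples = 300, n_genes = 2000,
                               n_loaded = 200, loading = 0.8,
                               batch_shift_sd = 0, survival_link = 0) {
  loadings <- c(rep(loading, n_loaded / 2), rep(-loading, n_loaded / 2),
                rep(0, n_genes - n_loaded))
  gen_expression_cohort(cohort_spec(
    n_samples = n_samples, n_genes = n_genes,
    module_loadings = loadings, batch_shift_sd = batch_shift_sd,
    survival_link = survival_link, seed = seed))
}
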