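# GR value computation, curve fitting, and derived metrics

test_that("GR values match the defining formula on hand-computed signals", {
  # k(c)/k(0) = log2(4)/log2(8) = 2/3, so GR = 2^(2/3) - 1
  grt <- compute_gr_table(make_gr_hand_table(1000, 4000, 8000))
  expect_equal(grt$gr_value[grt$drug == "drugX"], 2^(2 / 3) - 1,
               tolerance = 1e-12)
  # no net growth under treatment: complete cytostasis, GR = 0
  grt0 <- compute_gr_table(make_gr_hand_table(1000, 1000, 8000))
  expect_equal(grt0$gr_value[grt0$drug == "drugX"], 0, tolerance = 1e-12)
  # treated wells equal to vehicle: GR = 1
  grt1 <- compute_gr_table(make_gr_hand_table(1000, 8000, 8000))
  expect_equal(grt1$gr_value[grt1$drug == "drugX"], 1, tolerance = 1e-12)
  # vehicle GR is 1 by construction
  expect_equal(grt$gr_value[grt$conc_nM == 0], 1, tolerance = 1e-15)
})

test_that("GR computation flags bad wells and missing vehicles", {
  d <- make_gr_hand_table()
  expect_error(compute_gr_table(d[d$conc_nM > 0, ]), "vehicle")
  d2 <- rbind(d, data.frame(cell_line = "X", drug = "drugX", conc_nM = 300,
                            replicate = 1L, signal_t0 = 5, signal_t = 5,
                            duration_h = 72))
  expect_warning(compute_gr_table(d2, background = 10), "non-positive")
})

test_that("GR is independent of doubling time at zero noise", {
  grt_fast <- compute_gr_table(gen_dose_response(make_plate_spec(doubling_h = 20)))
  grt_slow <- compute_gr_table(gen_dose_response(make_plate_spec(doubling_h = 60)))
  expect_lt(max(abs(grt_fast$gr_value - grt_slow$gr_value)), 1e-9)
})

test_that("curve fit recovers noiseless generating parameters", {
  spec <- make_plate_spec(gr_inf = -0.5, gec50 = 20, hill = 1, noise_cv = 0)
  grt <- compute_gr_table(gen_dose_response(spec))
  fit <- fit_gr_curve(grt[grt$drug == "drugX", ])
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$gr_inf - (-0.5)) / 0.5, 1e-3)
  expect_lt(abs(fit$gec50 - 20) / 20, 1e-3)
  expect_lt(abs(fit$hill - 1), 1e-3)
  expect_equal(unname(coef(fit)["gec50"]), fit$gec50)
  expect_equal(predict(fit, 20), (-0.5 + 1.5 / 2), tolerance = 1e-3)
})

test_that("flat and degenerate inputs get the right fit status", {
  ladder <- default_ladder()
  flat <- data.frame(conc_nM = ladder, gr_value = 1)
  expect_equal(fit_gr_curve(flat)$status, "flat")
  expect_error(fit_gr_curve(data.frame(conc_nM = c(1, 10, 100),
                                       gr_value = c(1, 0.5, 0))), "4 distinct")
  # random GR values must essentially never earn a confident sigmoid
  ok <- vapply(1:100, function(s) {
    y <- local({set.seed(s); stats::runif(10, -1, 1)})
    fit_gr_curve(data.frame(conc_nM = ladder, gr_value = y))$status
  }, character(1))
  expect_lt(mean(ok == "ok"), 0.05)
})

test_that("GR50 solves the fitted curve analytically and respects sentinels", {
  spec <- make_plate_spec(gr_inf = -0.5, gec50 = 20, hill = 1, noise_cv = 0)
  grt <- compute_gr_table(gen_dose_response(spec))
  sl <- grt[grt$drug == "drugX", ]
  m <- gr_metrics_summary(fit_gr_curve(sl), sl)
  # -0.5 + 1.5 / (1 + c/20) = 0.5  =>  c = 10
  expect_equal(m$gr50, 10, tolerance = 1e-6)
  expect_equal(m$gr50_flag, "ok")
  # curve never reaching 0.5 yields the sentinel
  spec2 <- make_plate_spec(gr_inf = 0.8, gec50 = 100, hill = 1, noise_cv = 0)
  grt2 <- compute_gr_table(gen_dose_response(spec2))
  sl2 <- grt2[grt2$drug == "drugX", ]
  m2 <- gr_metrics_summary(fit_gr_curve(sl2), sl2)
  expect_true(is.na(m2$gr50))
  expect_equal(m2$gr50_flag, ">max_tested")
})

test_that("GRmax is the raw mean at the top dose and GRaoc the raw trapezoid", {
  ladder <- default_ladder()
  sl <- data.frame(conc_nM = ladder, gr_value = 0)
  fit <- fit_gr_curve(data.frame(conc_nM = ladder,
                                 gr_value = seq(1, -0.5, length.out = 10)))
  m <- gr_metrics_summary(fit, sl)
  expect_equal(m$gr_max, 0)
  expect_equal(m$gr_aoc, log10(27000 / 1.4), tolerance = 1e-12)
  ones <- data.frame(conc_nM = ladder, gr_value = 1)
  expect_equal(gr_metrics_summary(fit, ones)$gr_aoc, 0)
})

test_that("GRaoc is replicate-invariant and monotone in GR decreases", {
  ladder <- default_ladder()
  y <- seq(0.9, -0.3, length.out = 10)
  sl <- data.frame(conc_nM = ladder, gr_value = y)
  fit <- fit_gr_curve(sl)
  base <- gr_metrics_summary(fit, sl)$gr_aoc
  dup <- rbind(sl, sl)  # replicates of existing doses
  expect_equal(gr_metrics_summary(fit, dup)$gr_aoc, base, tolerance = 1e-12)
  y2 <- y; y2[5] <- y2[5] - 0.3
  expect_gt(gr_metrics_summary(fit, data.frame(conc_nM = ladder,
                                               gr_value = y2))$gr_aoc, base)
})

test_that("absolute IC50 is the 0.5 crossing of the fitted viability curve", {
  conc <- default_ladder()
  v <- 0.05 + (1 - 0.05) / (1 + (conc / 100)^1.5)
  # generating curve crosses 0.5 at 100 * ((0.95/0.45) - 1)^(1/1.5)
  crossing <- 100 * ((0.95 / 0.45) - 1)^(1 / 1.5)
  ic <- fit_viability_ic50(conc, v)
  expect_equal(ic$ic50, crossing, tolerance = 1e-3)
  expect_equal(ic$ic50_flag, "ok")
  high <- 0.85 + 0.1 / (1 + conc / 500)
  expect_equal(fit_viability_ic50(conc, high)$ic50_flag, ">max_tested")
})

test_that("sensitivity calls use strict per-drug cutoffs", {
  expect_true(classify_sensitivity("gedatolisib", 80))
  expect_false(classify_sensitivity("gedatolisib", 100))
  expect_false(classify_sensitivity("everolimus", 50))  # strict less-than
  expect_true(classify_sensitivity("everolimus", 49.9))
  expect_false(classify_sensitivity("alpelisib", NA))   # sentinel
  expect_error(classify_sensitivity("unknown_drug", 10), "cutoff")
})

test_that("gr_analysis drives all metrics per pair", {
  spec <- plate_spec(cell_lines = "A", drugs = c("gedatolisib", "alpelisib"),
                     doubling_time_h = c(A = 24),
                     gr_params = list(
                       "A:gedatolisib" = list(gr_inf = -0.4, gec50 = 30, hill = 1),
                       "A:alpelisib" = list(gr_inf = 0.3, gec50 = 2000, hill = 1)),
                     noise_cv = 0.02, seed = 3)
  res <- gr_analysis(gen_dose_response(spec))
  expect_s3_class(res$gr_table, "gr_table")
  expect_equal(nrow(res$metrics), 2)
  expect_true(all(c("gr50", "gr_max", "gr_aoc", "ic50", "sensitive") %in%
                  names(res$metrics)))
  expect_true(res$metrics$sensitive[res$metrics$drug == "gedatolisib"])
})
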