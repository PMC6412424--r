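# R-peak detection, isoelectric estimation and per-beat delineation.

test_that("monotone error profiles yield no candidates and plateaus break leftmost", {
  # hand-built profile objects exercise the local-minimum rule directly
  mk_prof <- function(eps, a) {
    structure(list(center = seq.int(2L, 1L + length(eps)), a = a, v = a,
                   epsilon = eps, w = 2L, fs = 500), class = "fit_profile")
  }
  mono <- mk_prof(seq(1, 2, length.out = 10), rep(-1, 10))
  expect_length(find_error_minima(mono, 1e-4, "either"), 0L)
  plat <- mk_prof(c(5, 3, 3, 3, 5, 6), rep(-1, 6))
  expect_identical(find_error_minima(plat, 1e-4, "max"), 3L)  # leftmost of run
  # magnitude and sign filters
  dip <- mk_prof(c(5, 1, 5), c(-1, -5e-5, -1))
  expect_length(find_error_minima(dip, 1e-4, "max"), 0L)  # |a| too small
  dip2 <- mk_prof(c(5, 1, 5), c(1, 1, 1))
  expect_length(find_error_minima(dip2, 1e-4, "max"), 0L) # wrong sign
  expect_identical(find_error_minima(dip2, 1e-4, "min"), 3L)
})

test_that("a single Gaussian peak produces exactly one candidate at its apex", {
  sig <- gaussian_peak_signal(n = 600, apex = 300, sigma = 8)
  prof <- error_profile(sig, 15L)
  cand <- find_error_minima(prof, 5e-4, "max")
  expect_length(cand, 1L)
  expect_lt(abs(cand - 300), 2)
})

test_that("R peaks of a clean synthetic record are all found within 10 ms", {
  gen <- generate_ecg(n_beats = 10, rr_mean = 1.0, seed = 31)
  pre <- preprocess_ecg(gen$signal)
  r <- detect_r_peaks(pre)
  truth <- gen$annotations$index[gen$annotations$label == "R"]
  expect_identical(nrow(r), 10L)
  expect_true(all(abs(r$index - truth) <= 5))  # 10 ms at 500 Hz
  # inverted signal: no upward R peaks to find
  inv <- ecg_signal(-pre$samples, 500)
  expect_identical(nrow(detect_r_peaks(inv)), 0L)
})

test_that("R detection is robust to moderate in-band noise", {
  gen0 <- generate_ecg(n_beats = 10, seed = 32)
  r0 <- detect_r_peaks(preprocess_ecg(gen0$signal))
  # 2% of R amplitude at 25 Hz: ripple curvature stays well under the R
  # threshold even stacked on the T wave; detections are unchanged
  gen1 <- generate_ecg(n_beats = 10, seed = 32,
                       noise = noise_spec(powerline_amp = 0.02, powerline_freq = 25))
  r1 <- detect_r_peaks(preprocess_ecg(gen1$signal))
  expect_identical(nrow(r0), nrow(r1))
  expect_true(all(abs(r0$index - r1$index) <= 1))
  # 5% ripple can push a T apex over the R curvature threshold (the
  # margin between T and R curvature is finite); the true R apices must
  # nevertheless stay put
  gen2 <- generate_ecg(n_beats = 10, seed = 32,
                       noise = noise_spec(powerline_amp = 0.05, powerline_freq = 25))
  r2 <- detect_r_peaks(preprocess_ecg(gen2$signal))
  expect_true(all(vapply(r0$index,
                         function(i) min(abs(r2$index - i)) <= 1, logical(1))))
})

test_that("isoelectric level recovers the construction baseline", {
  expect_equal(estimate_isoelectric_level(ecg_signal(rep(0, 500), 500)), 0)
  gen <- generate_ecg(default_template(baseline_level = 0.1),
                      n_beats = 10, seed = 33)
  iso <- estimate_isoelectric_level(gen$signal)
  # gentle wave shoulders pass the flatness gates and bias the mean
  # upward by a few hundredths of a mV; 0.05 bounds the observed bias
  expect_lt(abs(iso - 0.1), 0.05)
  expect_gt(iso, 0.1)  # the bias is upward (waves are net positive)
  # pure steep parabola: never line-like, median fallback fires
  i <- 0:499
  steep <- ecg_signal(1e-2 * (i - 250)^2, 500)
  expect_warning(lvl <- estimate_isoelectric_level(steep), "median")
  expect_equal(lvl, stats::median(steep$samples))
})

test_that("a clean beat yields all five waves at their true apices", {
  # deepen Q so its rendered apex (partly filled in by the R upslope)
  # clears the lower margin: template -0.18 renders near -0.15
  tpl <- default_template()
  tpl$waves$amplitude_mv[tpl$waves$label == "Q"] <- -0.18
  gen <- generate_ecg(tpl, n_beats = 3, seed = 34, rr_sd = 0)
  pre <- gen$signal  # noiseless; no preprocessing needed
  r_idx <- gen$annotations$index[gen$annotations$label == "R"][2]
  half <- 192L
  beat <- ecg_signal(pre$samples[(r_idx - half):(r_idx + half) + 1], 500)
  ann <- detect_pqrst(beat, half, iso_level = 0)
  expect_setequal(ann$label, c("P", "Q", "R", "S", "T"))
  truth <- gen$annotations[abs(gen$annotations$index - r_idx) <= half, ]
  for (l in truth$label) {
    expect_lt(abs(ann$index[ann$label == l] -
                  (truth$index[truth$label == l] - r_idx + half)), 6)
  }
  # label ordering within the beat
  ord <- ann$index[match(c("P", "Q", "R", "S", "T"), ann$label)]
  expect_true(all(diff(ord) > 0))
})

test_that("a Q wave inside the isoelectric margin is absent, never mislabelled", {
  tpl <- default_template()
  tpl$waves$amplitude_mv[tpl$waves$label == "Q"] <- -0.04
  gen <- generate_ecg(tpl, n_beats = 3, seed = 35, rr_sd = 0)
  r_idx <- gen$annotations$index[gen$annotations$label == "R"][2]
  beat <- ecg_signal(gen$signal$samples[(r_idx - 192):(r_idx + 192) + 1], 500)
  ann <- detect_pqrst(beat, 192L, iso_level = 0)
  expect_false("Q" %in% ann$label)
  expect_true(all(c("P", "R", "S", "T") %in% ann$label))
})

test_that("a flat beat yields only the R row it was given", {
  beat <- ecg_signal(rep(0, 385), 500)
  ann <- detect_pqrst(beat, 192L, iso_level = 0)
  expect_true(all(ann$label == "R"))
  expect_error(detect_pqrst(beat, 500L, 0), "outside")
})

test_that("detection is deterministic and labels are ordered on random morphologies", {
  set.seed(36)
  for (k in 1:5) {
    tpl <- random_template()
    gen <- generate_ecg(tpl, n_beats = 8, seed = k, rr_seed = k + 100)
    res1 <- delineate_ecg(gen$signal)
    res2 <- delineate_ecg(gen$signal)
    expect_identical(res1$annotations, res2$annotations)
    ann <- res1$annotations
    # within each beat (nearest R), indices respect P < Q < R < S < T
    rt <- ann$index[ann$label == "R"]
    for (r in rt) {
      beat <- ann[abs(ann$index - r) < 200, ]
      ord <- beat$index[match(c("P", "Q", "R", "S", "T"), beat$label)]
      expect_true(all(diff(ord[!is.na(ord)]) > 0))
    }
  }
})

test_that("every annotation lies on or beside the local extremum of the trace", {
  # the error minimum marks the fitted vertex; asymmetric neighbours
  # (the R upslope inside a Q window) can shift it by a sample or two
  # relative to the raw sample extremum, well inside the 10 ms tolerance
  gen <- generate_ecg(n_beats = 8, seed = 37)
  res <- delineate_ecg(gen$signal)
  y <- res$signal$samples
  w <- pqrst_window_halfwidth(500)
  for (k in seq_len(nrow(res$annotations))) {
    i <- res$annotations$index[k] + 1
    lab <- res$annotations$label[k]
    lo <- max(1, i - w); hi <- min(length(y), i + w)
    ext <- if (lab %in% c("P", "R", "T")) which.max(y[lo:hi]) else which.min(y[lo:hi])
    expect_lte(abs(lo + ext - 1L - i), 3L)
  }
})

test_that("detector configuration validates its invariants", {
  expect_error(detector_config(a_min_r = -1), "> 0")
  expect_error(detector_config(min_peak_distance_ms = 300), "r_refractory")
  expect_s3_class(detector_config(), "detector_config")
})
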