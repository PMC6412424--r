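# Sensitivity metric: tolerance matching and pooling.

ann <- function(label, index, fs = 500, rec = "r1")
  fiducial_annotations(label, index, amplitude = rep(0, length(index)),
                       fs = fs, record_id = rec)

test_that("identical annotation sets match completely", {
  a <- ann(c("P", "R", "T"), c(10, 100, 220))
  m <- match_annotations(a, a, tolerance_ms = 10, fs = 500)
  expect_equal(m$matched, m$total)
  rep <- sensitivity(a, a, tolerance_ms = 10, fs = 500)
  expect_true(all(rep$per_label == 100))
})

test_that("the tolerance boundary is inclusive", {
  fs <- 1000
  refp <- ann("R", 100, fs = fs)
  # 10 ms at 1 kHz = 10 samples: exactly at the boundary -> matched
  expect_equal(match_annotations(ann("R", 110, fs = fs), refp, 10, fs)$matched, 1L)
  # 11 samples = 11 ms -> unmatched
  expect_equal(match_annotations(ann("R", 111, fs = fs), refp, 10, fs)$matched, 0L)
})

test_that("each detected point consumes at most one reference, nearest first", {
  refp <- ann("R", c(100, 104))
  det <- ann("R", 101)
  m <- match_annotations(det, refp, tolerance_ms = 10, fs = 500)
  expect_equal(m$matched, 1L)
  expect_equal(m$total, 2L)
})

test_that("greedy matching equals brute-force optimal assignment on small instances", {
  # brute force: maximise the number of within-tolerance pairs over all
  # one-to-one assignments (references to detections)
  brute <- function(refi, deti, tol) {
    if (!length(refi) || !length(deti)) return(0L)
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    best <- 0L
    for (p in perms(seq_along(deti))) {
      k <- min(length(refi), length(deti))
      ok <- abs(refi[seq_len(k)] - deti[p[seq_len(k)]]) <= tol
      best <- max(best, sum(ok))
    }
    best
  }
  set.seed(51)
  for (trial in 1:20) {
    refi <- sort(sample(0:300, sample(1:5, 1)))
    deti <- sort(sample(0:300, sample(1:5, 1)))
    m <- match_annotations(ann("R", deti), ann("R", refi), 20, 500)
    expect_equal(m$matched, brute(refi, deti, 10))  # 20 ms at 500 Hz = 10 samples
  }
})

test_that("uniform jitter within the tolerance still matches everything", {
  set.seed(52)
  refi <- seq(100, 4000, by = 400)
  jit <- round(stats::runif(length(refi), -4, 4))  # +/- 8 ms at 500 Hz
  m <- match_annotations(ann("R", refi + jit), ann("R", refi), 10, 500)
  expect_equal(m$matched, m$total)
})

test_that("pooled counts reproduce printed-table arithmetic", {
  # 6845 of 7020 Q points matched -> 97.5% to one decimal
  set.seed(53)
  idx <- seq(0, by = 50, length.out = 7020)
  refp <- ann("Q", idx)
  det <- ann("Q", idx[seq_len(6845)])
  rep <- sensitivity(det, refp, tolerance_ms = 10, fs = 500)
  expect_equal(round(rep$per_label[["Q"]], 1), 97.5)
  # empty detections -> 0% for every referenced label
  none <- sensitivity(ann("R", 10)[0, ], refp, 10, 500)
  expect_equal(none$per_label[["Q"]], 0)
})

test_that("labels without references are undefined rather than zero", {
  refp <- ann("R", c(100, 500))
  det <- ann(c("R", "P"), c(100, 50))
  rep <- sensitivity(det, refp, 10, 500)
  expect_false("P" %in% names(rep$per_label))
  expect_equal(rep$per_label[["R"]], 50)  # one of two R references matched
})

test_that("sensitivity is record-order invariant and monotone in tolerance", {
  set.seed(54)
  mk <- function(rec) {
    idx <- sort(sample(0:5000, 12))
    list(ref = ann("R", idx, rec = rec),
         det = ann("R", idx + round(stats::rnorm(12, 0, 4)), rec = rec))
  }
  recs <- lapply(c("a", "b", "c"), mk)
  det <- do.call(rbind, lapply(recs, `[[`, "det"))
  refp <- do.call(rbind, lapply(recs, `[[`, "ref"))
  fwd <- sensitivity(det, refp, 10, 500)
  bwd <- sensitivity(det[rev(seq_len(nrow(det))), ], refp[rev(seq_len(nrow(refp))), ], 10, 500)
  expect_equal(fwd$per_label, bwd$per_label)
  tols <- c(2, 6, 10, 20)
  vals <- vapply(tols, function(tl) sensitivity(det, refp, tl, 500)$per_label[["R"]],
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("two single-record tables with different ids are aligned with a message", {
  det <- ann("R", c(100, 500), rec = "detected-file")
  refp <- ann("R", c(100, 500), rec = "truth-file")
  expect_message(rep <- sensitivity(det, refp, 10, 500), "aligning")
  expect_equal(rep$per_label[["R"]], 100)
})

test_that("record-level pooling counts whole records", {
  refp <- rbind(ann("R", c(100, 500), rec = "a"), ann("R", c(100, 500), rec = "b"))
  det <- rbind(ann("R", c(100, 500), rec = "a"), ann("R", c(100, 900), rec = "b"))
  rep <- sensitivity(det, refp, 10, 500, level = "record")
  expect_equal(rep$per_label[["R"]], 50)  # one of two records fully matched
})
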