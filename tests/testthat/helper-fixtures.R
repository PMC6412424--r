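# Shared fixtures and oracles for the suite. Everything is generated in
# code; no binary files are shipped.

# generic two-parameter least-squares oracle: solve the normal equations
# for y ~ a * x + v with plain lm-style linear algebra, independent of the
# closed-form slope/intercept path used by the package
ls_oracle <- function(x, y) {
  fit <- stats::lm.fit(cbind(x = x, v = 1), y)
  list(a = unname(fit$coefficients[1]), v = unname(fit$coefficients[2]),
       epsilon = mean(fit$residuals^2))
}

# parabola-fit oracle for a window of `signal` centred at `center`
window_oracle <- function(signal, center, w) {
  j <- (center - w):(center + w)
  ls_oracle(as.numeric(center - j)^2, signal$samples[j + 1])
}

# drop non-R reference annotations belonging to the first and last beat:
# segmentation excludes those beats by construction, so the pipeline
# never delineates them
interior_refs <- function(ref) {
  rt <- ref$index[ref$label == "R"]
  own <- vapply(ref$index, function(i) rt[which.min(abs(rt - i))], numeric(1))
  ref[ref$label == "R" | (own != min(rt) & own != max(rt)), , drop = FALSE]
}

# evaluate descending-order polynomial coefficients on a numeric grid
eval_poly_desc <- function(coefs, u) {
  drop(outer(u, (length(coefs) - 1):0, `^`) %*% coefs)
}

# single clean Gaussian peak riding on a flat baseline
gaussian_peak_signal <- function(n = 400, apex = 200, sigma = 10, amp = 1,
                                 fs = 500) {
  i <- seq_len(n) - 1
  ecg_signal(amp * exp(-((i - apex)^2) / (2 * sigma^2)), fs, "gauss")
}
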