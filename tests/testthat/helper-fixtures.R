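# Shared fixture builders and independent oracles.

# well-separated two-system glucosidase-like parameter draw (inside the
# printed field ranges, LA Km within the assayed ladder)
draw_m4_params <- function() {
  c(Vmax_HA = runif(1, 5, 50), Km_HA = runif(1, 0.3, 6),
    Vmax_LA = runif(1, 50, 400), Km_LA = runif(1, 30, 300))
}

noiseless_curve <- function(model, params, ladder = build_ladder("BG")) {
  simulate_response_curve(model, params, ladder = ladder,
                          noise_cv = 0, noise_floor = 0, seed = 1L)
}

fit_all <- function(curve) {
  fits <- list()
  for (m in c("M1", "M2", "M3", "M4")) {
    f <- try(fit_model(curve, m), silent = TRUE)
    if (!inherits(f, "try-error")) fits[[m]] <- f
  }
  fits
}

# independent oracle: exhaustive enumeration of every contiguous aligned
# segment at every offset |d| <= D, with the same tie-break rules
ls_brute_force <- function(x, y, D) {
  n <- length(x)
  cand <- list()
  for (d in -D:D) {
    if (d >= 0) { i <- seq_len(n - d); j <- i + d } else { j <- seq_len(n + d); i <- j - d }
    m <- length(i)
    for (a in seq_len(m)) for (b in a:m) {
      s <- sum(x[i[a:b]] * y[j[a:b]])
      cand[[length(cand) + 1L]] <- c(score = abs(s) / n, sgn = sign(s), d = d)
    }
  }
  cd <- do.call(rbind, cand)
  mx <- max(cd[, "score"])
  if (mx < 1e-12) return(c(score = 0, sgn = 1, d = 0))
  sel <- cd[cd[, "score"] >= mx - 1e-12, , drop = FALSE]
  sel[order(abs(sel[, "d"]), -sel[, "sgn"], -sel[, "d"])[1L], ]
}

# simulated plate: product accumulates linearly at the model rate, read as
# fluorescence through a known standard line on top of a background series
make_plate <- function(rates_by_S, times = c(0, 3, 6), slope = 2,
                       intercept = 50, background = function(t) 100 + 0 * t,
                       sample_id = "plate1", enzyme = "BG") {
  wells <- do.call(rbind, lapply(seq_along(rates_by_S), function(k) {
    S <- as.numeric(names(rates_by_S)[k])
    prod_nM <- rates_by_S[[k]] * times
    data.frame(well = sprintf("W%02d", k), substrate_conc_uM = S,
               time_h = times,
               fluorescence = background(times) + intercept + slope * prod_nM)
  }))
  # blank wells carry the background only; the reagent intercept belongs to
  # the calibration line and is removed by the standard-curve conversion
  blanks <- data.frame(time_h = rep(times, 2),
                       fluorescence = rep(background(times), 2))
  plate_timecourse(sample_id, enzyme, wells, blanks)
}

std_exact <- function(slope = 2, intercept = 50, standard = "MUF") {
  conc <- c(0, 100, 250, 500)
  fit_standard_curve(
    data.frame(conc_nM = conc, fluorescence = intercept + slope * conc),
    standard = standard)
}
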