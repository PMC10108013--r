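#' Simulate a noisy kinetic response curve
#'
#' Draws observed hydrolysis rates around the chosen true model:
#' `V_obs = V_true * (1 + e_mult) + e_add`, with `e_mult ~ N(0, noise_cv)`
#' and `e_add ~ N(0, noise_floor)`, independently per replicate well.
#' Fluorescence-based rate measurements scale roughly with signal, hence
#' the multiplicative term; the small additive floor models read noise near
#' the detection limit. Defaults mirror the field assay: 12-level
#' half-dilution ladder, 4 replicates, 5% CV, 0.5 nM h^-1 floor.
#'
#' @param true_model Model identifier (see [model_spec()]).
#' @param true_params Named parameter vector for `true_model`.
#' @param ladder A [build_ladder()] object (default: glucosidase ladder,
#'   top 300 uM, 12 levels).
#' @param n_replicates Replicates per level (default: the ladder's).
#' @param noise_cv Multiplicative noise coefficient of variation
#'   (default 0.05).
#' @param noise_floor Additive noise SD in nM h^-1 (default 0.5).
#' @param seed Integer seed; the curve is deterministic given the seed.
#' @param sample_id,bacterial_abundance Passed to [response_curve()].
#' @return A [response_curve()] whose attribute `"truth"` records the
#'   generating model and parameters.
#' @export
simulate_response_curve <- function(true_model, true_params,
                                    ladder = build_ladder("BG"),
                                    n_replicates = NULL,
                                    noise_cv = 0.05, noise_floor = 0.5,
                                    seed = 1L,
                                    sample_id = "sim",
                                    bacterial_abundance = NA_real_) {
  stopifnot(inherits(ladder, "substrate_ladder"))
  true_params <- model_params(true_model, true_params)
  if (noise_cv < 0 || noise_floor < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  if (is.null(n_replicates)) n_replicates <- ladder$n_replicates
  S <- rep(ladder$concentrations, each = n_replicates)
  mu <- eval_model_raw(true_model, true_params, S)
  V <- withr::with_seed(seed, {
    mu * (1 + rnorm(length(S), 0, noise_cv)) + rnorm(length(S), 0, noise_floor)
  })
  cv <- response_curve(sample_id, ladder$enzyme, S = S, V = V,
                       replicate = rep(seq_len(n_replicates),
                                       times = length(ladder$concentrations)),
                       bacterial_abundance = bacterial_abundance)
  attr(cv, "truth") <- list(model = true_model, params = true_params,
                            noise_cv = noise_cv, noise_floor = noise_floor,
                            seed = seed)
  cv
}

#' Describe a synthetic seasonal campaign
#'
#' Ground-truth recipe for [simulate_campaign()]: a monthly coastal
#' time-series with recurring bloom-like pulses and known 0/1-month-lagged
#' couplings between variables. The default emulates a temperate coastal
#' station sampled roughly monthly over ~2.7 years (32 months with 5 random
#' dropout months, leaving 27 samples): a chlorophyll-like spring bloom, a
#' cyanobacteria-like late-summer bloom, two uncoupled bacterial-group
#' series, and two kinetic-parameter-like variables driven by the blooms —
#' one positively at a 1-month lag (substrate released by a collapsing bloom
#' reaches the bacteria a sampling interval later) and one negatively with
#' no lag.
#'
#' Each variable is a sum of annual Gaussian pulses
#' `amp * exp(-(m - month)^2 / (2 width^2))` (in months, wrapped around the
#' year) plus white noise; each planted coupling adds
#' `strength * sign * source(t - lag)` to its target.
#'
#' @param start First sampling date (default `"2011-02-01"`).
#' @param n_months Campaign length in months (default 32).
#' @param n_dropout Months removed at random, emulating missed cruises
#'   (default 5).
#' @param variables Named list; each element a list with `pulses` (list of
#'   `c(month, width, amp)` vectors, possibly empty) and `noise_sd`.
#' @param couplings List of lists with `source`, `target`, `lag` (0 or 1),
#'   `sign` (+1/-1), `strength`.
#' @param seed Integer seed.
#' @return Object of class `campaign_truth`.
#' @export
campaign_truth <- function(start = as.Date("2011-02-01"),
                           n_months = 32L, n_dropout = 5L,
                           variables = NULL, couplings = NULL,
                           seed = 1L) {
  if (is.null(variables)) {
    variables <- list(
      chl_a         = list(pulses = list(c(month = 4, width = 1, amp = 3)),
                           noise_sd = 0.5),
      cyanobacteria = list(pulses = list(c(month = 9, width = 1, amp = 3)),
                           noise_sd = 0.5),
      bacteroidetes = list(pulses = list(), noise_sd = 0.5),
      sar11         = list(pulses = list(), noise_sd = 0.5),
      LAP_spVmax_HA = list(pulses = list(), noise_sd = 0.5),
      BG_spVmax_HA  = list(pulses = list(), noise_sd = 0.5)
    )
  }
  if (is.null(couplings)) {
    couplings <- list(
      list(source = "chl_a", target = "LAP_spVmax_HA",
           lag = 1L, sign = 1, strength = 1.2),
      list(source = "cyanobacteria", target = "BG_spVmax_HA",
           lag = 0L, sign = -1, strength = 1.2)
    )
  }
  n_months <- as.integer(n_months)
  if (n_months < 24L) stop("need >= 24 months for delay detection power", call. = FALSE)
  for (cp in couplings) {
    if (!cp$source %in% names(variables) || !cp$target %in% names(variables)) {
      stop("coupling names unknown variable(s)", call. = FALSE)
    }
    if (!cp$lag %in% c(0L, 1L)) stop("lags must be 0 or 1 month", call. = FALSE)
  }
  structure(
    list(start = as.Date(start), n_months = n_months,
         n_dropout = as.integer(n_dropout), variables = variables,
         couplings = couplings, seed = as.integer(seed)),
    class = "campaign_truth"
  )
}

seasonal_signal <- function(month_of_year, pulses) {
  sig <- numeric(length(month_of_year))
  for (p in pulses) {
    dm <- abs(month_of_year - p[["month"]])
    dm <- pmin(dm, 12 - dm) # wrap around the year
    sig <- sig + p[["amp"]] * exp(-dm^2 / (2 * p[["width"]]^2))
  }
  sig
}

#' Simulate a seasonal multivariate campaign
#'
#' Realizes the recipe in a [campaign_truth()]: monthly dates, seasonal
#' pulse + noise base signals, planted lagged couplings, and random dropout
#' months recorded as missing values across all variables. Deterministic
#' given the truth's seed.
#'
#' @param truth A [campaign_truth()].
#' @return List with `table` (data frame: `date` plus one column per
#'   variable) and `truth` (the input, for recovery scoring).
#' @export
simulate_campaign <- function(truth) {
  stopifnot(inherits(truth, "campaign_truth"))
  n <- truth$n_months
  dates <- seq(truth$start, by = "month", length.out = n)
  moy <- as.integer(format(dates, "%m"))
  withr::with_seed(truth$seed, {
    base <- lapply(truth$variables, function(v) {
      seasonal_signal(moy, v$pulses) + rnorm(n, 0, v$noise_sd)
    })
    series <- base
    for (cp in truth$couplings) {
      src <- base[[cp$source]]
      shifted <- if (cp$lag == 0L) src else c(rep(NA_real_, cp$lag),
                                              head(src, n - cp$lag))
      add <- ifelse(is.na(shifted), 0, cp$strength * cp$sign * shifted)
      series[[cp$target]] <- series[[cp$target]] + add
    }
    tab <- data.frame(date = dates)
    for (nm in names(series)) tab[[nm]] <- series[[nm]]
    if (truth$n_dropout > 0L) {
      drop <- sort(sample(2:(n - 1L), truth$n_dropout))
      tab[drop, -1L] <- NA_real_
    }
    list(table = tab, truth = truth)
  })
}
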