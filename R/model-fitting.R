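#' Small-sample corrected Akaike information criterion for least squares
#'
#' Least-squares form with the residual variance counted as a parameter:
#' with `k = n_params + 1`,
#' `AICc = n * ln(RSS / n) + 2k + 2k(k + 1) / (n - k - 1)`.
#' A machine-epsilon floor is applied to `RSS` so that interpolating fits
#' (RSS = 0 on noiseless data) remain comparable: all models reaching the
#' floor are then ranked purely by their parameter count.
#'
#' @param RSS Residual sum of squares ((nM h^-1)^2), >= 0.
#' @param n_points Number of fitted points.
#' @param n_params Number of kinetic parameters (excluding the error
#'   variance).
#' @return The AICc value.
#' @examples
#' aicc(RSS = 10, n_points = 10, n_params = 2) # 10 * log(1) + 6 + 4 = 10
#' @export
aicc <- function(RSS, n_points, n_params) {
  if (!is.finite(RSS) || RSS < 0) stop("'RSS' must be finite and >= 0", call. = FALSE)
  k <- n_params + 1
  if (n_points <= k + 1) {
    stop("AICc undefined: n_points must exceed n_params + 2", call. = FALSE)
  }
  RSS <- max(RSS, .Machine$double.eps)
  n_points * log(RSS / n_points) + 2 * k + 2 * k * (k + 1) / (n_points - k - 1)
}

## ---- multi-start machinery ------------------------------------------------

## parameters are bounded below by zero and unbounded above: a finite upper
## Km bound would cut M3's linear limit out of M4's closure and break the
## nested-RSS ordering; implausibly large Km estimates are reported with
## extrapolation flags instead of being constrained away
param_bounds <- function(model_id) {
  nm <- model_spec(model_id)$parameter_names
  list(lower = setNames(rep(0, length(nm)), nm),
       upper = setNames(rep(Inf, length(nm)), nm))
}

## single Levenberg-Marquardt run; returns par/RSS/ok
lm_run <- function(model_id, start, S, V) {
  b <- param_bounds(model_id)
  start <- pmin(pmax(start, b$lower), b$upper)
  fit <- try(minpack.lm::nls.lm(
    par = start, lower = b$lower, upper = b$upper,
    fn = function(p) V - eval_model_raw(model_id, p, S),
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-10, maxiter = 500, maxfev = 10000)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  list(par = fit$par, RSS = sum(fit$fvec^2), ok = fit$info %in% 1:3)
}

## deterministic start grid
start_pool <- function(model_id, S, V) {
  lv <- sort(unique(S))
  Smin <- min(lv); Smed <- median(lv); Smax <- max(lv)
  V0 <- max(max(V), .Machine$double.eps)
  b_ols <- max(sum(S * V) / sum(S^2), 0) # nM h^-1 per uM, slope through origin
  Kms <- c(Smin, Smed, Smax, 3 * Smax)
  pool <- list()
  add <- function(p) pool[[length(pool) + 1L]] <<- p

  if (model_id == "M2") {
    for (km in Kms) for (vm in c(V0, 2 * V0)) {
      add(c(Vmax = vm, Km = km))
    }
  } else if (model_id == "M3") {
    add(c(Vmax_HA = 0.1 * V0, Km_HA = Smin, Tt_LA = b_ols / 1000))
    for (km in Kms) for (vm in c(V0, 2 * V0)) {
      add(c(Vmax_HA = vm, Km_HA = km, Tt_LA = b_ols / 2 / 1000))
    }
  } else if (model_id == "M4") {
    pairs <- which(outer(Kms, Kms, "<"), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      kha <- Kms[pairs[r, 1L]]; kla <- Kms[pairs[r, 2L]]
      add(c(Vmax_HA = V0, Km_HA = kha, Vmax_LA = V0, Km_LA = kla))
      add(c(Vmax_HA = V0, Km_HA = kha, Vmax_LA = 2 * V0, Km_LA = kla))
    }
  }
  pool
}

## warm starts for the two-system models: the solutions of their fully
## fitted nested submodels, embedded so the start's RSS already equals the
## submodel's optimum (M2 inside M3 via Tt_LA = 0; M2 inside M4 via
## Vmax_LA = 0; M3 inside M4 approximately, mapping the linear LA term to a
## large-Km Michaelis-Menten term of equal initial slope). These keep the
## fitted RSS ordering of the nested hierarchy within optimizer tolerance.
warm_starts <- function(model_id, curve, S, V) {
  warm <- list()
  Smax <- max(S)
  b_ols <- max(sum(S * V) / sum(S^2), 0)
  sub <- function(m) {
    f <- try(fit_model(curve, m), silent = TRUE)
    if (!inherits(f, "try-error") && f$converged) f$estimates else NULL
  }
  if (model_id == "M3") {
    e2 <- sub("M2")
    if (!is.null(e2)) {
      warm <- list(
        c(Vmax_HA = e2[["Vmax"]], Km_HA = e2[["Km"]], Tt_LA = 0),
        c(Vmax_HA = e2[["Vmax"]], Km_HA = e2[["Km"]], Tt_LA = b_ols / 10 / 1000))
    }
  } else if (model_id == "M4") {
    e3 <- sub("M3")
    if (!is.null(e3)) {
      for (km_la in c(50, 1e4) * Smax) {
        warm <- c(warm, list(
          c(Vmax_HA = e3[["Vmax_HA"]], Km_HA = e3[["Km_HA"]],
            Vmax_LA = e3[["Tt_LA"]] * 1000 * km_la, Km_LA = km_la)))
      }
    }
    e2 <- sub("M2")
    if (!is.null(e2)) {
      warm <- c(warm, list(
        c(Vmax_HA = e2[["Vmax"]], Km_HA = e2[["Km"]], Vmax_LA = 0,
          Km_LA = 10 * e2[["Km"]] + Smax),
        c(Vmax_HA = e2[["Vmax"]] / 2, Km_HA = e2[["Km"]] / 2,
          Vmax_LA = e2[["Vmax"]] / 2, Km_LA = 2 * e2[["Km"]])))
    }
  }
  warm
}

#' Fit one kinetic model to a response curve
#'
#' Minimizes the residual sum of squares of [eval_model()] against the
#' replicate-level points of a response curve (no pre-averaging; zero
#' substrate wells are excluded) by bounded Levenberg–Marquardt nonlinear
#' least squares from a deterministic grid of starting values plus warm
#' starts obtained from cheaper nested fits. `M1` is linear through the
#' origin and is solved in closed form. For `M4` the two systems are
#' relabelled after fitting so that `Km_HA < Km_LA`.
#'
#' Starting values follow the assay geometry: `Km` candidates from
#' `{min S, median S, max S, 3 max S}` (for `M4`, every ordered pair),
#' `Vmax` candidates from `{max V, 2 max V}`, and first-order coefficients
#' from the OLS slope through the origin. All parameters are bounded below
#' by 0 and unbounded above; half-saturation constants that wander far
#' beyond the assayed ladder are reported with extrapolation flags (see
#' [kinetic_parameters()]) rather than constrained away.
#'
#' @param curve A [response_curve()] or data frame with columns `S`, `V`.
#' @param model_id Model identifier (see [model_spec()]).
#' @param starts Optional integer: total number of starts. `NULL` (default)
#'   uses the full deterministic pool; a larger value appends starts jittered
#'   by a seeded +/-20% factor; a smaller value truncates the pool.
#' @param seed Integer seed controlling the jitter (the fit is deterministic
#'   given `curve`, `model_id`, `starts`, `seed`).
#' @return Object of class `kinetic_fit`: list with `model_id`, `estimates`
#'   (canonical order), `RSS`, `n_points`, `AICc`, `converged`,
#'   `n_starts_tried`.
#' @export
fit_model <- function(curve, model_id, starts = NULL, seed = 1L) {
  spec <- model_spec(model_id)
  pts <- curve_points(curve)
  S <- pts$S; V <- pts$V
  n_levels <- length(unique(S))
  if (n_levels < spec$n_params + 2L) {
    stop(sprintf("%s needs >= %d distinct substrate levels, got %d",
                 spec$model_id, spec$n_params + 2L, n_levels), call. = FALSE)
  }
  n <- length(S)

  if (model_id == "M1") {
    tt <- max(sum(S * V) / sum(S^2), 0) / 1000
    rss <- sum((V - 1000 * tt * S)^2)
    return(new_kinetic_fit("M1", c(Tt = tt), rss, n, TRUE, 1L))
  }

  pool <- c(warm_starts(model_id, curve, S, V), start_pool(model_id, S, V))
  if (!is.null(starts)) {
    starts <- as.integer(starts)
    if (starts < 1L) stop("'starts' must be >= 1", call. = FALSE)
    if (starts <= length(pool)) {
      pool <- pool[seq_len(starts)]
    } else {
      extra <- withr::with_seed(seed, {
        lapply(seq_len(starts - length(pool)), function(i) {
          base <- pool[[((i - 1L) %% length(pool)) + 1L]]
          base * runif(length(base), 0.8, 1.2)
        })
      })
      pool <- c(pool, extra)
    }
  }

  best <- NULL
  any_ok <- FALSE
  for (p0 in pool) {
    r <- lm_run(model_id, p0, S, V)
    if (is.null(r)) next
    any_ok <- any_ok || r$ok
    if (r$ok && (is.null(best) || r$RSS < best$RSS)) best <- r
  }
  if (is.null(best)) {
    return(new_kinetic_fit(model_id,
                           setNames(rep(NA_real_, spec$n_params),
                                    spec$parameter_names),
                           NA_real_, n, FALSE, length(pool)))
  }
  est <- model_params(model_id, best$par) # canonical order + M4 relabel
  new_kinetic_fit(model_id, est, best$RSS, n, TRUE, length(pool))
}

new_kinetic_fit <- function(model_id, estimates, RSS, n_points, converged,
                            n_starts) {
  k <- model_spec(model_id)$n_params
  aic <- if (converged && n_points > k + 2L) aicc(RSS, n_points, k) else NA_real_
  structure(
    list(model_id = model_id, estimates = estimates, RSS = RSS,
         n_points = n_points, AICc = aic, converged = converged,
         n_starts_tried = n_starts),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s  RSS = %.4g  AICc = %.4g  converged = %s\n",
              x$model_id, x$RSS, x$AICc, x$converged))
  print(x$estimates)
  invisible(x)
}

#' Select the best kinetic model by AICc
#'
#' A more complex model is accepted only when it lowers the AICc. Ties
#' (|dAICc| < 1e-9) resolve to the model with fewer parameters.
#'
#' @param fits List of [fit_model()] results for one response curve.
#' @return The winning `kinetic_fit`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "kinetic_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$AICc),
               logical(1L))
  fits <- fits[ok]
  if (length(fits) == 0L) stop("no converged, AICc-eligible fits", call. = FALSE)
  aic <- vapply(fits, `[[`, numeric(1L), "AICc")
  np <- vapply(fits, function(f) model_spec(f$model_id)$n_params, integer(1L))
  tied <- aic < min(aic) + 1e-9
  fits[tied][[which.min(np[tied])]]
}

#' Cell-specific maximum hydrolysis rate
#'
#' Divides a bulk `Vmax` by the bacterial abundance of the sample.
#' 1 nM h^-1 spread over 1e9 cells L^-1 is 1 amol cell^-1 h^-1, hence
#' `sp_Vmax = Vmax * 1e9 / abundance`.
#'
#' @param Vmax Bulk maximum hydrolysis rate (nM h^-1).
#' @param abundance Bacterial abundance (cells L^-1), > 0.
#' @return Cell-specific Vmax (amol cell^-1 h^-1).
#' @examples
#' specific_vmax(100, 1e9) # 100
#' @export
specific_vmax <- function(Vmax, abundance) {
  if (any(!is.finite(abundance)) || any(abundance <= 0)) {
    stop("'abundance' must be > 0", call. = FALSE)
  }
  Vmax * 1e9 / abundance
}

#' Paired comparison of high- vs low-affinity parameters
#'
#' Wilcoxon signed-rank test for paired samples across the campaign, used to
#' ask whether the low-affinity system's parameters differ systematically
#' from the high-affinity system's. Zero differences are dropped; the exact
#' permutation distribution is used for up to 30 informative pairs and the
#' normal approximation above that.
#'
#' @param ha,la Numeric vectors of paired parameter values (same sample
#'   order).
#' @return List with `W` (signed-rank statistic of the HA - LA differences),
#'   `p_value` (two-sided) and `n` (informative pairs).
#' @export
compare_ha_la <- function(ha, la) {
  if (length(ha) != length(la)) stop("paired vectors differ in length", call. = FALSE)
  keep <- is.finite(ha) & is.finite(la) & (ha != la)
  if (sum(is.finite(ha) & is.finite(la) & (ha == la)) == length(ha)) {
    stop("all paired differences are zero", call. = FALSE)
  }
  ha <- ha[keep]; la <- la[keep]
  n <- length(ha)
  if (n < 5L) stop("need >= 5 informative pairs", call. = FALSE)
  wt <- wilcox.test(ha, la, paired = TRUE, exact = n <= 30L, correct = TRUE)
  list(W = unname(wt$statistic), p_value = wt$p.value, n = n)
}

#' Extract the selected model's kinetic parameter set
#'
#' Maps a selected fit onto the high-affinity / low-affinity summary used in
#' the output tables: `M4` fills both systems; `M3` fills the HA system plus
#' the LA first-order coefficient `Tt_LA`; `M2` reports its single
#' saturating system under the HA columns; `M1` reports only `Tt_LA`. When
#' the sample's bacterial abundance is known, cell-specific Vmax values are
#' added. Any `Km` above the highest assayed substrate concentration is
#' flagged as an extrapolation (reported, never censored).
#'
#' @param fit A [fit_model()] result (normally from [select_model()]).
#' @param curve The fitted [response_curve()] (supplies identifiers,
#'   abundance, and the assayed range).
#' @return One-row tibble with columns `sample_id`, `enzyme`,
#'   `selected_model`, `Vmax_HA_nM_h`, `Km_HA_uM`, `sp_Vmax_HA_amol_cell_h`,
#'   `Vmax_LA_nM_h`, `Km_LA_uM`, `sp_Vmax_LA_amol_cell_h`, `Tt_LA_per_h`,
#'   `Km_HA_extrapolated`, `Km_LA_extrapolated`.
#' @export
kinetic_parameters <- function(fit, curve) {
  stopifnot(inherits(fit, "kinetic_fit"))
  pts <- curve_points(curve)
  smax <- max(pts$S)
  ab <- if (inherits(curve, "response_curve")) curve$bacterial_abundance else NA_real_
  e <- as.list(fit$estimates)
  out <- list(
    sample_id = if (inherits(curve, "response_curve")) curve$sample_id else NA,
    enzyme = if (inherits(curve, "response_curve")) curve$enzyme else NA,
    selected_model = fit$model_id,
    Vmax_HA_nM_h = NA_real_, Km_HA_uM = NA_real_,
    sp_Vmax_HA_amol_cell_h = NA_real_,
    Vmax_LA_nM_h = NA_real_, Km_LA_uM = NA_real_,
    sp_Vmax_LA_amol_cell_h = NA_real_,
    Tt_LA_per_h = NA_real_
  )
  if (fit$model_id == "M1") {
    out$Tt_LA_per_h <- e$Tt
  } else if (fit$model_id == "M2") {
    out$Vmax_HA_nM_h <- e$Vmax
    out$Km_HA_uM <- e$Km
  } else if (fit$model_id == "M3") {
    out$Vmax_HA_nM_h <- e$Vmax_HA
    out$Km_HA_uM <- e$Km_HA
    out$Tt_LA_per_h <- e$Tt_LA
  } else {
    out$Vmax_HA_nM_h <- e$Vmax_HA
    out$Km_HA_uM <- e$Km_HA
    out$Vmax_LA_nM_h <- e$Vmax_LA
    out$Km_LA_uM <- e$Km_LA
  }
  if (is.finite(ab) && ab > 0) {
    if (is.finite(out$Vmax_HA_nM_h)) {
      out$sp_Vmax_HA_amol_cell_h <- specific_vmax(out$Vmax_HA_nM_h, ab)
    }
    if (is.finite(out$Vmax_LA_nM_h)) {
      out$sp_Vmax_LA_amol_cell_h <- specific_vmax(out$Vmax_LA_nM_h, ab)
    }
  }
  out$Km_HA_extrapolated <- is.finite(out$Km_HA_uM) && out$Km_HA_uM > smax
  out$Km_LA_extrapolated <- is.finite(out$Km_LA_uM) && out$Km_LA_uM > smax
  tibble::as_tibble(out)
}
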