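#' Build a serial half-dilution substrate ladder
#'
#' The assay design uses 12 final substrate concentrations obtained by serial
#' half-dilution from a top concentration (defaults: 400 uM for leucine
#' aminopeptidase, 300 uM for the glucosidases), with 4 replicate wells per
#' concentration.
#'
#' @param enzyme One of `"LAP"` (leucine aminopeptidase), `"BG"`
#'   (beta-glucosidase), `"AG"` (alpha-glucosidase).
#' @param top_concentration Highest final concentration (uM). Defaults to
#'   400 for LAP and 300 for the glucosidases.
#' @param n_levels Number of ladder levels (default 12).
#' @param n_replicates Replicate wells per level (default 4).
#' @return An object of class `substrate_ladder`: a list with `enzyme`,
#'   `concentrations` (strictly decreasing, each half the previous) and
#'   `n_replicates`.
#' @examples
#' build_ladder("LAP")$concentrations
#' @export
build_ladder <- function(enzyme = c("LAP", "BG", "AG"),
                         top_concentration = NULL,
                         n_levels = 12L, n_replicates = 4L) {
  enzyme <- match.arg(enzyme)
  if (is.null(top_concentration)) {
    top_concentration <- if (enzyme == "LAP") 400 else 300
  }
  if (!is.numeric(top_concentration) || top_concentration <= 0) {
    stop("'top_concentration' must be > 0", call. = FALSE)
  }
  n_levels <- as.integer(n_levels)
  n_replicates <- as.integer(n_replicates)
  if (n_levels < 2L) stop("'n_levels' must be >= 2", call. = FALSE)
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1", call. = FALSE)
  structure(
    list(enzyme = enzyme,
         concentrations = top_concentration / 2^(seq_len(n_levels) - 1),
         n_replicates = n_replicates),
    class = "substrate_ladder"
  )
}

#' Fit a fluorophore standard curve
#'
#' Ordinary least-squares line relating fluorescence to standard
#' concentration, used to convert plate fluorescence into end-product
#' concentration. Standards are MCA (7-amino-4-methylcoumarin, working range
#' 0-1000 nM) for peptidase substrates and MUF (4-methylumbelliferone,
#' 0-500 nM) for glucosidase substrates.
#'
#' @param standards Data frame (or list coercible to one) with columns
#'   `conc_nM` and `fluorescence`.
#' @param standard Fluorophore label, `"MUF"` or `"MCA"` (metadata only).
#' @param min_r2 Minimum r-squared accepted (default 0.98).
#' @return Object of class `standard_curve`: list with `standard`, `slope`
#'   (fluorescence units per nM), `intercept`, `r2`, `n`.
#' @export
fit_standard_curve <- function(standards, standard = c("MUF", "MCA"),
                               min_r2 = 0.98) {
  standard <- match.arg(standard)
  standards <- as.data.frame(standards)
  if (!all(c("conc_nM", "fluorescence") %in% names(standards))) {
    stop("'standards' needs columns conc_nM and fluorescence", call. = FALSE)
  }
  conc <- standards$conc_nM
  fl <- standards$fluorescence
  if (length(unique(conc)) < 3L) {
    stop("need >= 3 distinct standard concentrations", call. = FALSE)
  }
  fit <- lm(fl ~ conc)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop("standard curve slope <= 0: failed standard series", call. = FALSE)
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((fl - mean(fl))^2)
  if (r2 < min_r2) {
    warning(sprintf("standard curve r2 = %.4f below %.2f", r2, min_r2),
            call. = FALSE)
  }
  structure(
    list(standard = standard, slope = slope,
         intercept = unname(coef(fit)[1L]), r2 = r2, n = length(conc)),
    class = "standard_curve"
  )
}

#' Assemble a plate-reader timecourse
#'
#' Container for the raw fluorescence kinetics of one sample x enzyme plate:
#' substrate wells read repeatedly over the incubation, plus blank wells
#' (sample + Milli-Q water instead of substrate) tracking background
#' fluorescence.
#'
#' @param sample_id Sample identifier.
#' @param enzyme Enzyme label (`"LAP"`, `"BG"`, `"AG"`).
#' @param wells Data frame with columns `well`, `substrate_conc_uM`,
#'   `time_h`, `fluorescence`.
#' @param blanks Data frame with columns `time_h`, `fluorescence` (and
#'   optionally `well`).
#' @return Object of class `plate_timecourse`.
#' @export
plate_timecourse <- function(sample_id, enzyme, wells, blanks) {
  wells <- as.data.frame(wells)
  blanks <- as.data.frame(blanks)
  need <- c("well", "substrate_conc_uM", "time_h", "fluorescence")
  if (!all(need %in% names(wells))) {
    stop("'wells' needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(c("time_h", "fluorescence") %in% names(blanks)) || nrow(blanks) < 2L) {
    stop("'blanks' must provide >= 2 timed readings", call. = FALSE)
  }
  if (any(wells$time_h < 0)) stop("times must be nonnegative", call. = FALSE)
  tp <- tapply(wells$time_h, wells$well, function(t) length(unique(t)))
  if (any(tp < 2L)) stop("every well needs >= 2 timepoints", call. = FALSE)
  structure(
    list(sample_id = sample_id, enzyme = enzyme, wells = wells,
         blanks = blanks),
    class = "plate_timecourse"
  )
}

#' Hydrolysis-rate response curve
#'
#' One sample x enzyme set of (substrate concentration, rate) points with
#' replicate structure preserved. Rates may be slightly negative through
#' measurement noise; such points are kept and flagged, never clipped.
#'
#' @param sample_id,enzyme Identifiers.
#' @param S Substrate concentrations (uM), replicated per level.
#' @param V Hydrolysis rates (nM h^-1), same length as `S`.
#' @param replicate Optional replicate index per point.
#' @param date Optional sampling date.
#' @param temperature Optional in situ temperature (deg C).
#' @param bacterial_abundance Optional bacterial abundance (cells L^-1),
#'   required later for cell-specific Vmax.
#' @return Object of class `response_curve`; `$points` is a tibble with
#'   columns `S`, `V`, `replicate`, `negative_rate`.
#' @export
response_curve <- function(sample_id, enzyme, S, V, replicate = NULL,
                           date = NA, temperature = NA_real_,
                           bacterial_abundance = NA_real_) {
  if (length(S) != length(V)) stop("S and V lengths differ", call. = FALSE)
  if (any(!is.finite(S)) || any(S < 0)) {
    stop("substrate concentrations must be finite and >= 0", call. = FALSE)
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(S), S, FUN = seq_along)
  }
  structure(
    list(sample_id = sample_id, enzyme = enzyme, date = date,
         temperature = temperature,
         bacterial_abundance = bacterial_abundance,
         points = tibble::tibble(S = as.numeric(S), V = as.numeric(V),
                                 replicate = as.integer(replicate),
                                 negative_rate = V < 0)),
    class = "response_curve"
  )
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> %s / %s: %d points, %d substrate levels\n",
              x$sample_id, x$enzyme, nrow(x$points),
              length(unique(x$points$S))))
  invisible(x)
}

## replicate-level fitting points; S = 0 wells are excluded (V(0) = 0 is
## structural in every model, blanks handle background)
curve_points <- function(curve) {
  if (inherits(curve, "response_curve")) {
    pts <- curve$points
  } else {
    pts <- as.data.frame(curve)
    if (!all(c("S", "V") %in% names(pts))) {
      stop("curve needs columns S and V", call. = FALSE)
    }
  }
  pts[pts$S > 0, , drop = FALSE]
}

#' Compute hydrolysis rates from a plate timecourse
#'
#' Per substrate well: the time-matched mean blank fluorescence is
#' subtracted, residual fluorescence is converted to end-product
#' concentration through the standard curve (`(F - intercept) / slope`), and
#' the rate is the OLS slope of product concentration against time
#' (nM h^-1). With exactly two timepoints this reduces to the increase in
#' product concentration divided by the incubation time. Blank fluorescence
#' at sample reading times is linearly interpolated between blank readings.
#'
#' @param tc A [plate_timecourse()].
#' @param std A [fit_standard_curve()] result.
#' @param incubation_window Length-2 numeric, hours; readings outside are
#'   dropped (default `c(0, 6)`, matching 3-6 h incubations read from t = 0).
#' @param negative_tolerance Warn when product concentrations fall below
#'   minus this value (nM, default 5).
#' @inheritParams response_curve
#' @return A [response_curve()].
#' @export
compute_rates <- function(tc, std, incubation_window = c(0, 6),
                          negative_tolerance = 5,
                          date = NA, temperature = NA_real_,
                          bacterial_abundance = NA_real_) {
  stopifnot(inherits(tc, "plate_timecourse"), inherits(std, "standard_curve"))
  w <- tc$wells
  keep <- w$time_h >= incubation_window[1L] & w$time_h <= incubation_window[2L]
  w <- w[keep, , drop = FALSE]
  if (nrow(w) == 0L) stop("no readings inside the incubation window", call. = FALSE)

  bl <- stats::aggregate(fluorescence ~ time_h, data = tc$blanks, FUN = mean)
  blank_at <- function(t) {
    if (nrow(bl) == 1L) return(rep(bl$fluorescence, length(t)))
    approx(bl$time_h, bl$fluorescence, xout = t, rule = 2)$y
  }

  rows <- lapply(split(w, w$well), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    if (length(unique(d$time_h)) < 2L) {
      warning("well with < 2 usable timepoints dropped", call. = FALSE)
      return(NULL)
    }
    resid_fl <- d$fluorescence - blank_at(d$time_h)
    prod_nM <- (resid_fl - std$intercept) / std$slope
    if (any(prod_nM < -negative_tolerance)) {
      warning(sprintf("well %s: product concentration below -%g nM",
                      d$well[1L], negative_tolerance), call. = FALSE)
    }
    v <- if (nrow(d) == 2L) {
      diff(prod_nM) / diff(d$time_h)
    } else {
      unname(coef(lm(prod_nM ~ d$time_h))[2L])
    }
    data.frame(S = d$substrate_conc_uM[1L], V = v)
  })
  rows <- do.call(rbind, rows)
  rows <- rows[order(-rows$S), , drop = FALSE]
  response_curve(tc$sample_id, tc$enzyme, S = rows$S, V = rows$V,
                 date = date, temperature = temperature,
                 bacterial_abundance = bacterial_abundance)
}

#' Read / write response-curve CSV files
#'
#' Long-format CSV with columns `sample_id`, `enzyme`, `date`,
#' `temperature_C`, `substrate_uM`, `rate_nM_per_h`, `replicate` and
#' optionally `bacterial_abundance`.
#'
#' @param path File path.
#' @return `read_response_curves()`: a named list of [response_curve()]
#'   objects (one per sample x enzyme). `write_response_curves()`: `path`,
#'   invisibly.
#' @export
read_response_curves <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "enzyme", "substrate_uM", "rate_nM_per_h")
  if (!all(need %in% names(d))) {
    stop("CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  key <- paste(d$sample_id, d$enzyme, sep = ".")
  out <- lapply(split(d, key), function(g) {
    response_curve(
      g$sample_id[1L], g$enzyme[1L],
      S = g$substrate_uM, V = g$rate_nM_per_h,
      replicate = if ("replicate" %in% names(g)) g$replicate else NULL,
      date = if ("date" %in% names(g)) g$date[1L] else NA,
      temperature = if ("temperature_C" %in% names(g)) g$temperature_C[1L] else NA_real_,
      bacterial_abundance = if ("bacterial_abundance" %in% names(g))
        g$bacterial_abundance[1L] else NA_real_
    )
  })
  out
}

#' @param curves List of [response_curve()] objects.
#' @rdname read_response_curves
#' @export
write_response_curves <- function(curves, path) {
  if (inherits(curves, "response_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    data.frame(sample_id = cv$sample_id, enzyme = cv$enzyme,
               date = as.character(cv$date), temperature_C = cv$temperature,
               substrate_uM = cv$points$S, rate_nM_per_h = cv$points$V,
               replicate = cv$points$replicate,
               bacterial_abundance = cv$bacterial_abundance)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
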