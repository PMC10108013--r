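#' Kinetic model catalogue
#'
#' Four nested models describe the substrate dependence of extracellular
#' hydrolysis rates, in increasing order of complexity:
#'
#' * `M1` — a single non-saturating system with first-order kinetics,
#'   `V = Tt * S`. `Tt` (h^-1) is the first-order rate coefficient,
#'   equivalent to the ratio Vmax/Km of a system assayed far below
#'   saturation.
#' * `M2` — a single system following classical Michaelis–Menten kinetics,
#'   `V = Vmax * S / (Km + S)`.
#' * `M3` — two independent isoenzyme groups: a high-affinity (HA) system
#'   that saturates within the assayed range (Michaelis–Menten) plus a
#'   low-affinity (LA) system that does not (first-order),
#'   `V = Vmax_HA * S / (Km_HA + S) + Tt_LA * S`.
#' * `M4` — two independent isoenzyme groups both approaching saturation,
#'   `V = Vmax_HA * S / (Km_HA + S) + Vmax_LA * S / (Km_LA + S)`.
#'
#' Units are fixed throughout the package: substrate concentration `S` in
#' uM, rates `V` and `Vmax` in nM h^-1, `Km` in uM, and `Tt` in h^-1.
#' Because `S` is carried in uM while `V` is carried in nM h^-1, the
#' first-order terms include an explicit factor of 1000 (1 uM = 1000 nM) so
#' that `Tt` keeps its natural units of h^-1.
#'
#' @param model_id One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @return A list with `model_id`, `parameter_names` (ordered) and
#'   `n_params`.
#' @examples
#' model_spec("M4")$parameter_names
#' @export
model_spec <- function(model_id) {
  model_id <- match.arg(model_id, c("M1", "M2", "M3", "M4"))
  pars <- switch(model_id,
    M1 = "Tt",
    M2 = c("Vmax", "Km"),
    M3 = c("Vmax_HA", "Km_HA", "Tt_LA"),
    M4 = c("Vmax_HA", "Km_HA", "Vmax_LA", "Km_LA")
  )
  list(model_id = model_id, parameter_names = pars, n_params = length(pars))
}

#' Construct and validate a kinetic parameter vector
#'
#' Checks that `values` carries exactly the parameters of `model_id`, that
#' all values are nonnegative and finite, and — for `M4` — relabels the two
#' systems so that `Km_HA < Km_LA` (the high-affinity system is, by
#' definition, the one with the lower half-saturation constant; relabelling
#' removes label switching between otherwise symmetric parameterizations).
#'
#' @param model_id Model identifier (see [model_spec()]).
#' @param values Named numeric vector of parameter values (any order).
#' @return A named numeric vector in canonical parameter order.
#' @examples
#' model_params("M4", c(Km_HA = 300, Vmax_HA = 500, Km_LA = 2, Vmax_LA = 50))
#' @export
model_params <- function(model_id, values) {
  spec <- model_spec(model_id)
  if (is.list(values)) values <- unlist(values)
  if (is.null(names(values)) || !setequal(names(values), spec$parameter_names) ||
      length(values) != spec$n_params) {
    stop("'values' must be named exactly: ",
         paste(spec$parameter_names, collapse = ", "), call. = FALSE)
  }
  values <- values[spec$parameter_names]
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("all kinetic parameters must be finite and >= 0", call. = FALSE)
  }
  if (spec$model_id == "M4" && values[["Km_HA"]] > values[["Km_LA"]]) {
    values <- c(Vmax_HA = values[["Vmax_LA"]], Km_HA = values[["Km_LA"]],
                Vmax_LA = values[["Vmax_HA"]], Km_LA = values[["Km_HA"]])
  }
  values
}

## unchecked evaluation used inside optimizer loops (par in canonical order)
eval_model_raw <- function(model_id, par, S) {
  switch(model_id,
    M1 = 1000 * par[[1L]] * S,
    M2 = par[[1L]] * S / (par[[2L]] + S),
    M3 = par[[1L]] * S / (par[[2L]] + S) + 1000 * par[[3L]] * S,
    M4 = par[[1L]] * S / (par[[2L]] + S) + par[[3L]] * S / (par[[4L]] + S)
  )
}

#' Evaluate a kinetic model
#'
#' Returns the hydrolysis rate predicted by one of the four kinetic models
#' at substrate concentrations `S`. See [model_spec()] for the equations and
#' the unit conventions (notably the factor 1000 that keeps `Tt` in h^-1
#' while `S` is in uM and `V` in nM h^-1).
#'
#' @param model_id Model identifier.
#' @param params Named numeric vector of parameters for `model_id`.
#' @param S Numeric vector of substrate concentrations (uM), all >= 0.
#' @return Numeric vector of rates (nM h^-1), same length as `S`.
#' @examples
#' eval_model("M2", c(Vmax = 100, Km = 10), S = 10) # half-saturation: 50
#' @export
eval_model <- function(model_id, params, S) {
  params <- model_params(model_id, params)
  if (!is.numeric(S) || any(!is.finite(S)) || any(S < 0)) {
    stop("'S' must be finite and >= 0", call. = FALSE)
  }
  eval_model_raw(model_id, params, S)
}
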