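# Cell-model registry: uniform access to the built-in ventricular myocyte
# models.  Each model exposes an ordered state vector, an ordered set of
# scalable parameters (maximal conductances / transport rates), published
# baseline values, and default initial conditions.

.model_table <- function() {
  list(
    lr1 = list(
      code = 1L,
      label = "Luo-Rudy 1991 (phase 1) guinea-pig ventricular model",
      state_names = c("V", "m", "h", "j", "d", "f", "X", "Cai"),
      # conductances in mS/cm^2 (currents in uA/cm^2 == pA/pF at Cm = 1 uF/cm^2)
      parameter_names = c("G_Na", "G_si", "G_K", "G_K1", "G_Kp", "G_b"),
      baseline = c(G_Na = 23, G_si = 0.09, G_K = 0.282, G_K1 = 0.6047,
                   G_Kp = 0.0183, G_b = 0.03921),
      Ko = 5.4,
      cai_state = "Cai",
      initial_state = c(V = -84.38, m = 0.0017, h = 0.983, j = 0.989,
                        d = 0.003, f = 0.999, X = 0.0057, Cai = 1.78e-4)
    ),
    tnnp = list(
      code = 2L,
      label = "ten Tusscher-Noble-Noble-Panfilov 2004 human ventricular model (epicardial)",
      state_names = c("V", "m", "h", "j", "d", "f", "fCa", "r", "s",
                      "xr1", "xr2", "xs", "g", "Cai", "CaSR", "Nai", "Ki"),
      # conductances in nS/pF; transport rates in source-model units
      parameter_names = c("G_Na", "G_CaL", "G_to", "G_Kr", "G_Ks", "G_K1",
                          "G_pK", "G_bNa", "G_bCa", "K_pCa", "K_NaK", "K_NCX",
                          "K_up", "K_leak", "K_rel1", "K_rel2"),
      baseline = c(G_Na = 14.838, G_CaL = 1.75e-4, G_to = 0.294, G_Kr = 0.096,
                   G_Ks = 0.245, G_K1 = 5.405, G_pK = 0.0146, G_bNa = 2.9e-4,
                   G_bCa = 5.92e-4, K_pCa = 0.825, K_NaK = 1.362, K_NCX = 1000,
                   K_up = 4.25e-4, K_leak = 8e-5, K_rel1 = 0.016464,
                   K_rel2 = 0.008232),
      Ko = 5.4,
      cai_state = "Cai",
      initial_state = c(V = -86.2, m = 0, h = 0.75, j = 0.75, d = 0, f = 1,
                        fCa = 1, r = 0, s = 1, xr1 = 0, xr2 = 1, xs = 0, g = 1,
                        Cai = 2e-4, CaSR = 0.2, Nai = 11.6, Ki = 138.3)
    ),
    bernus = list(
      code = 3L,
      label = "Bernus-type six-variable reduced human ventricular model",
      state_names = c("V", "m", "v", "f", "to", "X"),
      parameter_names = c("G_Na", "G_Ca", "G_to", "G_K", "G_K1", "K_NaK",
                          "K_NCX", "G_bNa"),
      baseline = c(G_Na = 12, G_Ca = 0.08, G_to = 0.35, G_K = 0.035,
                   G_K1 = 1.0, K_NaK = 1.3, K_NCX = 1000, G_bNa = 3e-4),
      Ko = 5.4,
      cai_state = NA_character_,
      initial_state = c(V = -86.2, m = 5e-4, v = 1, f = 1, to = 1, X = 0)
    )
  )
}

.resolve_model <- function(model_id) {
  tab <- .model_table()
  if (!is.character(model_id) || length(model_id) != 1L ||
      !(tolower(model_id) %in% names(tab))) {
    stop("unknown model_id ", deparse(model_id), "; available models: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  tab[[tolower(model_id)]]
}

#' List the built-in cell models
#'
#' @return A tibble with one row per registered model: its id, a descriptive
#'   label, the number of state variables, and the number of scalable
#'   parameters.
#' @export
#' @examples
#' list_models()
list_models <- function() {
  tab <- .model_table()
  tibble::tibble(
    model_id = names(tab),
    label = purrr::map_chr(tab, "label"),
    n_states = purrr::map_int(tab, ~ length(.x$state_names)),
    n_parameters = purrr::map_int(tab, ~ length(.x$parameter_names))
  )
}

#' Structural description of a cell model
#'
#' Returns the ordered state-variable labels, the ordered scalable-parameter
#' labels with their published baseline values, the default extracellular
#' potassium concentration, and the default initial conditions.
#'
#' @param model_id One of `"lr1"`, `"tnnp"`, `"bernus"`.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(model_id) {
  m <- .resolve_model(model_id)
  structure(
    list(model_id = tolower(model_id), label = m$label,
         state_names = m$state_names, parameter_names = m$parameter_names,
         baseline_values = m$baseline, Ko = m$Ko, cai_state = m$cai_state,
         initial_state = m$initial_state),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$model_id, ": ", x$label, "\n", sep = "")
  cat("  states (", length(x$state_names), "): ",
      paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("  parameters (", length(x$parameter_names), "): ",
      paste(x$parameter_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Baseline parameter set of a cell model
#'
#' @inheritParams model_spec
#' @return A tibble of class `parameter_set` with columns `parameter`,
#'   `baseline`, `scale_factor`, and `value` (`value = baseline *
#'   scale_factor`); all scale factors are 1.
#' @export
#' @examples
#' baseline_parameters("lr1")
baseline_parameters <- function(model_id) {
  m <- .resolve_model(model_id)
  out <- tibble::tibble(
    parameter = m$parameter_names,
    baseline = unname(m$baseline[m$parameter_names]),
    scale_factor = 1,
    value = unname(m$baseline[m$parameter_names])
  )
  attr(out, "model_id") <- tolower(model_id)
  class(out) <- c("parameter_set", class(out))
  out
}

#' Scale a parameter set by multiplicative factors
#'
#' @param base A `parameter_set` (see [baseline_parameters()]).
#' @param factors Positive multiplicative factors, one per parameter, either
#'   unnamed in parameter order or named by parameter.
#' @return A new `parameter_set` with `value = baseline * factor`.
#' @export
#' @examples
#' scale_parameters(baseline_parameters("lr1"), rep(1.2, 6))
scale_parameters <- function(base, factors) {
  stopifnot(inherits(base, "parameter_set"))
  p <- nrow(base)
  if (length(factors) != p) {
    stop("expected ", p, " factors, got ", length(factors), call. = FALSE)
  }
  if (!is.null(names(factors))) {
    if (!setequal(names(factors), base$parameter)) {
      stop("factor names do not match the model's parameters", call. = FALSE)
    }
    factors <- factors[base$parameter]
  }
  bad <- which(!is.finite(factors) | factors <= 0)
  if (length(bad) > 0) {
    stop("non-positive or non-finite scale factor for parameter ",
         paste(base$parameter[bad], collapse = ", "), call. = FALSE)
  }
  out <- base
  out$scale_factor <- unname(factors)
  out$value <- out$baseline * out$scale_factor
  out
}

# named numeric vector of parameter values in model order (internal)
.param_values <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  setNames(params$value, params$parameter)
}

#' Evaluate the model's state derivatives
#'
#' Computes d(state)/dt for the given state, parameters, stimulus current and
#' extracellular potassium.  The voltage derivative is the negated sum of all
#' membrane currents plus the (depolarizing) stimulus.
#'
#' @inheritParams model_spec
#' @param state Named or ordered numeric state vector (see [model_spec()]).
#' @param params A `parameter_set` for the same model.
#' @param stim Stimulus current in pA/pF (depolarizing positive). Default 0.
#' @param Ko Extracellular potassium in mM; defaults to the model's normal
#'   value (5.4 mM).
#' @return Named numeric vector of state derivatives (per ms).
#' @export
evaluate_derivatives <- function(model_id, state, params, stim = 0, Ko = NULL) {
  m <- .resolve_model(model_id)
  pid <- attr(params, "model_id")
  if (!identical(pid, tolower(model_id))) {
    stop("parameter set is for model ", deparse(pid), ", not ", model_id,
         call. = FALSE)
  }
  if (length(state) != length(m$state_names)) {
    stop("state length ", length(state), " does not match model (expected ",
         length(m$state_names), ")", call. = FALSE)
  }
  if (!is.null(names(state))) state <- state[m$state_names]
  if (any(!is.finite(state))) {
    stop("non-finite entries in state vector", call. = FALSE)
  }
  if (is.null(Ko)) Ko <- m$Ko
  dy <- cm_derivs_cpp(m$code, as.numeric(state), unname(.param_values(params)),
                      stim, Ko)
  setNames(as.numeric(dy), m$state_names)
}

#' Default initial conditions of a model
#'
#' @inheritParams model_spec
#' @return Named numeric state vector.
#' @export
model_initial_state <- function(model_id) {
  .resolve_model(model_id)$initial_state
}
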