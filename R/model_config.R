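# model_config: declarative population-PK models --------------------------
#
# A popPK model is fully described by: the structural disposition model
# (1 or 2 compartments, linear elimination, IV infusion input), typical
# parameter values, covariate effects on those parameters, log-normal
# inter-individual variability (eta), optional inter-occasion variability on
# clearance (kappa, one occasion per dosing interval) and a combined
# proportional + additive residual error.

STRUCT_PARS <- c("CL", "Vc", "Q", "Vp")
COV_FORMS <- c("power", "proportional", "exponential", "binary_multiplier",
               "piecewise_time_multiplier")

#' Construct and validate a population-PK model definition
#'
#' @param name Model name.
#' @param n_compartments 1 or 2.
#' @param typical Named list of typical values: `CL` (L/day), `Vc` (L) and,
#'   for two-compartment models, `Q` (L/day) and `Vp` (L).
#' @param covariate_effects List of effects, each a list with `target`
#'   (`CL`, `Vc`, `Q` or `Vp`), `covariate` (column name; for
#'   `piecewise_time_multiplier` a time switch, see below), `form` and
#'   `coefficient`, plus `reference` where the form requires one. Forms
#'   (all multiplicative on the target parameter):
#'   * `power`: `(value/reference)^coefficient` (e.g. allometric scaling);
#'   * `proportional`: `1 + coefficient * (value - reference)`;
#'   * `exponential`: `exp(coefficient * (value - reference))`;
#'   * `binary_multiplier`: `coefficient` while the covariate is true/1,
#'     otherwise 1 (e.g. ADA positivity);
#'   * `piecewise_time_multiplier`: `coefficient` from time `reference`
#'     (hours) onward, otherwise 1 (time-varying clearance components).
#' @param iiv_omega Covariance matrix (or named vector of variances) of the
#'   log-scale inter-individual random effects, dimnames naming structural
#'   parameters.
#' @param iov_pi Variance of the log-scale inter-occasion effect on `CL`,
#'   or `NULL` for no IOV.
#' @param sigma_prop Proportional residual error SD (dimensionless).
#' @param sigma_add Additive residual error SD (ug/mL).
#' @param required_covariates Covariate columns the model needs beyond those
#'   named by effects (rarely used).
#' @return A validated `poppk_model` object.
#' @export
poppk_model <- function(name, n_compartments, typical,
                        covariate_effects = list(),
                        iiv_omega = NULL, iov_pi = NULL,
                        sigma_prop = 0, sigma_add = 0,
                        required_covariates = character(0)) {
  stopifnot(n_compartments %in% c(1L, 2L))
  n_compartments <- as.integer(n_compartments)
  need <- if (n_compartments == 2) STRUCT_PARS else c("CL", "Vc")
  typical <- lapply(typical, as.numeric)
  miss <- setdiff(need, names(typical))
  if (length(miss)) stop("typical values missing for: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(typical), need)
  if (length(extra)) stop("typical values declared for parameters not in a ",
                          n_compartments, "-compartment model: ",
                          paste(extra, collapse = ", "), call. = FALSE)
  vals <- unlist(typical[need])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("typical parameter values must be strictly positive", call. = FALSE)
  }
  for (eff in covariate_effects) {
    stopifnot(is.list(eff))
    if (!all(c("target", "covariate", "form", "coefficient") %in% names(eff))) {
      stop("covariate effect needs fields target/covariate/form/coefficient",
           call. = FALSE)
    }
    if (!eff$target %in% need) {
      stop("covariate effect targets '", eff$target,
           "', absent from this model", call. = FALSE)
    }
    if (!eff$form %in% COV_FORMS) {
      stop("unknown covariate-effect form '", eff$form, "'", call. = FALSE)
    }
    if (eff$form == "power" && (is.null(eff$reference) || eff$reference <= 0)) {
      stop("power covariate effect needs a positive reference", call. = FALSE)
    }
  }
  if (!is.null(iiv_omega)) {
    if (is.null(dim(iiv_omega))) {
      iiv_omega <- diag(unlist(iiv_omega), nrow = length(iiv_omega)) |>
        `dimnames<-`(list(names(unlist(iiv_omega)), names(unlist(iiv_omega))))
    }
    iiv_omega <- as.matrix(iiv_omega)
    if (is.null(rownames(iiv_omega)) ||
        !all(rownames(iiv_omega) %in% need)) {
      stop("iiv_omega dimnames must name structural parameters", call. = FALSE)
    }
    if (!isSymmetric(unname(iiv_omega), tol = 1e-8)) {
      stop("iiv_omega must be symmetric", call. = FALSE)
    }
    if (any(eigen(iiv_omega, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
      stop("iiv_omega must be positive semidefinite", call. = FALSE)
    }
  }
  if (!is.null(iov_pi)) {
    iov_pi <- as.numeric(iov_pi)
    if (!is.finite(iov_pi) || iov_pi < 0) {
      stop("iov_pi must be a non-negative variance", call. = FALSE)
    }
    if (iov_pi == 0) iov_pi <- NULL
  }
  sigma_prop <- as.numeric(sigma_prop); sigma_add <- as.numeric(sigma_add)
  if (sigma_prop < 0 || sigma_add < 0) {
    stop("residual error SDs must be non-negative", call. = FALSE)
  }
  if (sigma_prop == 0 && sigma_add == 0) {
    stop("at least one residual error component must be > 0", call. = FALSE)
  }
  structure(list(
    name = as.character(name),
    n_compartments = n_compartments,
    typical = typical[need],
    covariate_effects = covariate_effects,
    random = list(iiv_omega = iiv_omega, iov_pi = iov_pi,
                  occasion_rule = "dosing_interval"),
    error = list(sigma_prop = sigma_prop, sigma_add = sigma_add)
  ), class = "poppk_model")
}

#' @export
print.poppk_model <- function(x, ...) {
  cat(sprintf("<poppk_model> %s: %d-compartment, %d covariate effect(s), %s IOV\n",
              x$name, x$n_compartments, length(x$covariate_effects),
              if (is.null(x$random$iov_pi)) "no" else "CL"))
  invisible(x)
}

MODEL_SCHEMA_VERSION <- 1L
MODEL_SPEC_KEYS <- c("schema_version", "name", "n_compartments", "typical",
                     "covariate_effects", "iiv_omega", "iov_pi",
                     "sigma_prop", "sigma_add", "required_covariates",
                     "notes", "source", "status")

#' Load a population-PK model from a YAML or JSON file
#'
#' The on-disk schema mirrors the arguments of [poppk_model()], plus a
#' `schema_version` key and optional `notes`/`source`/`status` metadata.
#' `iiv_omega` may be given as a named variance map or a full matrix (list
#' of rows with a `parameters` vector). Files with `status: stub` carry the
#' published model structure but no usable parameter values and can only be
#' loaded with `allow_stub = TRUE`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` model file.
#' @param allow_stub Return unvalidated stub definitions instead of erroring.
#' @return A `poppk_model`, or (for stubs) a `poppk_model_stub` list.
#' @export
load_model_spec <- function(path, allow_stub = FALSE) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(spec), MODEL_SPEC_KEYS)
  if (length(unknown)) {
    stop("unknown key(s) in model file: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (identical(spec$status, "stub")) {
    if (!allow_stub) {
      stop("'", path, "' is a structure-only stub without parameter values; ",
           "load with allow_stub = TRUE", call. = FALSE)
    }
    return(structure(spec, class = "poppk_model_stub"))
  }
  omega <- spec$iiv_omega
  if (!is.null(omega) && is.list(omega) && !is.null(omega$parameters)) {
    pars <- unlist(omega$parameters)
    m <- matrix(unlist(omega$matrix), nrow = length(pars), byrow = TRUE,
                dimnames = list(pars, pars))
    omega <- m
  } else if (!is.null(omega)) {
    omega <- unlist(omega)
  }
  poppk_model(
    name = spec$name %||% basename(path),
    n_compartments = spec$n_compartments,
    typical = spec$typical,
    covariate_effects = spec$covariate_effects %||% list(),
    iiv_omega = omega,
    iov_pi = spec$iov_pi,
    sigma_prop = spec$sigma_prop %||% 0,
    sigma_add = spec$sigma_add %||% 0,
    required_covariates = unlist(spec$required_covariates %||% character(0))
  )
}

#' Serialize a model to the on-disk schema
#'
#' `load_model_spec(serialize_model_spec(m, path))` reproduces `m`.
#'
#' @param model A `poppk_model`.
#' @param path Output path (`.yaml` or `.json`).
#' @export
serialize_model_spec <- function(model, path) {
  stopifnot(inherits(model, "poppk_model"))
  omega <- model$random$iiv_omega
  spec <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    name = model$name,
    n_compartments = model$n_compartments,
    typical = model$typical,
    covariate_effects = model$covariate_effects,
    iiv_omega = if (is.null(omega)) NULL else list(
      parameters = as.list(rownames(omega)),
      matrix = apply(omega, 1, as.list, simplify = FALSE)
    ),
    iov_pi = model$random$iov_pi,
    sigma_prop = model$error$sigma_prop,
    sigma_add = model$error$sigma_add
  )
  spec <- spec[!vapply(spec, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(spec, path)
  }
  invisible(path)
}

model_required_covariates <- function(model) {
  effs <- model$covariate_effects
  covs <- vapply(effs, function(e) e$covariate, character(1))
  forms <- vapply(effs, function(e) e$form, character(1))
  unique(covs[forms != "piecewise_time_multiplier"])
}

#' Check a model's covariate requirements against a dataset
#'
#' Mirrors the eligibility screen used before external evaluation: a model
#' requiring covariates a data set does not carry cannot be evaluated on it.
#'
#' @param model A `poppk_model`.
#' @param data An [event_table()].
#' @return A character vector of findings, one per missing covariate;
#'   `character(0)` means the model and data set are compatible.
#' @export
validate_against_dataset <- function(model, data) {
  stopifnot(inherits(model, "poppk_model"), inherits(data, "event_table"))
  need <- model_required_covariates(model)
  have <- attr(data, "covariates")
  # ADA positivity is derived from the ADA measurement column, not a covariate
  have <- c(have, if (any(!is.na(data$ada))) "ada_positive")
  missing <- setdiff(need, have)
  vapply(missing, function(cv) {
    paste0("model '", model$name, "' requires covariate '", cv,
           "', absent from the data set")
  }, character(1), USE.NAMES = FALSE)
}
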