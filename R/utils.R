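# Internal helpers: classed conditions and the per-variable transform registry.

md_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "micdiv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

md_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "micdiv_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_columns <- function(data, required, name) {
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    md_stop(
      sprintf("`%s` is missing required column(s): %s",
              name, paste(missing, collapse = ", ")),
      "schema_error"
    )
  }
  invisible(data)
}

#' Apply a named transform to a numeric vector
#'
#' Transforms are referred to by label throughout the package so that the
#' per-variable registry can be stored in plain configuration.
#'
#' @param x Numeric vector.
#' @param label One of `"identity"`, `"log"`, `"sqrt"`.
#' @return Transformed numeric vector.
#' @export
apply_transform <- function(x, label = "identity") {
  switch(label,
    identity = x,
    log = {
      if (any(x <= 0, na.rm = TRUE))
        md_stop("log transform requires strictly positive values", "transform_error")
      log(x)
    },
    sqrt = {
      if (any(x < 0, na.rm = TRUE))
        md_stop("sqrt transform requires nonnegative values", "transform_error")
      sqrt(x)
    },
    md_stop(sprintf("unknown transform label '%s'", label), "transform_error")
  )
}

#' Default transform registry for mixed-model tests
#'
#' Right-skewed variables are linearised before model fitting: root biomass
#' carbon, biomass-specific growth, turnover time and the fungal:bacterial
#' necromass ratio on the log scale, gross growth on the square-root scale.
#' All other variables enter untransformed. The registry is a named character
#' vector mapping variable names to transform labels; variables absent from it
#' default to `"identity"`.
#'
#' @return Named character vector of transform labels.
#' @export
lmm_default_transforms <- function() {
  c(root_c = "log", growth = "sqrt", q_growth = "log",
    turnover_time = "log", fb_ratio = "log")
}

#' Default transform registry for path models
#'
#' The causal system is specified on the measurement scale, with two
#' exceptions: sown plant species richness enters as log(PSR) (the diversity
#' treatment is a geometric series) and root biomass carbon, whose
#' distribution is strongly right-skewed, enters on the log scale.
#'
#' @return Named character vector of transform labels.
#' @export
sem_default_transforms <- function() {
  c(psr_sown = "log", root_c = "log")
}

transform_of <- function(variable, registry) {
  if (!is.null(registry) && variable %in% names(registry)) registry[[variable]]
  else "identity"
}

transform_columns <- function(data, variables, registry) {
  out <- data
  for (v in variables) {
    out[[v]] <- apply_transform(data[[v]], transform_of(v, registry))
  }
  out
}
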