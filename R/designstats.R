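# Plot-level inference for the randomized block design: block correction,
# ML mixed models with sequential likelihood-ratio tests, and the
# block-corrected Pearson correlation matrix.

#' Remove block effects from a plot-level variable
#'
#' Recenters every block on the grand mean: each value has its block mean
#' minus the grand mean subtracted, so that all corrected block means equal
#' the grand mean while within-block deviations (and the grand mean itself)
#' are preserved. The operation is idempotent.
#'
#' @param values Numeric vector, one value per plot.
#' @param blocks Block labels, same length.
#' @return Block-corrected numeric vector.
#' @export
block_correct <- function(values, blocks) {
  if (length(values) != length(blocks)) {
    md_stop("values and blocks must have equal length", "schema_error")
  }
  if (anyNA(values) || anyNA(blocks)) {
    md_stop("missing values or block labels", "degenerate_design")
  }
  blocks <- factor(blocks)
  if (any(table(blocks) == 0L)) {
    md_stop("empty block in design", "degenerate_design")
  }
  bm <- tapply(values, blocks, mean)
  as.numeric(values - (bm[as.character(blocks)] - mean(values)))
}

block_correct_columns <- function(data, variables, block = "block") {
  for (v in variables) data[[v]] <- block_correct(data[[v]], data[[block]])
  data
}

#' Fit a linear mixed model with a block random intercept
#'
#' Thin wrapper around [nlme::lme()] exposing what the inference chain
#' needs: the maximised log-likelihood, the fixed-effect table, and the
#' random-intercept and residual standard deviations. Fits use maximum
#' likelihood by default so that models differing in fixed effects are
#' comparable by likelihood-ratio test.
#'
#' @param data Data frame containing the response, the fixed-term columns
#'   and the block column.
#' @param response Name of the response column.
#' @param fixed_terms Character vector of fixed-effect column names (may be
#'   empty for an intercept-only model).
#' @param block Name of the block column.
#' @param method `"ML"` (default) or `"REML"`.
#' @return Object of class `micdiv_lmm`: a list with elements `model`,
#'   `logLik`, `coefficients` (estimate, SE, df, t, p per term), `varcomp`
#'   (block and residual SDs), `n`, `response`, `fixed_terms`.
#' @export
fit_lmm <- function(data, response, fixed_terms = character(),
                    block = "block", method = "ML") {
  check_columns(data, c(response, fixed_terms, block), "data")
  if (length(unique(data[[block]])) < 2L) {
    md_stop("need at least 2 blocks for a block random intercept",
            "degenerate_design")
  }
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  fixed <- stats::as.formula(paste(response, "~", rhs))
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = data)
  if (qr(mm)$rank < ncol(mm)) {
    md_stop("fixed-effect design matrix is rank deficient", "collinear_terms")
  }
  d <- data
  d[[block]] <- factor(d[[block]])
  # fit on the z-scaled response for numerical robustness (extreme response
  # scales otherwise break the optimizer); every reported quantity is
  # back-transformed, and likelihood differences are unaffected
  mu_y <- mean(d[[response]])
  s_y <- stats::sd(d[[response]])
  if (!is.finite(s_y) || s_y <= 0) {
    md_stop("response has zero variance", "fit_failure")
  }
  d[[response]] <- (d[[response]] - mu_y) / s_y
  random <- stats::as.formula(paste("~ 1 |", block))
  fit <- tryCatch(
    nlme::lme(fixed, random = random, data = d, method = method),
    error = function(e) {
      # retry with the BFGS optimizer; nlminb occasionally false-converges
      # when the block variance sits on the boundary
      tryCatch(
        nlme::lme(fixed, random = random, data = d, method = method,
                  control = nlme::lmeControl(opt = "optim")),
        error = function(e2) {
          md_stop(paste("mixed model failed to converge:",
                        conditionMessage(e2)), "fit_failure")
        }
      )
    }
  )
  tt <- summary(fit)$tTable
  vc <- nlme::VarCorr(fit)
  varcomp <- c(block_sd = as.numeric(vc["(Intercept)", "StdDev"]) * s_y,
               resid_sd = as.numeric(vc["Residual", "StdDev"]) * s_y)
  est <- tt[, "Value"] * s_y
  est[rownames(tt) == "(Intercept)"] <-
    est[rownames(tt) == "(Intercept)"] + mu_y
  structure(list(
    model = fit,
    logLik = as.numeric(stats::logLik(fit)) - nrow(d) * log(s_y),
    coefficients = data.frame(
      term = rownames(tt), estimate = est,
      se = tt[, "Std.Error"] * s_y, df = tt[, "DF"],
      t = tt[, "t-value"], p = tt[, "p-value"],
      row.names = NULL, stringsAsFactors = FALSE
    ),
    varcomp = varcomp,
    n = nrow(d),
    response = response,
    fixed_terms = fixed_terms
  ), class = "micdiv_lmm")
}

#' @export
print.micdiv_lmm <- function(x, ...) {
  cat("Linear mixed model (", x$response, " ~ ",
      if (length(x$fixed_terms)) paste(x$fixed_terms, collapse = " + ") else "1",
      " + (1 | block)), logLik = ", format(x$logLik, digits = 6), "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between nested ML fits
#'
#' @param full,reduced `micdiv_lmm` fits of nested fixed-effect structures
#'   (same response, same data, ML).
#' @param df Degrees of freedom of the test (number of added terms).
#' @return List with `L` (the likelihood-ratio statistic), `df` and `p`.
#' @export
lr_test <- function(full, reduced, df = 1L) {
  L <- 2 * (full$logLik - reduced$logLik)
  # guard against tiny negative values from convergence noise
  L <- max(L, 0)
  list(L = L, df = df, p = stats::pchisq(L, df = df, lower.tail = FALSE))
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-partitioning R-squared for a Gaussian random-intercept model:
#' the marginal value is the fixed-effect variance over the total (fixed +
#' random-intercept + residual) variance, the conditional value additionally
#' credits the random intercept.
#'
#' @param fit A `micdiv_lmm` object.
#' @return Named numeric vector with `r2_marginal` and `r2_conditional`.
#' @export
r2_mixed <- function(fit) {
  # all three components on the model's internal (z-scaled) response scale;
  # the ratios are scale invariant
  vc <- nlme::VarCorr(fit$model)
  var_f <- stats::var(as.numeric(stats::predict(fit$model, level = 0)))
  var_b <- as.numeric(vc["(Intercept)", "Variance"])
  var_e <- as.numeric(vc["Residual", "Variance"])
  tot <- var_f + var_b + var_e
  c(r2_marginal = var_f / tot, r2_conditional = (var_f + var_b) / tot)
}

#' Significance codes for p-values
#'
#' `***` for p <= .001, `**` for p <= .01, `*` for p <= .05, a dagger for
#' p <= .1, empty otherwise; boundary values take the stronger code.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    md_stop("p-values must lie in [0, 1]", "invalid_p")
  }
  out <- character(length(p))
  out[p <= 0.1] <- "\u2020"
  out[p <= 0.05] <- "*"
  out[p <= 0.01] <- "**"
  out[p <= 0.001] <- "***"
  out
}

#' Sequential likelihood-ratio tests for plant diversity terms
#'
#' Reproduces the sequential testing scheme of a randomized-block diversity
#' experiment: log-transformed sown species richness (PSR) is tested against
#' the intercept-only model, functional-group richness (PFGR) is tested
#' after PSR, and each functional-group identity flag (small herbs, tall
#' herbs, grasses, legumes) is tested in a separate model already containing
#' PSR and PFGR. All fits are ML linear mixed models with a block random
#' intercept; each test has 1 df. With `order = "pfgr-first"` the roles of
#' PSR and PFGR in the first two tests are swapped.
#'
#' @param data Plot-level data frame with columns `psr_sown`, `pfgr`,
#'   `has_small_herbs`, `has_tall_herbs`, `has_grasses`, `has_legumes`,
#'   `block`, and the response.
#' @param response Name of the response column.
#' @param order `"psr-first"` (default) or `"pfgr-first"`.
#' @param transforms Transform registry applied to the response, see
#'   [lmm_default_transforms()].
#' @return Data frame with one row per term (`PSR_log`, `PFGR`, `SH`, `TH`,
#'   `GR`, `LEG`): likelihood-ratio statistic `L`, `df`, `p`, significance
#'   `code`, and `direction` (sign of the fitted coefficient).
#' @export
sequential_lr_tests <- function(data, response,
                                order = c("psr-first", "pfgr-first"),
                                transforms = lmm_default_transforms()) {
  order <- match.arg(order)
  flags <- c(SH = "has_small_herbs", TH = "has_tall_herbs",
             GR = "has_grasses", LEG = "has_legumes")
  check_columns(data, c("psr_sown", "pfgr", flags, "block", response), "data")

  d <- data
  d$.y <- apply_transform(d[[response]], transform_of(response, transforms))
  if (stats::sd(d$.y) == 0) {
    # a strictly constant response carries no information: every comparison
    # of nested models is a tie
    return(data.frame(
      response = response,
      term = c("PSR_log", "PFGR", "SH", "TH", "GR", "LEG"),
      L = 0, df = 1L, p = 1, code = "", direction = 0,
      stringsAsFactors = FALSE))
  }
  d$.psr_log <- log(d$psr_sown)
  d$.pfgr <- as.numeric(d$pfgr)
  for (f in flags) d[[f]] <- as.numeric(d[[f]])

  first <- if (order == "psr-first") ".psr_log" else ".pfgr"
  second <- if (order == "psr-first") ".pfgr" else ".psr_log"

  m0 <- fit_lmm(d, ".y", character(), block = "block")
  m1 <- fit_lmm(d, ".y", first, block = "block")
  m2 <- fit_lmm(d, ".y", c(first, second), block = "block")

  one_row <- function(term, full, reduced, coef_name) {
    lt <- lr_test(full, reduced)
    est <- full$coefficients$estimate[full$coefficients$term == coef_name]
    data.frame(response = response, term = term, L = lt$L, df = lt$df,
               p = lt$p, code = significance_code(lt$p),
               direction = sign(est), stringsAsFactors = FALSE)
  }

  rows <- list(
    one_row(if (order == "psr-first") "PSR_log" else "PFGR", m1, m0, first),
    one_row(if (order == "psr-first") "PFGR" else "PSR_log", m2, m1, second)
  )
  for (nm in names(flags)) {
    mf <- fit_lmm(d, ".y", c(first, second, flags[[nm]]), block = "block")
    rows[[length(rows) + 1L]] <- one_row(nm, mf, m2, flags[[nm]])
  }
  out <- do.call(rbind, rows)
  # report in the canonical PSR_log, PFGR, SH, TH, GR, LEG order
  out[order(match(out$term, c("PSR_log", "PFGR", names(flags)))), , drop = FALSE]
}

#' Pearson correlation matrix with t-based p-values
#'
#' Intended for block-corrected plot-level variables (see [block_correct()];
#' correction is the caller's responsibility so that the same corrected data
#' can feed several analyses). P-values are two-sided from the t
#' distribution with n - 2 df.
#'
#' @param data Data frame of plot-level variables.
#' @param variables Character vector of column names to correlate.
#' @return Object of class `micdiv_cormat`: list with matrices `r`, `p`,
#'   `code` and the sample size `n`.
#' @export
correlation_matrix <- function(data, variables) {
  check_columns(data, variables, "data")
  x <- as.matrix(data[variables])
  if (anyNA(x)) md_stop("missing values in correlation input", "schema_error")
  n <- nrow(x)
  if (n < 3L) md_stop("need at least 3 observations", "degenerate_design")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    md_stop(sprintf("zero-variance variable(s): %s",
                    paste(variables[sds == 0], collapse = ", ")),
            "undefined_correlation")
  }
  r <- stats::cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  code <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  off <- !is.na(p)
  code[off] <- significance_code(p[off])
  structure(list(r = r, p = p, code = code, n = n), class = "micdiv_cormat")
}

#' @export
print.micdiv_cormat <- function(x, digits = 2, ...) {
  cat("Pearson correlation matrix (n =", x$n, ")\n")
  m <- matrix(paste0(format(round(x$r, digits)), x$code),
              nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  m[upper.tri(m, diag = TRUE)] <- ""
  print(as.data.frame(m), right = TRUE)
  invisible(x)
}
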