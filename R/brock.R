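#' Brock model coefficients
#'
#' The published coefficients of the Brock (PanCan) full logistic model with
#' spiculation (McWilliams et al., N Engl J Med 2013, model 2b), shipped as
#' a versioned JSON file under `inst/extdata/`. Nodule size enters through
#' the transform `(d/10)^(-1/2) - (4/10)^(-1/2)` of the diameter `d` in mm,
#' so the linear predictor is increasing in size; age is centred at 62
#' years and nodule count at 4.
#'
#' @return A list with elements `intercept` and `terms` (named list of
#'   `coefficient` plus optional `center`/`transform`).
#' @export
brock_coefficients <- function() {
  path <- system.file("extdata", "brock_coefficients.json",
                      package = "noduleablate", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Predictor subsets of the Brock model variants
#'
#' `full` uses every term. `non_morphological` keeps age, sex, family
#' history, emphysema, nodule location, and nodule count.
#' `morphological_only` keeps nodule size, nodule type (part-solid
#' indicator), and spiculation. `no_spiculation` keeps all terms except
#' spiculation. Variants drop terms from the published linear predictor
#' without refitting; the intercept is always retained.
#'
#' @param variant One of `"full"`, `"non_morphological"`,
#'   `"morphological_only"`, `"no_spiculation"`.
#' @return Character vector of included term names.
#' @export
brock_variant_terms <- function(variant = c("full", "non_morphological",
                                            "morphological_only",
                                            "no_spiculation")) {
  variant <- match.arg(variant)
  all_terms <- c("age", "sex", "family_history", "emphysema", "size",
                 "upper_lobe", "part_solid", "nodule_count", "spiculation")
  switch(variant,
    full = all_terms,
    non_morphological = c("age", "sex", "family_history", "emphysema",
                          "upper_lobe", "nodule_count"),
    morphological_only = c("size", "part_solid", "spiculation"),
    no_spiculation = setdiff(all_terms, "spiculation")
  )
}

brock_term_value <- function(term, data, size_mm) {
  switch(term,
    age = data$age_years,
    sex = as.numeric(data$sex == "female"),
    family_history = as.numeric(data$family_history),
    emphysema = as.numeric(data$emphysema),
    size = size_mm,
    upper_lobe = as.numeric(data$upper_lobe),
    part_solid = as.numeric(data$nodule_type == "part_solid"),
    nodule_count = as.numeric(data$nodule_count),
    spiculation = as.numeric(data$spiculation),
    abort(sprintf("Unknown Brock term `%s`.", term))
  )
}

brock_term_contribution <- function(term, spec, value) {
  x <- value
  if (!is.null(spec$transform) && identical(spec$transform, "inverse_sqrt_cm")) {
    x <- (x / 10)^(-0.5)
  }
  if (!is.null(spec$center)) x <- x - spec$center
  spec$coefficient * x
}

#' Brock linear predictor
#'
#' Evaluates the published Brock linear predictor for each row of a nodule
#' table, using the chosen size input and variant. Excluded terms of a
#' feature-reduced variant contribute exactly zero. Sizes outside (0, 30]
#' mm trigger a warning, as the published calculator was not designed for
#' masses above 30 mm.
#'
#' @param data A tibble with columns `age_years`, `sex`, `family_history`,
#'   `emphysema`, `upper_lobe`, `nodule_type`, `nodule_count`,
#'   `spiculation` (cohort-table layout).
#' @param size_mm Numeric vector of nodule sizes in mm (recycled to rows of
#'   `data`), or the name of a column of `data` to use.
#' @param variant See [brock_variant_terms()].
#' @param coefficients Coefficient set, defaulting to
#'   [brock_coefficients()].
#' @return Numeric vector of linear predictors.
#' @export
brock_linear_predictor <- function(data, size_mm,
                                   variant = "full",
                                   coefficients = brock_coefficients()) {
  if (is.character(size_mm) && length(size_mm) == 1) {
    if (!size_mm %in% names(data)) abort(sprintf("No column `%s` in `data`.", size_mm))
    size_mm <- data[[size_mm]]
  }
  size_mm <- rep_len(as.numeric(size_mm), nrow(data))
  if (any(!is.finite(size_mm)) || any(size_mm <= 0)) {
    abort("`size_mm` must be strictly positive.")
  }
  if (any(size_mm > 30)) {
    warn("Some sizes exceed 30 mm; the Brock calculator was not designed for masses > 30 mm.")
  }
  terms <- brock_variant_terms(variant)
  lp <- rep(coefficients$intercept, nrow(data))
  for (term in terms) {
    spec <- coefficients$terms[[term]]
    if (is.null(spec) || is.null(spec$coefficient)) {
      abort(sprintf("Coefficient for term `%s` is missing.", term))
    }
    lp <- lp + brock_term_contribution(term, spec, brock_term_value(term, data, size_mm))
  }
  lp
}

#' Brock malignancy risk
#'
#' Logistic transform of [brock_linear_predictor()]; returns the input
#' table augmented with the linear predictor and the malignancy
#' probability, which is strictly increasing in `size_mm` with all other
#' predictors held fixed.
#'
#' @inheritParams brock_linear_predictor
#' @return The input tibble with added columns `brock_lp`,
#'   `brock_probability`, and `brock_variant`.
#' @export
brock_risk <- function(data, size_mm, variant = "full",
                       coefficients = brock_coefficients()) {
  lp <- brock_linear_predictor(data, size_mm, variant, coefficients)
  out <- as_tibble(data)
  out$brock_lp <- lp
  out$brock_probability <- plogis(lp)
  out$brock_variant <- variant
  out
}

#' Refit a Brock-style logistic model on a cohort
#'
#' Sensitivity-analysis alternative to term dropping: refits a logistic
#' regression with the variant's predictors (same transforms and centrings
#' as the published model) against the cohort's labels via
#' [stats::glm()]. Intended for checking how much variant conclusions
#' depend on using the published coefficients unchanged.
#'
#' @inheritParams brock_linear_predictor
#' @param labels Logical/0-1 outcome vector aligned with `data`.
#' @return A tibble of refitted coefficients with columns `term` and
#'   `estimate`, with the fitted probabilities in `attr(,"fitted")`.
#' @export
brock_refit <- function(data, size_mm, labels, variant = "full",
                        coefficients = brock_coefficients()) {
  if (is.character(size_mm) && length(size_mm) == 1) size_mm <- data[[size_mm]]
  terms <- brock_variant_terms(variant)
  X <- vapply(terms, function(term) {
    spec <- coefficients$terms[[term]]
    brock_term_contribution(term, spec, brock_term_value(term, data, size_mm)) /
      spec$coefficient
  }, numeric(nrow(data)))
  df <- as.data.frame(X)
  df$.y <- as.numeric(labels)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  out <- tibble(term = names(stats::coef(fit)), estimate = unname(stats::coef(fit)))
  attr(out, "fitted") <- unname(stats::fitted(fit))
  out
}
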