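# cache for the parsed equation resource
.published_env <- new.env(parent = emptyenv())

#' @noRd
published_equation_table <- function() {
  if (is.null(.published_env$tab)) {
    path <- system.file("extdata", "published_equations.json",
                        package = "wantpower", mustWork = TRUE)
    .published_env$tab <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  .published_env$tab
}

#' Load a published prediction equation
#'
#' Returns one of the six previously published multiple-regression equations
#' predicting Wingate peak power (PP) or mean power (MP), watts, at 85, 90 or
#' 100 percent of age-predicted HRmax. The equations are shipped as a
#' versioned JSON resource; coefficients apply to z-scored features and the
#' intercept is the predicted wattage at the standardised origin. Because the
#' original calibration cohort's feature means and SDs are not available,
#' absolute predictions depend on the standardisation frame supplied at
#' prediction time.
#'
#' @param outcome `"pp"` or `"mp"`.
#' @param level 0.85, 0.90 or 1.00.
#' @return object of class `published_equation` with fields `outcome`,
#'   `level`, `intercept`, `terms` (named coefficient vector), `provenance`.
#' @examples
#' eq <- load_published_equation("pp", 0.85)
#' eq$intercept # 644
#' @export
load_published_equation <- function(outcome = c("pp", "mp"), level) {
  outcome <- match.arg(outcome)
  tab <- published_equation_table()
  for (e in tab$equations) {
    if (e$outcome == outcome && abs(e$level - level) < 1e-9) {
      coefs <- vapply(e$terms, function(t) t$coefficient, numeric(1))
      names(coefs) <- vapply(e$terms, function(t) t$feature, character(1))
      return(structure(list(
        outcome = outcome, level = e$level, intercept = e$intercept,
        terms = coefs, provenance = e$provenance
      ), class = "published_equation"))
    }
  }
  wp_stop(sprintf("no published equation for outcome '%s' at level %s",
                  outcome, format(level)), "wp_not_found")
}

#' All published equations
#'
#' @return list of the six [load_published_equation()] objects.
#' @export
published_equations <- function() {
  tab <- published_equation_table()
  lapply(tab$equations, function(e) load_published_equation(e$outcome, e$level))
}

#' Apply a published equation to a feature vector
#'
#' Computes `intercept + sum(coefficient * z)` where `z` are the z-scored
#' feature values under the supplied standardisation statistics. A warning
#' (not an error) is raised for non-positive predicted wattages.
#'
#' @param equation a `published_equation`.
#' @param features named numeric vector, one-row data.frame or row of a
#'   [feature_matrix()] holding the raw-scale feature values the equation
#'   needs.
#' @param stats list with named numeric vectors `mean` and `sd` covering the
#'   equation's features (the standardisation frame).
#' @return predicted power, watts.
#' @export
predict_power <- function(equation, features, stats) {
  stopifnot(inherits(equation, "published_equation"))
  if (is.data.frame(features)) features <- unlist(features[1L, , drop = TRUE])
  need <- names(equation$terms)
  missing_f <- need[!need %in% names(features)]
  if (length(missing_f)) {
    wp_stop(paste0("missing required feature(s): ", paste(missing_f, collapse = ", ")),
            "wp_not_found")
  }
  mu <- stats$mean[need]
  sdv <- stats$sd[need]
  if (anyNA(mu) || anyNA(sdv)) {
    wp_stop("standardisation stats do not cover all equation features",
            "wp_invalid_input")
  }
  z <- (as.numeric(features[need]) - mu) / sdv
  pred <- equation$intercept + sum(equation$terms * z)
  if (pred <= 0) {
    warning(sprintf("non-positive predicted power (%.1f W) from %s equation",
                    pred, toupper(equation$outcome)))
  }
  unname(pred)
}

#' Serialise / restore a published equation
#'
#' @param equation a `published_equation`.
#' @param path file path for the JSON.
#' @return `write_equation_json` returns `path` invisibly;
#'   `read_equation_json` returns the restored `published_equation`.
#' @export
write_equation_json <- function(equation, path) {
  stopifnot(inherits(equation, "published_equation"))
  jsonlite::write_json(list(
    outcome = equation$outcome, level = equation$level,
    intercept = equation$intercept,
    terms = lapply(seq_along(equation$terms), function(i) {
      list(feature = names(equation$terms)[i],
           coefficient = unname(equation$terms[i]))
    }),
    provenance = equation$provenance
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_equation_json
#' @export
read_equation_json <- function(path) {
  e <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  coefs <- vapply(e$terms, function(t) t$coefficient, numeric(1))
  names(coefs) <- vapply(e$terms, function(t) t$feature, character(1))
  structure(list(
    outcome = e$outcome, level = e$level, intercept = e$intercept,
    terms = coefs, provenance = e$provenance
  ), class = "published_equation")
}

#' @export
print.published_equation <- function(x, ...) {
  cat(sprintf("<published_equation> %s at %d%% HRmax: %g %s\n",
              toupper(x$outcome), round(x$level * 100), x$intercept,
              paste(sprintf("%+g*z(%s)", x$terms, names(x$terms)), collapse = " ")))
  invisible(x)
}
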