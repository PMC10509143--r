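#' Fit the colour-feature linear predictor of Hb mass
#'
#' Ordinary least squares regression of Hb mass (mg) on the four image
#' features, `mass = b0 + b1*x1 + b2*x2 + b3*x3 + b4*x4`, fitted with
#' [stats::lm()]. No regularisation is applied.
#'
#' @param features data.frame or matrix with columns `x1, x2, x3, x4`
#'   (see [extract_features()]).
#' @param mass numeric vector of true Hb masses (mg), one per row.
#' @return An object of class `hb_linear` with components `coefficients`
#'   (named `b0..b4`, in mg per feature unit), `fit` (the underlying `lm`)
#'   and `n`.
#' @seealso [predict.hb_linear()], [write_linear_coefs()]
#' @export
fit_hb_linear <- function(features, mass) {
  features <- as.data.frame(features)
  required <- c("x1", "x2", "x3", "x4")
  if (!all(required %in% names(features))) {
    stop("`features` must have columns x1, x2, x3, x4", call. = FALSE)
  }
  n <- nrow(features)
  if (length(mass) != n) {
    stop("`mass` must have one value per feature row", call. = FALSE)
  }
  if (n < 5L) {
    stop(sprintf(paste0("need at least 5 samples to estimate 5 coefficients ",
                        "(got %d)"), n), call. = FALSE)
  }
  dat <- cbind(features[required], hb_mass = mass)
  X <- stats::model.matrix(~ x1 + x2 + x3 + x4, dat)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient: the four features (plus ",
         "intercept) are collinear on this sample", call. = FALSE)
  }
  fit <- stats::lm(hb_mass ~ x1 + x2 + x3 + x4, data = dat)
  coefs <- stats::coef(fit)
  names(coefs) <- paste0("b", 0:4)
  structure(list(coefficients = coefs, fit = fit, n = n),
            class = "hb_linear")
}

#' @export
coef.hb_linear <- function(object, ...) object$coefficients

#' @export
print.hb_linear <- function(x, ...) {
  cat("Colour-feature linear Hb-loss model (OLS, n =", x$n, ")\n")
  cat("  mass_mg = b0 + b1*x1 + b2*x2 + b3*x3 + b4*x4\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.hb_linear <- function(object, ...) summary(object$fit, ...)

#' @export
residuals.hb_linear <- function(object, ...) stats::residuals(object$fit)

#' Predict Hb mass from features
#'
#' @param object an `hb_linear` model.
#' @param newdata data.frame/matrix with columns `x1..x4`, or a single named
#'   feature vector.
#' @param clamp if `TRUE`, negative predictions are reported as 0 mg (a
#'   physical mass cannot be negative). The default `FALSE` returns the raw
#'   linear predictor, which is what evaluation metrics are computed on.
#' @param ... unused.
#' @return Numeric vector of predicted Hb masses (mg).
#' @export
predict.hb_linear <- function(object, newdata, clamp = FALSE, ...) {
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
  }
  newdata <- as.data.frame(newdata)
  b <- object$coefficients
  pred <- b[1] + b[2] * newdata$x1 + b[3] * newdata$x2 +
    b[4] * newdata$x3 + b[5] * newdata$x4
  pred <- unname(pred)
  if (clamp) pmax(pred, 0) else pred
}

#' Serialise linear coefficients to JSON
#'
#' Writes `{"b0": ..., "b1": ..., ...}`; [read_linear_coefs()] restores an
#' `hb_linear` object usable for prediction (without the underlying `lm`).
#'
#' @param object an `hb_linear` model or a named `b0..b4` vector.
#' @param path output JSON file.
#' @export
write_linear_coefs <- function(object, path) {
  coefs <- if (inherits(object, "hb_linear")) object$coefficients else object
  stopifnot(length(coefs) == 5L)
  names(coefs) <- paste0("b", 0:4)
  jsonlite::write_json(as.list(coefs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_linear_coefs
#' @export
read_linear_coefs <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(vals[paste0("b", 0:4)])
  if (length(coefs) != 5L || any(!is.finite(coefs))) {
    stop("JSON file does not contain finite coefficients b0..b4",
         call. = FALSE)
  }
  structure(list(coefficients = coefs, fit = NULL, n = NA_integer_),
            class = "hb_linear")
}
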