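#' Fit a single regression decision stump
#'
#' Finds the depth-1 split of `x` that minimises the residual sum of squares
#' of `r`.  Candidate thresholds are the midpoints of consecutive distinct
#' sorted values of `x`; the two leaf values are the mean residual on each
#' side of the split.  Ties in SSE are broken towards the smallest threshold.
#' A constant `x` yields the degenerate stump with threshold `-Inf` and both
#' leaves equal to `mean(r)`.
#'
#' @param x numeric feature vector.
#' @param r numeric residual vector of the same length (at least 2).
#' @return A list with components `threshold`, `left`, `right` (leaf values,
#'   applied as `x <= threshold` -> left, else right) and `sse`, the residual
#'   sum of squares attained by the stump.
#' @examples
#' fit_stump(c(1, 2, 3, 4), c(-1, -1, 1, 1))  # splits at 2.5 with SSE 0
#' @export
fit_stump <- function(x, r) {
  x <- as.numeric(x)
  r <- as.numeric(r)
  if (length(x) != length(r))
    stop("'x' and 'r' must have the same length")
  if (length(x) < 2L)
    stop("need at least 2 observations to fit a stump")
  if (anyNA(x) || anyNA(r))
    stop("missing values are not allowed")
  fit_stump_cpp(x, r)
}

#' Gaussian-family deviance
#'
#' The deviance \eqn{D = -2(\log L - \log L_s)} of a Gaussian response
#' under a unit-variance working likelihood, where \eqn{L_s} is the
#' saturated model fitting every observation exactly.  It equals the
#' residual sum of squares \eqn{\sum_i (y_i - \hat y_i)^2} and is 0 iff
#' the fit is perfect.
#'
#' @param y observed responses.
#' @param y_hat fitted values of the same length.
#' @return The deviance (a single non-negative number).
#' @examples
#' gaussian_deviance(c(0, 1), c(0.5, 0.5))  # 0.5
#' @export
gaussian_deviance <- function(y, y_hat) {
  if (length(y) != length(y_hat))
    stop("'y' and 'y_hat' must have the same length")
  sum((y - y_hat)^2)
}

.check_binary_response <- function(y) {
  if (!is.numeric(y))
    stop("response must be numeric 0/1")
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("response must be binary, coded 0/1")
  invisible(y)
}

#' Gradient-boosted additive model of decision stumps
#'
#' Fits the additive model \eqn{y = c + f_1(x_1) + \dots + f_p(x_p)} by
#' gradient boosting with depth-1 regression trees (decision stumps) as weak
#' learners under a Gaussian deviance.  The response is a binary class
#' indicator treated as a Gaussian regression target, so fitted values are
#' continuous scores; each shape function \eqn{f_j} is the sum of the
#' learning-rate-scaled stumps grown on feature \eqn{j} and is exactly
#' piecewise constant.
#'
#' The intercept is initialised to `mean(y)`.  Under the default `"cyclic"`
#' policy every feature receives one stump per boosting round, fitted to the
#' current residuals in canonical column order; under `"best"` a single stump
#' per round is grown on the feature whose stump attains the lowest SSE.
#' Because every stump's leaves are mean residuals and the learning rate lies
#' in (0, 1], the training deviance (residual sum of squares) is
#' non-increasing round over round.
#'
#' @param formula model formula; the response must be coded 0/1.
#' @param data a data frame containing the variables in the model.
#' @param n_rounds number of boosting rounds (>= 1).
#' @param learning_rate shrinkage factor \eqn{\eta} in (0, 1] applied to every
#'   stump.
#' @param feature_policy `"cyclic"` (one stump per feature per round, the
#'   default) or `"best"` (one stump per round on the best feature).
#' @param na.action how to handle missing values (default: fail).
#' @return An object of class `"gam_boost"`; see Details for components.
#'   Methods are provided for [predict][predict.gam_boost],
#'   `print`, `summary`, `coef`, `fitted`, `residuals`, `deviance`,
#'   [plot][plot.gam_boost] and [simulate][simulate.gam_boost].
#' @details The returned object contains, among others, `intercept`,
#'   `stumps` (a data frame of learning-rate-scaled stumps), `shapes`
#'   (per-feature breakpoint/value tables; see [shape_functions()]),
#'   `deviance_trace` (training deviance after each round), `null_deviance`
#'   and `diagnostics` (log-likelihoods of the fitted and saturated model
#'   under a unit-variance Gaussian working likelihood, for which the
#'   deviance \eqn{-2(\log L - \log L_s)} equals the residual sum of
#'   squares exactly).
#' @seealso [gam_boost_fit()] for the matrix interface used in tight loops.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(200))
#' d$y <- as.numeric(d$x + rnorm(200, sd = 0.5) > 0)
#' fit <- gam_boost(y ~ x, d, n_rounds = 50)
#' fit
#' @export
gam_boost <- function(formula, data, n_rounds = 300, learning_rate = 0.1,
                      feature_policy = c("cyclic", "best"),
                      na.action = stats::na.fail) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = na.action)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  x <- stats::model.matrix(mt, mf)
  ic <- match("(Intercept)", colnames(x))
  if (!is.na(ic)) x <- x[, -ic, drop = FALSE]
  fit <- gam_boost_fit(x, y, n_rounds = n_rounds,
                       learning_rate = learning_rate,
                       feature_policy = feature_policy)
  fit$terms <- mt
  fit$xlevels <- stats::.getXlevels(mt, mf)
  fit$call <- cl
  fit
}

#' Matrix-interface workhorse for [gam_boost()]
#'
#' @param x numeric matrix of predictors (columns are features).
#' @param y binary 0/1 response vector.
#' @inheritParams gam_boost
#' @return A fitted `"gam_boost"` object (without formula metadata).
#' @export
gam_boost_fit <- function(x, y, n_rounds = 300, learning_rate = 0.1,
                          feature_policy = c("cyclic", "best")) {
  feature_policy <- match.arg(feature_policy)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  .check_binary_response(y)
  y <- as.numeric(y)
  if (nrow(x) != length(y) && ncol(x) > 0L)
    stop("nrow(x) must equal length(y)")
  if (anyNA(x))
    stop("missing values in predictors")
  n_rounds <- as.integer(n_rounds)
  if (n_rounds < 1L) stop("n_rounds must be >= 1")
  if (!(learning_rate > 0 && learning_rate <= 1))
    stop("learning_rate must lie in (0, 1]")

  nm <- colnames(x)
  if (is.null(nm) && ncol(x) > 0L) nm <- paste0("x", seq_len(ncol(x)))
  n <- length(y)

  if (ncol(x) == 0L) {
    # intercept-only model
    intercept <- mean(y)
    resid <- y - intercept
    nd <- sum(resid^2)
    core <- list(intercept = intercept,
                 stumps = matrix(numeric(0), 0, 4),
                 deviance_trace = rep(nd, n_rounds),
                 null_deviance = nd, residuals = resid)
  } else {
    core <- boost_fit_cpp(x, y, learning_rate, n_rounds,
                          if (feature_policy == "cyclic") 0L else 1L)
  }

  stumps <- as.data.frame(core$stumps)
  names(stumps) <- c("feature", "threshold", "left", "right")
  stumps$feature <- as.integer(stumps$feature)

  shapes <- .build_shapes(stumps, length(nm))
  names(shapes) <- nm

  dev <- core$deviance_trace[n_rounds]
  obj <- structure(list(
    intercept = core$intercept,
    stumps = stumps,
    shapes = shapes,
    feature_names = nm,
    learning_rate = learning_rate,
    n_rounds = n_rounds,
    feature_policy = feature_policy,
    deviance_trace = as.numeric(core$deviance_trace),
    null_deviance = core$null_deviance,
    deviance = dev,
    residuals = as.numeric(core$residuals),
    fitted.values = y - as.numeric(core$residuals),
    n = n,
    diagnostics = list(
      logLik_fitted = -dev / 2 - n / 2 * log(2 * pi),
      logLik_saturated = -n / 2 * log(2 * pi))
  ), class = "gam_boost")
  obj
}

# Collapse a feature's stump list into its piecewise-constant shape table:
# intervals (-Inf, b1], (b1, b2], ..., (bu, Inf) with one value per interval.
.build_shapes <- function(stumps, p) {
  lapply(seq_len(p), function(j) {
    s <- stumps[stumps$feature == j, , drop = FALSE]
    if (nrow(s) == 0L)
      return(list(breaks = numeric(0), values = 0))
    th <- s$threshold
    breaks <- sort(unique(th[is.finite(th)]))
    reps <- c(breaks, Inf)
    # value at representative z: sum over stumps of (z <= t ? left : right)
    left_side <- outer(reps, th, "<=")
    values <- as.numeric(left_side %*% s$left + (!left_side) %*% s$right)
    list(breaks = breaks, values = values)
  })
}

.eval_shape <- function(shape, x) {
  if (length(shape$breaks) == 0L)
    return(rep.int(shape$values[1L], length(x)))
  idx <- findInterval(x, shape$breaks, left.open = TRUE) + 1L
  shape$values[idx]
}

#' Export the fitted univariate shape functions
#'
#' Returns, for each fitted feature, the exact piecewise-constant shape
#' function \eqn{f_j} as an ordered breakpoint/value table: row *i* gives the
#' value of \eqn{f_j(x)} for \eqn{x \le \code{upper}_i} (and greater than the
#' previous row's `upper`); the final row has `upper = Inf`.
#'
#' @param object a fitted [gam_boost()] model.
#' @return A named list of data frames with columns `upper` and `value`.
#' @export
shape_functions <- function(object) {
  if (!inherits(object, "gam_boost"))
    stop("'object' must be a fitted gam_boost model")
  lapply(object$shapes, function(s)
    data.frame(upper = c(s$breaks, Inf), value = s$values))
}

.newdata_matrix <- function(object, newdata) {
  if (!is.null(object$terms)) {
    if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata)
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail,
                             xlev = object$xlevels)
    x <- stats::model.matrix(tt, mf)
    ic <- match("(Intercept)", colnames(x))
    if (!is.na(ic)) x <- x[, -ic, drop = FALSE]
  } else {
    x <- as.matrix(newdata)
    storage.mode(x) <- "double"
  }
  nm <- object$feature_names
  if (!is.null(colnames(x))) {
    missing <- setdiff(nm, colnames(x))
    extra <- setdiff(colnames(x), nm)
    if (length(missing))
      stop("newdata is missing fitted feature(s): ",
           paste(missing, collapse = ", "))
    if (length(extra))
      stop("newdata has unknown column(s): ", paste(extra, collapse = ", "))
    x <- x[, nm, drop = FALSE]
  } else if (ncol(x) != length(nm)) {
    stop("newdata must have ", length(nm), " columns")
  }
  x
}

#' Predict method for boosted additive models
#'
#' Evaluates \eqn{c + \sum_j f_j(x_j)} from the stored shape tables.  With
#' `type = "terms"` the per-feature contributions \eqn{f_j(x_j)} are returned
#' as a matrix with the intercept in `attr(, "constant")`, so that
#' `rowSums(terms) + constant` reproduces the response-scale score exactly.
#'
#' @param object a fitted [gam_boost()] model.
#' @param newdata data frame (formula fits) or numeric matrix with the fitted
#'   feature columns; if omitted, training fitted values are returned.
#' @param type `"response"` (default) or `"terms"`.
#' @param ... unused.
#' @return Numeric vector of scores, or a matrix for `type = "terms"`.
#' @export
predict.gam_boost <- function(object, newdata, type = c("response", "terms"),
                              ...) {
  type <- match.arg(type)
  if (missing(newdata) || is.null(newdata)) {
    if (type == "response") return(object$fitted.values)
    stop("type = \"terms\" requires 'newdata'")
  }
  x <- .newdata_matrix(object, newdata)
  p <- length(object$feature_names)
  contrib <- matrix(0, nrow(x), p,
                    dimnames = list(NULL, object$feature_names))
  for (j in seq_len(p))
    contrib[, j] <- .eval_shape(object$shapes[[j]], x[, j])
  if (type == "terms") {
    attr(contrib, "constant") <- object$intercept
    return(contrib)
  }
  object$intercept + rowSums(contrib)
}

#' @export
coef.gam_boost <- function(object, ...) {
  c("(Intercept)" = object$intercept)
}

#' @export
fitted.gam_boost <- function(object, ...) object$fitted.values

#' @export
residuals.gam_boost <- function(object, ...) object$residuals

#' @export
deviance.gam_boost <- function(object, ...) object$deviance

#' @export
print.gam_boost <- function(x, ...) {
  cat("Gradient-boosted stump GAM\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cat(sprintf("Features: %s\n",
              if (length(x$feature_names))
                paste(x$feature_names, collapse = ", ") else "(none)"))
  cat(sprintf("Rounds: %d  learning rate: %g  policy: %s\n",
              x$n_rounds, x$learning_rate, x$feature_policy))
  cat(sprintf("Intercept: %.4f\n", x$intercept))
  cat(sprintf("Deviance: %.4f on %d obs (null %.4f)\n",
              x$deviance, x$n, x$null_deviance))
  invisible(x)
}

#' @export
summary.gam_boost <- function(object, ...) {
  p <- length(object$feature_names)
  tab <- data.frame(
    feature = object$feature_names,
    n_stumps = vapply(seq_len(p), function(j)
      sum(object$stumps$feature == j), 0L),
    shape_min = vapply(object$shapes, function(s) min(s$values), 0),
    shape_max = vapply(object$shapes, function(s) max(s$values), 0),
    row.names = NULL)
  out <- list(call = object$call, features = tab,
              intercept = object$intercept,
              n = object$n, n_rounds = object$n_rounds,
              learning_rate = object$learning_rate,
              feature_policy = object$feature_policy,
              null_deviance = object$null_deviance,
              deviance = object$deviance,
              r_squared = 1 - object$deviance / object$null_deviance)
  class(out) <- "summary.gam_boost"
  out
}

#' @export
print.summary.gam_boost <- function(x, ...) {
  cat("Gradient-boosted stump GAM\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cat(sprintf("\n%d observations, %d rounds, eta = %g, policy = %s\n",
              x$n, x$n_rounds, x$learning_rate, x$feature_policy))
  cat(sprintf("Intercept: %.4f\n\nShape functions:\n", x$intercept))
  print(x$features, row.names = FALSE)
  cat(sprintf("\nNull deviance: %.4f\nResidual deviance: %.4f  (R^2 = %.4f)\n",
              x$null_deviance, x$deviance, x$r_squared))
  invisible(x)
}

#' Plot fitted shape functions
#'
#' Draws each univariate shape function \eqn{f_j} as a step function over the
#' range of its breakpoints.
#'
#' @param x a fitted [gam_boost()] model.
#' @param features which features to plot (names or indices; default all).
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.gam_boost <- function(x, features = NULL, ...) {
  nm <- x$feature_names
  if (is.null(features)) features <- nm
  if (is.numeric(features)) features <- nm[features]
  features <- intersect(features, nm)
  if (!length(features)) stop("no fitted features to plot")
  op <- par(mfrow = grDevices::n2mfrow(length(features)))
  on.exit(par(op))
  for (f in features) {
    s <- x$shapes[[f]]
    if (length(s$breaks) == 0L) {
      plot(0, s$values[1L], xlab = f, ylab = sprintf("f(%s)", f),
           type = "p", ...)
      next
    }
    rng <- range(s$breaks)
    pad <- 0.05 * max(diff(rng), 1e-8)
    xs <- c(rng[1] - pad, s$breaks, rng[2] + pad)
    plot(xs, s$values[c(seq_along(s$breaks), length(s$values) - 1L,
                        length(s$values))],
         type = "s", xlab = f, ylab = sprintf("f(%s)", f), ...)
    abline(h = 0, lty = 3, col = "grey60")
  }
  invisible(x)
}

#' Simulate responses from a fitted boosted GAM
#'
#' Draws Gaussian responses around the fitted scores with residual standard
#' deviation \eqn{\hat\sigma = \sqrt{D/n}} (the maximum-likelihood estimate
#' under the model's Gaussian response family).
#'
#' @param object a fitted [gam_boost()] model.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed, handled as in [stats::simulate()].
#' @param ... unused.
#' @return A data frame with `nsim` columns, as [stats::simulate()].
#' @export
simulate.gam_boost <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  sigma <- sqrt(object$deviance / object$n)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), sd = sigma),
                                 simplify = FALSE),
                       col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' Serialize a boosted GAM to JSON
#'
#' Writes the model's intercept, learning rate, rounds, policy, feature
#' names, full stump list and deviance trace at full floating-point
#' precision, so that [read_gam_boost()] reproduces predictions bit-exactly.
#'
#' @param object a fitted [gam_boost()] model.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_gam_boost <- function(object, path) {
  if (!inherits(object, "gam_boost"))
    stop("'object' must be a fitted gam_boost model")
  payload <- list(
    format = "radiogam-gam-boost",
    intercept = object$intercept,
    learning_rate = object$learning_rate,
    n_rounds = object$n_rounds,
    feature_policy = object$feature_policy,
    feature_names = object$feature_names,
    # column-wise: row-record serialization would drop -Inf thresholds
    stumps = list(feature = object$stumps$feature,
                  threshold = object$stumps$threshold,
                  left = object$stumps$left,
                  right = object$stumps$right),
    null_deviance = object$null_deviance,
    deviance_trace = object$deviance_trace,
    n = object$n)
  # 17 significant digits round-trip IEEE doubles exactly; +/-Inf thresholds
  # serialize as strings and are coerced back on read
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a serialized boosted GAM
#'
#' @param path file written by [write_gam_boost()].
#' @return A `"gam_boost"` object (without training fitted values or
#'   residuals, which are not serialized).
#' @export
read_gam_boost <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "radiogam-gam-boost"))
    stop("not a serialized gam_boost model: ", path)
  # +/-Inf thresholds round-trip through JSON as strings
  stumps <- data.frame(
    feature = as.integer(unlist(payload$stumps$feature)),
    threshold = as.numeric(unlist(payload$stumps$threshold)),
    left = as.numeric(unlist(payload$stumps$left)),
    right = as.numeric(unlist(payload$stumps$right)))
  nm <- as.character(payload$feature_names)
  shapes <- .build_shapes(stumps, length(nm))
  names(shapes) <- nm
  n <- payload$n
  dev <- payload$deviance_trace[payload$n_rounds]
  structure(list(
    intercept = payload$intercept,
    stumps = stumps,
    shapes = shapes,
    feature_names = nm,
    learning_rate = payload$learning_rate,
    n_rounds = payload$n_rounds,
    feature_policy = payload$feature_policy,
    deviance_trace = as.numeric(payload$deviance_trace),
    null_deviance = payload$null_deviance,
    deviance = dev,
    residuals = NULL,
    fitted.values = NULL,
    n = n,
    diagnostics = list(
      logLik_fitted = -dev / 2 - n / 2 * log(2 * pi),
      logLik_saturated = -n / 2 * log(2 * pi))
  ), class = "gam_boost")
}
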