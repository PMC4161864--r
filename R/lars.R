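#' @include MirnaExperiment-class.R
NULL

#' Least-angle-regression lasso path
#'
#' Computes the full piecewise-linear lasso solution path of a linear
#' regression by least angle regression with the lasso modification
#' (coefficients that hit zero are dropped from the active set and the
#' direction recomputed). Predictors are centered and scaled to unit
#' Euclidean norm internally and an intercept is fitted, matching the
#' common conventions of lasso-path software; returned coefficients are
#' on the original predictor scale. The path starts at the empty model
#' and ends at the least-penalized solution (the OLS fit when the number
#' of predictors allows it).
#'
#' @param x numeric matrix of predictors, samples in rows.
#' @param y numeric response.
#' @param eps numerical tolerance for correlation ties and zero
#'   crossings.
#' @param maxSteps cap on path steps; default `8 * min(p, n - 1)`.
#' @return An object of class `larsPath`: a list with `beta` (matrix of
#'   path knots, one row per step, original scale), `intercepts`,
#'   `l1` (L1 norm at each knot), `actions` (variable entering/leaving,
#'   negative = drop), `meanx`, `meany`, `normx`.
#' @seealso [predictLarsPath()], [lassoPathPredict()]
#' @export
larsPath <- function(x, y, eps = 1e-10, maxSteps = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n, n >= 2L)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  meanx <- colMeans(x)
  xc <- sweep(x, 2L, meanx)
  normx <- sqrt(colSums(xc^2))
  valid <- which(normx > eps * sqrt(n))
  xs <- xc
  xs[, valid] <- sweep(xc[, valid, drop = FALSE], 2L, normx[valid], "/")
  meany <- mean(y)
  r <- y - meany
  beta <- numeric(p)
  active <- integer(0)
  justDropped <- integer(0)
  limit <- min(length(valid), n - 1L)
  if (is.null(maxSteps)) maxSteps <- 8L * max(1L, min(p, n - 1L))
  knots <- matrix(0, nrow = 1L, ncol = p)
  actions <- integer(0)
  step <- 0L

  while (step < maxSteps && limit > 0L) {
    step <- step + 1L
    r <- (y - meany) - xs[, valid, drop = FALSE] %*% beta[valid]
    cvec <- numeric(p)
    cvec[valid] <- crossprod(xs[, valid, drop = FALSE], r)
    Cmax <- max(abs(cvec[valid]))
    if (Cmax < eps) break
    candidates <- setdiff(valid, c(active, justDropped))
    entering <- candidates[abs(cvec[candidates]) >= Cmax - eps]
    if (length(entering)) {
      active <- c(active, entering)
      actions <- c(actions, entering)
    }
    justDropped <- integer(0)
    if (length(active) == 0L) break
    sgn <- sign(cvec[active])
    XA <- sweep(xs[, active, drop = FALSE], 2L, sgn, "*")
    GA <- crossprod(XA)
    w1 <- tryCatch(solve(GA, rep(1, length(active))),
                   error = function(e)
                     solve(GA + diag(1e-12, nrow(GA)),
                           rep(1, length(active))))
    AA <- 1 / sqrt(sum(w1))
    w <- AA * w1
    u <- XA %*% w
    dirA <- sgn * w                       # movement of beta[active]
    atLimit <- length(active) >= limit
    if (atLimit) {
      gamma <- Cmax / AA
    } else {
      inactive <- setdiff(valid, active)
      a <- as.numeric(crossprod(xs[, inactive, drop = FALSE], u))
      cj <- cvec[inactive]
      g <- c((Cmax - cj) / (AA - a), (Cmax + cj) / (AA + a))
      g <- g[is.finite(g) & g > eps]
      gamma <- min(c(g, Cmax / AA))
    }
    # lasso modification: stop where a coefficient would cross zero
    gz <- -beta[active] / dirA
    hit <- which(is.finite(gz) & gz > eps & gz < gamma - eps)
    dropped <- integer(0)
    if (length(hit)) {
      gtilde <- min(gz[hit])
      dropped <- active[which(abs(gz - gtilde) <= eps & gz > eps)]
      gamma <- gtilde
    }
    beta[active] <- beta[active] + gamma * dirA
    if (length(dropped)) {
      beta[dropped] <- 0
      actions <- c(actions, -dropped)
      justDropped <- dropped
      active <- setdiff(active, dropped)
    }
    knots <- rbind(knots, beta)
    if (atLimit && !length(dropped)) break
  }

  betaOrig <- sweep(knots, 2L, pmax(normx, eps), "/")
  betaOrig[, setdiff(seq_len(p), valid)] <- 0
  colnames(betaOrig) <- colnames(x)
  intercepts <- meany - as.numeric(betaOrig %*% meanx)
  structure(list(beta = betaOrig, intercepts = intercepts,
                 l1 = rowSums(abs(betaOrig)), actions = actions,
                 meanx = meanx, meany = meany, normx = normx),
            class = "larsPath")
}

#' @export
print.larsPath <- function(x, ...) {
  cat("LARS-lasso path:", nrow(x$beta) - 1L, "steps,",
      ncol(x$beta), "predictors, max |beta|_1 =",
      signif(max(x$l1), 4L), "\n")
  invisible(x)
}

# Interpolate coefficients at path fraction(s) s = |beta|_1 / max|beta|_1.
.larsCoefAt <- function(fit, s) {
  stopifnot(all(s >= 0 & s <= 1))
  B <- fit$beta
  l1 <- fit$l1
  if (max(l1) == 0) {
    out <- matrix(0, length(s), ncol(B), dimnames = list(NULL, colnames(B)))
    return(list(beta = out, intercept = rep(fit$meany, length(s))))
  }
  target <- s * max(l1)
  l1m <- cummax(l1)                       # guard against tiny numeric dips
  idx <- vapply(target, function(t) max(which(l1m <= t + 1e-12)), 0L)
  frac <- numeric(length(s))
  for (i in seq_along(s)) {
    k <- idx[i]
    if (k < length(l1m) && l1m[k + 1L] > l1m[k])
      frac[i] <- (target[i] - l1m[k]) / (l1m[k + 1L] - l1m[k])
  }
  beta <- B[idx, , drop = FALSE] * (1 - frac) +
    B[pmin(idx + 1L, nrow(B)), , drop = FALSE] * frac
  intercept <- fit$intercepts[idx] * (1 - frac) +
    fit$intercepts[pmin(idx + 1L, nrow(B))] * frac
  list(beta = beta, intercept = intercept)
}

#' Predict from a LARS-lasso path at given path fractions
#'
#' Evaluates the path at one or more fractions
#' \eqn{s = |\beta|_1 / \max |\beta|_1} of the final L1 norm
#' (`s = 0` the empty model, `s = 1` the least-penalized end), linearly
#' interpolating coefficients between path knots.
#'
#' @param fit a [larsPath()] object.
#' @param newx matrix of samples (rows) to predict.
#' @param s numeric vector of fractions in `[0, 1]`.
#' @return A list with `fit` (matrix, `nrow(newx)` rows, one column per
#'   `s`) and `coefficients` (one row per `s`, original scale).
#' @export
predictLarsPath <- function(fit, newx, s) {
  stopifnot(inherits(fit, "larsPath"))
  if (any(s < 0 | s > 1))
    stop("path fraction s must lie in [0, 1]", call. = FALSE)
  newx <- as.matrix(newx)
  cf <- .larsCoefAt(fit, s)
  pred <- sweep(newx %*% t(cf$beta), 2L, cf$intercept, "+")
  colnames(pred) <- as.character(s)
  list(fit = pred, coefficients = cf$beta, intercept = cf$intercept)
}
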