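#' LMS (lambda-mu-sigma) percentile machinery
#'
#' Growth-reference distributions are summarised by three age- and
#' sex-specific parameters: a Box-Cox skewness power \code{L}, a median
#' \code{M} and a coefficient of variation \code{S}. A standard deviation
#' score (SDS, z-score) locates an individual on the reference; the
#' functions below convert between SDS and measurement value, extrapolate
#' tabulated percentile curves over age with a cubic polynomial, and fit
#' LMS triplets back from tabulated percentiles.
#'
#' @name lms
NULL

#' Convert an SDS (z-score) to a measurement value under an LMS reference
#'
#' Implements the standard LMS quantile function
#' \deqn{x = M (1 + L S z)^{1/L}} for \eqn{L \neq 0} and
#' \deqn{x = M \exp(S z)} for \eqn{L = 0}.
#'
#' @param L skewness power (dimensionless); may be 0.
#' @param M median, in the units of the measure; must be positive.
#' @param S coefficient of variation (dimensionless); must be positive.
#' @param z SDS value(s). Vectorised over all arguments.
#' @return measurement value(s) in the units of \code{M}.
#' @export
#' @examples
#' lms_value(1, 100, 0.1, 2) # 120
lms_value <- function(L, M, S, z) {
  stopifnot(all(S > 0), all(M > 0))
  n <- max(length(L), length(M), length(S), length(z))
  L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  z <- rep_len(z, n)
  out <- numeric(n)
  zero <- abs(L) < .Machine$double.eps
  if (any(!zero)) {
    base <- 1 + L[!zero] * S[!zero] * z[!zero]
    if (any(base <= 0)) {
      bad <- z[!zero][base <= 0]
      stop("SDS value(s) outside the LMS domain (1 + L*S*z <= 0): z = ",
           paste(signif(utils::head(bad, 5), 6), collapse = ", "))
    }
    # log1p keeps the general branch accurate and continuous as L -> 0
    out[!zero] <- M[!zero] * exp(log1p(L[!zero] * S[!zero] * z[!zero]) / L[!zero])
  }
  if (any(zero)) out[zero] <- M[zero] * exp(S[zero] * z[zero])
  out
}

#' Convert a measurement value to its SDS under an LMS reference
#'
#' Inverse of [lms_value()]: \eqn{z = ((x/M)^L - 1)/(L S)} for
#' \eqn{L \neq 0}, \eqn{z = \log(x/M)/S} for \eqn{L = 0}.
#'
#' @inheritParams lms_value
#' @param x measurement value(s); must be positive.
#' @return SDS value(s).
#' @export
lms_sds <- function(L, M, S, x) {
  stopifnot(all(S > 0), all(M > 0))
  if (any(x <= 0)) stop("measurement values must be positive")
  n <- max(length(L), length(M), length(S), length(x))
  L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  x <- rep_len(x, n)
  out <- numeric(n)
  zero <- abs(L) < .Machine$double.eps
  out[!zero] <- ((x[!zero] / M[!zero])^L[!zero] - 1) / (L[!zero] * S[!zero])
  out[zero] <- log(x[zero] / M[zero]) / S[zero]
  out
}

#' Standard-normal quantile of a percentile label
#'
#' Maps labels such as \code{"P3"}, \code{"P50"}, \code{"P97"} to the
#' corresponding standard-normal score (P3 -> -1.8808, P50 -> 0, ...).
#'
#' @param labels character vector of percentile labels (\code{"P<q>"} with
#'   \code{0 < q < 100}; decimal points allowed, e.g. \code{"P99.5"}).
#' @return numeric vector of z-scores.
#' @export
percentile_z <- function(labels) {
  q <- suppressWarnings(as.numeric(sub("^[Pp]", "", labels)))
  if (any(is.na(q)) || any(q <= 0) || any(q >= 100))
    stop("percentile labels must be of the form 'P<q>' with 0 < q < 100")
  stats::qnorm(q / 100)
}

#' Extrapolate percentile curves over age with a cubic polynomial
#'
#' Each percentile series is least-squares fitted with a degree-3 polynomial
#' in age and evaluated on \code{target_ages}. Used both to smooth
#' references tabulated in 5-year age groups into annual values and to
#' extend references that stop before the simulation's age cap. After
#' evaluation the cross-percentile ordering is re-checked; crossings are an
#' error, never silently clamped.
#'
#' @param curve data.frame with an \code{age} column and one column per
#'   percentile label (e.g. \code{P3}, \code{P10}, \code{P50}, \code{P90},
#'   \code{P97}); at least 4 distinct ages.
#' @param target_ages numeric vector of ages at which to evaluate.
#' @return data.frame of the same shape evaluated at \code{target_ages}.
#' @export
extrapolate_poly3 <- function(curve, target_ages) {
  stopifnot(is.data.frame(curve), "age" %in% names(curve))
  pcols <- setdiff(names(curve), "age")
  if (length(unique(curve$age)) < 4)
    stop("need at least 4 distinct ages to fit a cubic")
  out <- data.frame(age = target_ages)
  for (pc in pcols) {
    fit <- stats::lm(curve[[pc]] ~ stats::poly(curve$age, 3, raw = TRUE))
    out[[pc]] <- drop(cbind(1, target_ages, target_ages^2, target_ages^3) %*%
                        stats::coef(fit))
  }
  if (length(pcols) > 1) {
    vals <- as.matrix(out[pcols])
    ok <- apply(vals, 1, function(v) all(diff(v) > 0))
    if (!all(ok))
      stop("percentile curves cross after extrapolation at age(s): ",
           paste(out$age[!ok], collapse = ", "))
  }
  out
}

#' Fit an LMS triplet from tabulated percentiles at one age
#'
#' Finds (L, M, S) minimising the squared error between the LMS quantile
#' function evaluated at the standard-normal scores of the labels and the
#' tabulated values. With exactly three percentile points the fit is exact
#' up to solver tolerance.
#'
#' @param values numeric vector of percentile values, strictly increasing.
#' @param labels percentile labels matching \code{values} (see
#'   [percentile_z()]), or a numeric vector of z-scores.
#' @return named numeric vector \code{c(L =, M =, S =)}.
#' @export
fit_lms <- function(values, labels) {
  z <- if (is.numeric(labels)) labels else percentile_z(labels)
  if (length(values) < 3) stop("need at least 3 percentile points")
  if (any(diff(order(z)) < 0)) { o <- order(z); z <- z[o]; values <- values[o] }
  if (any(diff(values) <= 0))
    stop("percentile values must be strictly increasing across percentiles")
  if (any(values <= 0)) stop("percentile values must be positive")

  # start from the normal approximation: M at z=0, S from the spread
  m0 <- if (any(z == 0)) values[z == 0][1] else stats::approx(z, values, 0)$y
  s0 <- (values[length(values)] - values[1]) /
    (m0 * (z[length(z)] - z[1]))
  s0 <- max(s0, 1e-4)
  obj <- function(par) {
    L <- par[1]; M <- exp(par[2]); S <- exp(par[3])
    base <- 1 + L * S * z
    if (any(base <= 0)) return(1e12)
    pred <- if (abs(L) < 1e-12) M * exp(S * z) else M * exp(log1p(L * S * z) / L)
    sum((pred - values)^2)
  }
  best <- NULL
  for (L0 in c(1, 0.01, -0.5, -1.5)) {
    fit <- stats::optim(c(L0, log(m0), log(s0)), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # simplex polish: BFGS stalls ~1e-9 SSE, the exact fit is far below that
  for (i in 1:3)
    best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 5000))
  if (best$value > 1e-6 * sum(values^2) && best$convergence != 0)
    stop("LMS fit did not converge; residual SSE = ", signif(best$value, 4))
  c(L = best$par[1], M = exp(best$par[2]), S = exp(best$par[3]))
}

#' Fit LMS triplets for every age of a percentile table
#'
#' @param curve data.frame as in [extrapolate_poly3()].
#' @return data.frame with columns \code{age, L, M, S}.
#' @export
fit_lms_table <- function(curve) {
  pcols <- setdiff(names(curve), "age")
  z <- percentile_z(pcols)
  res <- t(vapply(seq_len(nrow(curve)), function(i) {
    fit_lms(as.numeric(curve[i, pcols]), z)
  }, numeric(3)))
  data.frame(age = curve$age, L = res[, 1], M = res[, 2], S = res[, 3])
}

# Linear interpolation of L, M, S in age; ages beyond the grid take the
# boundary row (tables cover the full simulated range after preparation).
lms_interp <- function(lms_table, age) {
  a <- pmin(pmax(age, min(lms_table$age)), max(lms_table$age))
  list(
    L = stats::approx(lms_table$age, lms_table$L, a, rule = 2)$y,
    M = stats::approx(lms_table$age, lms_table$M, a, rule = 2)$y,
    S = stats::approx(lms_table$age, lms_table$S, a, rule = 2)$y
  )
}
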