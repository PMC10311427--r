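#' @keywords internal
"_PACKAGE"

# Centralized unit conversions: ages are stored in decimal postnatal weeks,
# parenteral nutrition duration in integer days.
DAYS_PER_WEEK <- 7

#' Convert days to decimal weeks
#' @param days numeric vector of days.
#' @return numeric vector of weeks.
#' @export
days_to_weeks <- function(days) days / DAYS_PER_WEEK

#' Convert decimal weeks to days
#' @param weeks numeric vector of weeks.
#' @return numeric vector of days.
#' @export
weeks_to_days <- function(weeks) weeks * DAYS_PER_WEEK

# follow-up horizon (weeks) over which the treatment hazard is integrated
DIGIROP_HORIZON <- 20

# stage labels of the sequential decision tool
tool_stages <- function() c("prescreen", paste0("week", 6:14))

# short deterministic fingerprint of a numeric vector; used to stamp fits and
# cutoff tables so that apply_tool() can detect mismatched training runs
fingerprint <- function(x) {
  s <- paste(format(unlist(x), digits = 12, scientific = TRUE), collapse = ",")
  # simple polynomial rolling hash modulo a Mersenne prime
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# ridge-penalized IRLS for binomial/poisson glms; fallback when the ML fit
# separates. Penalty is not applied to the intercept.
ridge_glm <- function(X, y, offset = NULL, family = c("binomial", "poisson"),
                      lambda = 1e-3, maxit = 100, tol = 1e-10) {
  family <- match.arg(family)
  n <- nrow(X); p <- ncol(X)
  if (is.null(offset)) offset <- rep(0, n)
  pen <- diag(p) * lambda
  if (colnames(X)[1] == "(Intercept)") pen[1, 1] <- 0
  beta <- rep(0, p)
  linkinv <- if (family == "binomial") stats::plogis else exp
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- linkinv(eta)
    w <- if (family == "binomial") mu * (1 - mu) else mu
    w <- pmax(w, 1e-10)
    z <- eta - offset + (y - mu) / w
    XtW <- t(X * w)
    new_beta <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- drop(new_beta)
      break
    }
    beta <- drop(new_beta)
  }
  eta <- drop(X %*% beta) + offset
  mu <- linkinv(eta)
  w <- if (family == "binomial") mu * (1 - mu) else mu
  cov <- solve(t(X * pmax(w, 1e-10)) %*% X + pen)
  list(coefficients = stats::setNames(beta, colnames(X)), vcov = cov,
       fitted = mu, penalized = TRUE, lambda = lambda)
}
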