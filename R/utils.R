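# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used throughout the table reports: one decimal by
#' default, ties rounded away from zero (so 76.75 -> 76.8), matching the
#' convention of the published tables rather than banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Linear predictor from a named coefficient vector and a design matrix.
# Coefficient names must be a subset of colnames(X); validated at config
# construction time.
lp_from <- function(coefs, X) {
  if (is.null(coefs) || length(coefs) == 0L) return(rep(0, nrow(X)))
  drop(X[, names(coefs), drop = FALSE] %*% coefs)
}

# Least squares via pivoted QR.  Exactly collinear (aliased) columns are
# dropped lm-style: their coefficients are set to 0, so X %*% coef is the
# unique projection onto the fitted column space.
fast_lm <- function(X, y) {
  qx <- qr(X)
  cf <- qr.coef(qx, y)
  aliased <- is.na(cf)
  cf[aliased] <- 0
  res <- y - drop(X %*% cf)
  dfres <- length(y) - qx$rank
  sigma <- if (dfres > 0) sqrt(sum(res^2) / dfres) else 0
  list(coef = cf, sigma = sigma, rank = qx$rank, aliased = aliased)
}

# Generic dummy expansion for a confounder data frame: characters and
# factors become treatment-coded indicators, logicals 0/1, numerics pass
# through.  Returns a matrix with zero columns when `df` has none.
design_matrix <- function(df) {
  if (is.null(df) || ncol(df) == 0L) {
    return(matrix(numeric(0), nrow = if (is.null(df)) 0L else nrow(df),
                  ncol = 0L))
  }
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    if (is.logical(df[[nm]])) df[[nm]] <- as.numeric(df[[nm]])
  }
  mm <- model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

is_binary01 <- function(x) {
  u <- unique(x[!is.na(x)])
  all(u %in% c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}
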