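#' Fit a per-feature scaler on a training matrix
#'
#' Scaling statistics are always fit on training rows only and stored so that
#' validation/test data (and later, repurposing inputs) are transformed with
#' the training statistics, never their own.
#'
#' @param x numeric matrix, rows = samples, columns = features.
#' @param method `"minmax"` maps each feature to \[0, 1\] using the training
#'   min/max; `"zscore"` centers and scales by the training mean/sd;
#'   `"none"` is the identity.
#' @return A `feature_scaler` object.
#' @export
fit_scaler <- function(x, method = c("minmax", "zscore", "none")) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), is.numeric(x))
  sc <- switch(method,
    none = list(method = "none", dim = ncol(x)),
    minmax = {
      lo <- apply(x, 2L, min)
      hi <- apply(x, 2L, max)
      rng <- hi - lo
      rng[rng == 0] <- 1 # constant features map to 0, not NaN
      list(method = "minmax", dim = ncol(x), offset = lo, scale = rng)
    },
    zscore = {
      mu <- colMeans(x)
      sd <- apply(x, 2L, stats::sd)
      sd[sd == 0 | is.na(sd)] <- 1
      list(method = "zscore", dim = ncol(x), offset = mu, scale = sd)
    }
  )
  structure(sc, class = "feature_scaler")
}

#' Apply a fitted scaler to a matrix
#'
#' @param scaler a `feature_scaler` from [fit_scaler()].
#' @param x numeric matrix with the same number of columns the scaler was
#'   fit on.
#' @return The transformed matrix. Values outside the training range are not
#'   clipped (min-max outputs may fall outside \[0, 1\] on unseen data).
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"), is.matrix(x))
  if (scaler$method == "none") {
    return(x)
  }
  if (ncol(x) != scaler$dim) {
    stop("scaler was fit on ", scaler$dim, " features but input has ", ncol(x))
  }
  n <- nrow(x)
  off <- rep(scaler$offset, each = n)
  scl <- rep(scaler$scale, each = n)
  (x - off) / scl
}
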