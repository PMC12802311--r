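#' Specify a bounded sampling distribution
#'
#' Scene configurations describe cell length, width, sinuosity and debris
#' size as small distribution specifications. Normal and log-normal
#' specifications are truncated exactly (inverse-CDF on the restricted
#' support), so samples always respect the stated bounds.
#'
#' @param kind one of `"fixed"`, `"uniform"`, `"normal"`, `"lognormal"`.
#' @param value constant for `kind = "fixed"`.
#' @param min,max support bounds. Required for `"uniform"`; optional
#'   truncation bounds for the other kinds.
#' @param mean,sd parameters for `"normal"`.
#' @param meanlog,sdlog parameters for `"lognormal"`.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("uniform", min = 0.2, max = 1)
#' dist_spec("normal", mean = 2.5, sd = 0.7, min = 1.05, max = 4)
#' @export
dist_spec <- function(kind = c("fixed", "uniform", "normal", "lognormal"),
                      value = NULL, min = -Inf, max = Inf,
                      mean = NULL, sd = NULL, meanlog = NULL, sdlog = NULL) {
  kind <- match.arg(kind)
  if (min >= max && kind != "fixed")
    abort("dist_spec: min (%g) must be < max (%g)", min, max)
  spec <- switch(kind,
    fixed = {
      if (is.null(value)) abort("dist_spec: 'fixed' needs a value")
      list(kind = kind, value = value)
    },
    uniform = {
      if (!is.finite(min) || !is.finite(max))
        abort("dist_spec: 'uniform' needs finite min and max")
      list(kind = kind, min = min, max = max)
    },
    normal = {
      if (is.null(mean) || is.null(sd))
        abort("dist_spec: 'normal' needs mean and sd")
      list(kind = kind, mean = mean, sd = sd, min = min, max = max)
    },
    lognormal = {
      if (is.null(meanlog) || is.null(sdlog))
        abort("dist_spec: 'lognormal' needs meanlog and sdlog")
      list(kind = kind, meanlog = meanlog, sdlog = sdlog,
           min = min, max = max)
    })
  structure(spec, class = "dist_spec")
}

#' Draw samples from a `dist_spec`
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n`, inside the spec's support.
#' @export
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"), is_count(n))
  if (n == 0) return(numeric(0))
  switch(spec$kind,
    fixed = rep(spec$value, n),
    uniform = stats::runif(n, spec$min, spec$max),
    normal = {
      pa <- stats::pnorm(spec$min, spec$mean, spec$sd)
      pb <- stats::pnorm(spec$max, spec$mean, spec$sd)
      stats::qnorm(stats::runif(n, pa, pb), spec$mean, spec$sd)
    },
    lognormal = {
      lo <- if (spec$min > 0) log(spec$min) else -Inf
      hi <- if (is.finite(spec$max)) log(spec$max) else Inf
      pa <- stats::pnorm(lo, spec$meanlog, spec$sdlog)
      pb <- stats::pnorm(hi, spec$meanlog, spec$sdlog)
      exp(stats::qnorm(stats::runif(n, pa, pb), spec$meanlog, spec$sdlog))
    })
}

#' Support bounds of a `dist_spec`
#' @noRd
dist_support <- function(spec) {
  switch(spec$kind,
    fixed = c(spec$value, spec$value),
    uniform = c(spec$min, spec$max),
    c(spec$min, spec$max))
}
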