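#' Model families
#'
#' Families understood throughout the package:
#' * `"glogit_free"` — generalized logistic link with per-item shape
#'   parameters (lambda1, lambda2), both estimated;
#' * `"rasch"`, `"pno_glogit"`, `"cllm_glogit"` — generalized logistic link
#'   with the shapes fixed at the constants of [fixed_shape_constants()]
#'   (logit, probit-like, cloglog-like);
#' * `"pno_exact"`, `"cllm_exact"` — the exact normal-ogive and
#'   complementary log-log one-parameter models (the fixed-shape glogit
#'   variants approximate these only up to an affine rescaling of
#'   `theta - beta`, so both forms are exposed);
#' * `"threepl"`, `"fourpl"` — logistic models with discrimination `alpha`,
#'   guessing floor `c` and (for the 4PL) slipping ceiling `d`.
#'
#' @return character vector of family names.
#' @export
girt_families <- function() {
  c("glogit_free", "rasch", "pno_glogit", "cllm_glogit",
    "pno_exact", "cllm_exact", "threepl", "fourpl")
}

#' Resolve a family's fixed shape parameters
#'
#' Internal-facing helper: returns the (lambda1, lambda2) constants for the
#' fixed-shape generalized-logit families and `NULL` for families without
#' fixed shapes.
#' @param family a family name from [girt_families()].
#' @param fixed_shape optional numeric length-2 override for the fixed-shape
#'   glogit families.
#' @return named numeric vector or `NULL`.
#' @export
resolve_shape <- function(family, fixed_shape = NULL) {
  family <- match.arg(family, girt_families())
  if (family %in% c("rasch", "pno_glogit", "cllm_glogit")) {
    if (is.null(fixed_shape)) return(fixed_shape_constants(family))
    stopifnot(length(fixed_shape) == 2)
    check_shape(fixed_shape[1], fixed_shape[2])
    return(c(lambda1 = fixed_shape[1], lambda2 = fixed_shape[2]))
  }
  if (!is.null(fixed_shape))
    stop("'fixed_shape' is only meaningful for the fixed-shape glogit families")
  NULL
}

#' Item parameter set
#'
#' Validating constructor for one item's parameters.  All families share
#' the difficulty `beta`; the generalized-logit families use the shapes
#' `(lambda1, lambda2)`; the 3PL/4PL use discrimination `alpha`, lower
#' asymptote `c` (guessing) and upper asymptote `d` (1 - slipping; `d = 1`
#' for the 3PL).
#'
#' @param beta item difficulty (latent-trait units).
#' @param lambda1,lambda2 shape parameters, each > -1.
#' @param alpha discrimination, > 0.
#' @param c lower asymptote in `[0, 1)`.
#' @param d upper asymptote in `(c, 1]`.
#' @return a list of class `"girt_item"`.
#' @export
item_params <- function(beta, lambda1 = 0, lambda2 = lambda1,
                        alpha = 1, c = 0, d = 1) {
  stopifnot(is.finite(beta), is.finite(alpha), is.finite(c), is.finite(d))
  check_shape(lambda1, lambda2)
  if (alpha <= 0) stop("'alpha' must be positive")
  if (c < 0 || c >= 1) stop("'c' must lie in [0, 1)")
  if (d <= c || d > 1) stop("'d' must lie in (c, 1]")
  structure(list(beta = beta, lambda1 = lambda1, lambda2 = lambda2,
                 alpha = alpha, c = c, d = d),
            class = "girt_item")
}

#' Item characteristic curve
#'
#' Probability of a correct response as a function of ability `theta` for a
#' single item, under any supported family.  For the generalized-logit
#' families this is `plogis(h_lambda(theta - beta))`, computed
#' overflow-safely; for `"pno_exact"` it is `pnorm(theta - beta)`; for
#' `"cllm_exact"` it is `1 - exp(-exp(theta - beta))`; for the 3PL/4PL it
#' is `c + (d - c) * plogis(alpha * (theta - beta))`.  Only the difference
#' `theta - beta` enters, so the curve is invariant to a common shift of
#' ability and difficulty.
#'
#' @param family a family name from [girt_families()].
#' @param theta numeric vector of abilities.
#' @param item an [item_params()] object (or a plain list with the same
#'   fields).
#' @return numeric vector of probabilities in `(0, 1)` (bounded by `c`/`d`
#'   for the 3PL/4PL).
#' @examples
#' icc("rasch", 0.7, item_params(beta = 0))        # plogis(0.7)
#' icc("glogit_free", 4, item_params(0, -1, 0))    # 5/6
#' @export
icc <- function(family, theta, item) {
  family <- match.arg(family, girt_families())
  if (!is.list(item)) stop("'item' must be an item_params() list")
  it <- validate_item(family, item)
  eta <- theta - it$beta
  switch(family,
    pno_exact = stats::pnorm(eta),
    cllm_exact = -expm1(-exp(pmin(eta, 700))),
    threepl = ,
    fourpl = it$c + (it$d - it$c) * stats::plogis(it$alpha * eta),
    { # all generalized-logit variants
      sh <- glogit_shape_for(family, it)
      stats::plogis(pmin(pmax(h_lambda(eta, sh[1], sh[2]), -700), 700))
    })
}

glogit_shape_for <- function(family, it) {
  if (family == "glogit_free")
    c(it$lambda1, it$lambda2)
  else
    fixed_shape_constants(family)
}

validate_item <- function(family, item) {
  need <- function(f) if (is.null(item[[f]]))
    stop("item parameters lack '", f, "' required by family '", family, "'")
  need("beta")
  if (is.null(item$alpha)) item$alpha <- 1
  if (is.null(item$c)) item$c <- 0
  if (is.null(item$d)) item$d <- 1
  if (is.null(item$lambda1)) item$lambda1 <- 0
  if (is.null(item$lambda2)) item$lambda2 <- 0
  if (family == "glogit_free") check_shape(item$lambda1, item$lambda2)
  if (family %in% c("threepl", "fourpl")) {
    if (item$alpha <= 0) stop("'alpha' must be positive for ", family)
    if (item$c < 0 || item$c >= 1) stop("'c' outside [0, 1) for ", family)
    if (family == "threepl" && item$d != 1)
      stop("the 3PL fixes the upper asymptote at d = 1; got d = ", item$d)
    if (item$d <= item$c || item$d > 1) stop("need c < d <= 1 for ", family)
  }
  item
}
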