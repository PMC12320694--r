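# Circumference-based limb volumetry. The lower extremity lymphedema index
# (LELI) normalizes a squared-circumference volume surrogate by BMI so limbs
# can be compared across patients of different builds.

#' Lower extremity lymphedema index (LELI)
#'
#' Sum of squared limb circumferences at the five predefined measurement sites
#' (superior edge of the patella, 10 cm above and 10 cm below the patella, the
#' lateral malleolus, and the dorsum of the foot), divided by BMI.
#'
#' @param circumferences Circumferences in cm: a length-5 numeric vector for a
#'   single limb, or an n x 5 matrix/data frame (one limb per row).
#' @param bmi Body mass index in kg/m^2 (scalar or length n).
#' @return Dimensionless LELI value(s).
#' @examples
#' leli(rep(10, 5), bmi = 25)  # 500 / 25 = 20
#' @export
leli <- function(circumferences, bmi) {
  if (is.data.frame(circumferences)) circumferences <- as.matrix(circumferences)
  if (!is.matrix(circumferences)) {
    circumferences <- matrix(circumferences, nrow = 1)
  }
  if (ncol(circumferences) != 5) {
    stop("circumferences must have 5 sites per limb", call. = FALSE)
  }
  if (any(!is.finite(circumferences)) || any(circumferences <= 0)) {
    stop("circumferences must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("bmi must be positive and finite", call. = FALSE)
  }
  as.numeric(rowSums(circumferences^2) / bmi)
}

#' Postoperative percentage change in LELI
#'
#' `100 * (pre - post) / pre`: positive values are volume reductions, negative
#' values increases, matching the clinical convention that a successful
#' anastomosis reduces the index.
#'
#' @param pre,post LELI before and after surgery (vectorized; both > 0).
#' @return Percentage change(s).
#' @examples
#' pct_delta_leli(250, 225)  # 10% reduction
#' @export
pct_delta_leli <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0)) {
    stop("pre-operative LELI must be positive", call. = FALSE)
  }
  if (any(!is.finite(post)) || any(post <= 0)) {
    stop("post-operative LELI must be positive", call. = FALSE)
  }
  100 * (pre - post) / pre
}

#' Affected-versus-contralateral LELI excess
#'
#' Volume difference between the affected and the unaffected contralateral
#' limb, as a plain difference of LELI values.
#'
#' @param affected,contralateral LELI values (> 0), vectorized.
#' @return `affected - contralateral`.
#' @export
leli_excess <- function(affected, contralateral) {
  if (any(!is.finite(affected)) || any(affected <= 0) ||
      any(!is.finite(contralateral)) || any(contralateral <= 0)) {
    stop("LELI values must be positive", call. = FALSE)
  }
  affected - contralateral
}
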