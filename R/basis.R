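#' Natural cubic spline basis for the lag weight function
#'
#' Evaluates a K-dimensional natural cubic spline basis (including the
#' constant direction) over the gestational week grid 1..T, with interior
#' knots evenly spaced over the grid. The unit-norm weight function of the
#' distributed lag model lives in the span of these columns, which smooths
#' the weekly weights and reduces the effective dimension from T to K.
#'
#' @param T Number of gestational weeks.
#' @param K Basis dimension (number of columns), `2 <= K < T`.
#' @return A `T x K` matrix of full column rank with attributes `knots` and
#'   `Boundary.knots`.
#' @export
build_weight_basis <- function(T, K) {
  assert_spec(is.numeric(T) && T >= 3 && T == round(T), "T must be an integer >= 3")
  if (!(is.numeric(K) && K == round(K) && K >= 2)) {
    stop_bdlimwin("bdlimwin_invalid_spec", "K must be an integer >= 2")
  }
  if (K >= T) {
    stop_bdlimwin("bdlimwin_identifiability_error",
                  "basis dimension K must be smaller than T")
  }
  B <- splines::ns(seq_len(T), df = K, intercept = TRUE)
  knots <- attr(B, "knots"); bknots <- attr(B, "Boundary.knots")
  B <- matrix(as.numeric(B), nrow = T, ncol = K)
  if (qr(B)$rank < K) {
    stop_bdlimwin("bdlimwin_identifiability_error",
                  "weight basis is rank deficient")
  }
  attr(B, "knots") <- knots
  attr(B, "Boundary.knots") <- bknots
  B
}
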