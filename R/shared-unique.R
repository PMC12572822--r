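#' Shared vs unique trait variance across two feature sets
#'
#' Fits the morphometricity model three times — kernel A1 alone, kernel A2
#' alone, and the joint two-kernel model — to ask whether two gray-matter
#' representations capture the same trait variance or complementary parts of
#' it. The joint m2 is the total non-residual variance fraction; the rate of
#' increase `m2_joint / m2_k` is 1 when the added kernel brings nothing and
#' approaches 2 when each kernel explains a disjoint half.
#'
#' @param y trait vector.
#' @param A1,A2 `"mrm"` kernels on the same samples.
#' @param C covariate design (or `NULL`).
#' @return A list with the three fits, `m2_1`, `m2_2`, `m2_joint`,
#'   `increase_ratio_1`, `increase_ratio_2` and a `flagged` indicator set when
#'   any sub-fit failed to converge.
#' @export
shared_unique <- function(y, A1, A2, C = NULL) {
  fit1 <- morpho(y, A1, C, store_kernels = FALSE)
  fit2 <- morpho(y, A2, C, store_kernels = FALSE)
  joint <- morpho(y, list(A1, A2), C, store_kernels = FALSE)
  m2_joint <- sum(joint$m2)
  list(fit1 = fit1, fit2 = fit2, joint = joint,
       m2_1 = unname(fit1$m2), m2_2 = unname(fit2$m2), m2_joint = m2_joint,
       increase_ratio_1 = m2_joint / unname(fit1$m2),
       increase_ratio_2 = m2_joint / unname(fit2$m2),
       flagged = !(fit1$converged && fit2$converged && joint$converged))
}
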