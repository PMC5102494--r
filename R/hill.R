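# Hemoglobin oxygen binding (Hill model) and the effective convective
# capacity of the RBC suspension.

#' Hemoglobin oxygen saturation (Hill equation)
#'
#' Fraction of heme sites bound at a given oxygen partial pressure,
#' \deqn{SO_2 = \frac{PO_2^N}{P_{50}^N + PO_2^N}.}
#'
#' @param po2 Oxygen partial pressure (mmHg), non-negative; vectorized.
#' @param p50 Half-saturation pressure (mmHg). Default 37 (human RBCs).
#' @param n Hill cooperativity coefficient. Default 2.7.
#' @return Saturation fraction in \[0, 1).
#' @examples
#' hill_saturation(37)        # 0.5 at P50
#' hill_saturation(160)       # arterial-like, ~0.98
#' @export
hill_saturation <- function(po2, p50 = 37, n = 2.7) {
  stopifnot(p50 > 0, n > 0)
  if (any(po2 < 0)) stop("po2 must be non-negative")
  # (po2/p50)^n form avoids overflow for large po2^n
  r <- (po2 / p50)^n
  r / (1 + r)
}

#' Slope of the hemoglobin binding curve
#'
#' Analytic derivative dSO2/dPO2 of [hill_saturation()], in 1/mmHg.
#' At the half-saturation point the slope equals N/(4 P50).
#'
#' @inheritParams hill_saturation
#' @return Derivative of saturation with respect to PO2 (1/mmHg).
#' @export
hill_slope <- function(po2, p50 = 37, n = 2.7) {
  stopifnot(p50 > 0, n > 0)
  if (any(po2 < 0)) stop("po2 must be non-negative")
  out <- numeric(length(po2))
  pos <- po2 > 0
  r <- (po2[pos] / p50)^n
  out[pos] <- n * r / (po2[pos] * (1 + r)^2)
  if (any(!pos)) out[!pos] <- if (n > 1) 0 else if (n == 1) 1 / p50 else Inf
  out
}

#' Effective convective oxygen capacity of the RBC suspension
#'
#' Capacity coefficient multiplying the advection term in the blood region:
#' free oxygen dissolved in plasma and inside RBCs plus the hemoglobin-bound
#' reservoir, the total heme concentration of the suspension times the local
#' slope of the binding curve,
#' \deqn{\beta(PO_2) = (1-Ht)\,k_p + Ht\,k_{rbc} + [Hb_T]\,dSO_2/dPO_2.}
#' `HbT` is the heme concentration of the blood as delivered (not scaled by
#' hematocrit), so the hemoglobin reservoir — which dominates the capacity
#' in the mid-pressure range — is insensitive to the hematocrit parameter,
#' and hematocrit enters only through the small solubility difference
#' between plasma and RBC interior. Setting `HbT = 0` disables the binding
#' reservoir entirely (a plasma-only fluid).
#'
#' @param po2 Oxygen partial pressure (mmHg); vectorized.
#' @param phys A [physical_parameters()] object.
#' @return Capacity in uM/mmHg.
#' @export
effective_capacity <- function(po2, phys) {
  (1 - phys$Ht) * phys$k_plasma + phys$Ht * phys$k_rbc +
    phys$HbT * hill_slope(po2, phys$P50, phys$N_hill)
}
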