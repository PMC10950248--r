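#' Construct a GLIF3 parameter set
#'
#' @param C membrane capacitance (pF).
#' @param g membrane conductance (nS).
#' @param EL resting potential (mV).
#' @param vth spike threshold (mV).
#' @param vr reset potential (mV).
#' @param deltaR refractory period (ms), within \[2, 8\].
#' @param k1,k2 decay rates of the fast and slow after-spike currents
#'   (1/ms).
#' @param A1,A2 after-spike additive constants (pA); negative values give
#'   spike-frequency adaptation.
#' @param R1,R2 after-spike reset multipliers (dimensionless, typically 1).
#' @return A [GLIFParams-class] object.
#' @examples
#' p <- GLIFParams(C = 100, g = 10, EL = -70, vth = -60)
#' membraneTau(p) # 10 ms
#' @export
GLIFParams <- function(C = 100, g = 5, EL = -70, vth = -45, vr = -70,
                       deltaR = 2, k1 = 0.03, k2 = 0.003, A1 = 0, A2 = 0,
                       R1 = 1, R2 = 1) {
  obj <- new("GLIFParams") # slot name "C" would partially match Class
  obj@C <- C
  obj@g <- g
  obj@EL <- EL
  obj@vth <- vth
  obj@vr <- vr
  obj@deltaR <- deltaR
  obj@k <- c(k1, k2)
  obj@A <- c(A1, A2)
  obj@R <- c(R1, R2)
  validObject(obj)
  obj
}

#' Membrane time constant of a GLIF parameter set
#'
#' @param params a [GLIFParams-class] object.
#' @return tau = C/g in ms.
#' @export
membraneTau <- function(params) {
  stopifnot(is(params, "GLIFParams"))
  params@C / params@g
}

setMethod("show", "GLIFParams", function(object) {
  cat(sprintf(
    "GLIFParams: C=%g pF, g=%g nS (tau=%.2f ms), EL=%g, vth=%g, vr=%g mV\n",
    object@C, object@g, membraneTau(object), object@EL, object@vth,
    object@vr
  ))
  cat(sprintf(
    "  refractory %g ms; ASC k=(%g, %g)/ms, A=(%g, %g) pA, R=(%g, %g)\n",
    object@deltaR, object@k[1], object@k[2], object@A[1], object@A[2],
    object@R[1], object@R[2]
  ))
  invisible(NULL)
})
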