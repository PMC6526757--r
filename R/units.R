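# Unit registry: external interface is mmHg / mL / s / mm, internal physics SI.
.PA_PER_MMHG <- 133.322
.M_PER_MM <- 1e-3
.M3_PER_ML <- 1e-6
# Pa.s/m^3 -> mmHg.s/mL
.R_SI_TO_MMHG_ML <- 1 / (.PA_PER_MMHG / .M3_PER_ML)

#' Convert wall shear stress from Pa to dyn/cm^2
#'
#' @param wss_pa Wall shear stress in pascal.
#' @return The same stress in dyn/cm^2 (1 Pa = 10 dyn/cm^2).
#' @export
pa_to_dyn_cm2 <- function(wss_pa) wss_pa * 10

# Run an expression under a fixed seed without disturbing the caller's RNG
# stream; generators must be pure functions of their parameters.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
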