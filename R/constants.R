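# Unit system: nm, ps, amu, e, K, kJ/mol. Pressure in bar, field in V/nm.

#' Physical constants of the md unit system
#'
#' Returns the conversion factors used throughout the package:
#' \describe{
#'   \item{f_elec}{Coulomb prefactor \eqn{1/(4\pi\epsilon_0)}, kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}}
#'   \item{k_B}{Boltzmann constant, kJ mol\eqn{^{-1}} K\eqn{^{-1}}}
#'   \item{debye_per_enm}{Debye per e nm}
#'   \item{amu_per_nm3_to_kg_m3}{mass-density conversion, (amu nm\eqn{^{-3}}) to kg m\eqn{^{-3}}}
#'   \item{kj_nm3_to_bar}{pressure conversion, (kJ mol\eqn{^{-1}} nm\eqn{^{-3}}) to bar}
#'   \item{bar_nm_to_mN_m}{surface-tension conversion, bar nm to mN m\eqn{^{-1}}}
#'   \item{field_force}{force per unit charge in a 1 V nm\eqn{^{-1}} field, kJ mol\eqn{^{-1}} nm\eqn{^{-1}} e\eqn{^{-1}}}
#'   \item{nm2_ps_to_cm2_s}{diffusion conversion, nm\eqn{^2} ps\eqn{^{-1}} to cm\eqn{^2} s\eqn{^{-1}}}
#'   \item{kj_e_to_volt}{potential conversion, kJ mol\eqn{^{-1}} e\eqn{^{-1}} to V}
#' }
#'
#' @return Named numeric vector.
#' @export
md_constants <- function() {
  c(f_elec = 138.935485,
    k_B = 0.00831446,
    debye_per_enm = 48.0321,
    amu_per_nm3_to_kg_m3 = 1.66054,
    kj_nm3_to_bar = 16.6054,
    bar_nm_to_mN_m = 0.1,
    field_force = 96.4853,
    nm2_ps_to_cm2_s = 1e-2,
    kj_e_to_volt = 0.0103643)
}

.F_ELEC <- 138.935485
.KB <- 0.00831446
.DEBYE <- 48.0321
.AMU_DENS <- 1.66054
.PRESFAC <- 16.6054
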