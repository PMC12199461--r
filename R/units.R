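# Internal unit system: mass in u, length in Angstrom, energy in eV.
# The derived time unit is sqrt(u A^2 / eV) = 10.1805 fs; femtoseconds are
# converted at the interfaces only, so the equations of motion carry no
# unit constants.

#' Physical constants and unit conversions used by mtmd
#'
#' Returns the internal unit system: masses in u, lengths in Angstrom,
#' energies in eV.  The derived internal time unit is
#' \eqn{\sqrt{u\,\mathrm{\AA}^2/\mathrm{eV}} = 10.1805} fs; all user-facing
#' times (time steps, trajectory times) are in fs and converted internally.
#'
#' @return Named list with `k_B` (eV/K), `fs_per_time_unit`,
#'   `eV_A3_per_GPa` (pressure conversion) and `ps_inv_per_freq_unit`
#'   (frequency conversion from inverse internal time units to ps^-1).
#' @export
mtmd_units <- function() {
  list(
    k_B = 8.617333262e-5,
    fs_per_time_unit = 10.1805057107594,
    eV_A3_per_GPa = 6.241509074e-3,
    ps_inv_per_freq_unit = 1000 / 10.1805057107594
  )
}

.kB <- 8.617333262e-5          # eV / K
.TAU_FS <- 10.1805057107594    # fs per internal time unit
.GPA <- 6.241509074e-3         # eV / A^3 per GPa

.fs_to_internal <- function(t_fs) t_fs / .TAU_FS
.internal_to_fs <- function(t) t * .TAU_FS
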