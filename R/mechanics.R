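#' Rotational friction coefficient of the rotor arm
#'
#' For a slender rod of length `L` rotating about its centre in a fluid of
#' viscosity `eta`, the rotational friction coefficient is
#' `zeta_r = pi * eta * L^3`.
#'
#' @param eta_visc dynamic viscosity (Pa s), `> 0`.
#' @param length_m rotor arm length (m), `> 0`.
#' @return zeta_r in N m s.
#' @examples
#' rotational_friction(1e-3, 550e-9)  # about 5.2e-22 N m s
#' @export
rotational_friction <- function(eta_visc, length_m) {
  if (eta_visc <= 0) stop("eta_visc must be > 0")
  if (length_m <= 0) stop("length_m must be > 0")
  pi * eta_visc * length_m^3
}

#' Frictional torque at a given angular velocity
#'
#' `tau = zeta_r * omega`, reported in pN nm (1 pN nm = 1e-21 N m).
#'
#' @param zeta_r rotational friction coefficient (N m s), `> 0`.
#' @param omega angular velocity (rad/s).
#' @return torque in pN nm.
#' @examples
#' torque_from_speed(4e-22, 25)  # 10 pN nm
#' @export
torque_from_speed <- function(zeta_r, omega) {
  if (zeta_r <= 0) stop("zeta_r must be > 0")
  zeta_r * omega / 1e-21
}

#' Power dissipated in rotational friction
#'
#' `P = zeta_r * omega^2`, reported in pN nm/s, in thermal units k_B T/s at
#' the given temperature, and as the equivalent rate of ATP hydrolysis at the
#' given free energy per ATP.
#'
#' @param zeta_r rotational friction coefficient (N m s).
#' @param omega angular velocity (rad/s).
#' @param temp_K temperature (K), default 293.
#' @param dg_atp_kT free energy per ATP in k_B T, default 25 (cellular
#'   conditions).
#' @return list with `power_pN_nm_s`, `power_kT_s`, `atp_per_s`, `kT_pN_nm`.
#' @examples
#' dissipated_power(4e-22, 25)  # 250 pN nm/s, ~62 kT/s, ~2.5 ATP/s
#' @export
dissipated_power <- function(zeta_r, omega, temp_K = 293, dg_atp_kT = 25) {
  if (zeta_r <= 0) stop("zeta_r must be > 0")
  if (temp_K <= 0) stop("temp_K must be > 0")
  if (dg_atp_kT <= 0) stop("dg_atp_kT must be > 0")
  power_pN_nm <- zeta_r * omega^2 / 1e-21
  kT <- .kB_pNnm_per_K * temp_K
  power_kT <- power_pN_nm / kT
  list(power_pN_nm_s = power_pN_nm, power_kT_s = power_kT,
       atp_per_s = power_kT / dg_atp_kT, kT_pN_nm = kT)
}

#' Angular velocity under an external load torque
#'
#' With a linear friction response, a motor free-running at `omega_eff` and
#' loaded by torque `tau` turns at `omega_eff - tau / zeta_r`; the result is
#' negative when the load overdrives the motor and zero at the stall torque
#' `zeta_r * omega_eff`.
#'
#' @param omega_eff free-running effective angular velocity (rad/s).
#' @param tau_pN_nm load torque (pN nm).
#' @param zeta_r rotational friction coefficient (N m s), `> 0`.
#' @return loaded angular velocity (rad/s).
#' @export
loaded_velocity <- function(omega_eff, tau_pN_nm, zeta_r) {
  if (zeta_r <= 0) stop("zeta_r must be > 0")
  omega_eff - tau_pN_nm * 1e-21 / zeta_r
}

#' Nominal efficiency under load and its bound
#'
#' The useful output power against load `tau` is
#' `(omega_eff - tau/zeta_r) * tau`; normalizing by the invested power
#' `zeta_eff * omega_eff^2` gives the nominal efficiency
#' `eps(tau) = ((omega_eff - tau/zeta_r) * tau) / (zeta_eff * omega_eff^2)`,
#' a downward parabola in `tau` with roots at 0 and the stall torque. Maximum
#' work extraction occurs at `tau* = zeta_r * omega_eff / 2`, giving the
#' bound `eps <= zeta_r / (4 * zeta_eff)`.
#'
#' @param tau_pN_nm load torque (pN nm).
#' @param omega_eff free-running angular velocity (rad/s), nonzero.
#' @param zeta_r rotational friction coefficient (N m s).
#' @param zeta_eff effective friction coefficient of the drive (N m s),
#'   `> 0`; depends on the microscopic drive mechanism and is supplied, not
#'   computed.
#' @return list with `efficiency`, `bound` (= zeta_r / (4 zeta_eff)),
#'   `tau_opt_pN_nm` (= zeta_r * omega_eff / 2), `stall_tau_pN_nm`.
#' @export
efficiency <- function(tau_pN_nm, omega_eff, zeta_r, zeta_eff) {
  if (zeta_eff <= 0) stop("zeta_eff must be > 0")
  if (zeta_r <= 0) stop("zeta_r must be > 0")
  if (omega_eff == 0) stop("efficiency undefined at omega_eff = 0")
  tau <- tau_pN_nm * 1e-21
  eps <- ((omega_eff - tau / zeta_r) * tau) / (zeta_eff * omega_eff^2)
  bound <- zeta_r / (4 * zeta_eff)
  if (any(eps > bound + 1e-12)) stop("efficiency exceeded its bound (inconsistent inputs)")
  list(efficiency = eps, bound = bound,
       tau_opt_pN_nm = zeta_r * omega_eff / 2 / 1e-21,
       stall_tau_pN_nm = zeta_r * omega_eff / 1e-21)
}

#' Full motor-mechanics report
#'
#' Convenience wrapper combining the friction, torque, power and efficiency
#' calculators into one record.
#'
#' @param omega angular velocity (rad/s).
#' @param zeta_r rotational friction coefficient (N m s); if `NULL`, computed
#'   from `eta_visc` and `length_m`.
#' @param eta_visc dynamic viscosity (Pa s), used only when `zeta_r` is
#'   `NULL`.
#' @param length_m rotor length (m), used only when `zeta_r` is `NULL`.
#' @param temp_K temperature (K).
#' @param dg_atp_kT free energy per ATP (k_B T).
#' @param zeta_eff optional effective drive friction (N m s) for the
#'   efficiency bound.
#' @return list of class `mechanics_report`.
#' @export
mechanics_report <- function(omega, zeta_r = NULL, eta_visc = 1e-3,
                             length_m = 550e-9, temp_K = 293,
                             dg_atp_kT = 25, zeta_eff = NULL) {
  if (is.null(zeta_r)) zeta_r <- rotational_friction(eta_visc, length_m)
  pw <- dissipated_power(zeta_r, omega, temp_K, dg_atp_kT)
  rep <- list(
    zeta_r = zeta_r, omega = omega,
    torque_pN_nm = torque_from_speed(zeta_r, omega),
    power_pN_nm_s = pw$power_pN_nm_s, power_kT_s = pw$power_kT_s,
    atp_per_s = pw$atp_per_s, temp_K = temp_K, dg_atp_kT = dg_atp_kT,
    tau_opt_pN_nm = zeta_r * omega / 2 / 1e-21
  )
  if (!is.null(zeta_eff)) {
    rep$zeta_eff <- zeta_eff
    rep$efficiency_bound <- zeta_r / (4 * zeta_eff)
  }
  class(rep) <- "mechanics_report"
  rep
}

#' @export
print.mechanics_report <- function(x, ...) {
  cat(sprintf("Motor mechanics at omega = %g rad/s, zeta_r = %g N m s:\n", x$omega, x$zeta_r))
  cat(sprintf("  torque      %.3g pN nm\n", x$torque_pN_nm))
  cat(sprintf("  power       %.3g pN nm/s = %.3g kT/s = %.3g ATP/s\n",
              x$power_pN_nm_s, x$power_kT_s, x$atp_per_s))
  cat(sprintf("  optimal load torque %.3g pN nm\n", x$tau_opt_pN_nm))
  if (!is.null(x$efficiency_bound)) {
    cat(sprintf("  efficiency bound    %.3g\n", x$efficiency_bound))
  }
  invisible(x)
}
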