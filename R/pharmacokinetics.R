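#' Drug disposition parameters
#'
#' One-compartment disposition with first-order oral absorption and
#' elimination. Only the warfarin clearance of 0.2 L/h for the CYP2C9 *1
#' reference is a reported constant; the remaining defaults are documented
#' calibration choices and can be overridden here or through `param` rows
#' of the parameter table.
#'
#' @param drug `"warfarin"` or `"rivaroxaban"`.
#' @param cl clearance (L/h).
#' @param v volume of distribution (L).
#' @param f oral bioavailability (0-1].
#' @param ka absorption rate constant (1/h).
#' @param mw molecular weight (g/mol), used for the mg to nM conversion.
#' @return a `pk_parameters` object.
#' @export
pk_parameters <- function(drug = c("warfarin", "rivaroxaban"),
                          cl = NULL, v = NULL, f = NULL, ka = NULL, mw = NULL) {
  drug <- match.arg(drug)
  def <- if (drug == "warfarin")
    list(cl = 0.2, v = 10, f = 0.9, ka = 1, mw = 308.3)
  else
    list(cl = 6, v = 50, f = 0.8, ka = 1, mw = 435.9)
  p <- list(drug = drug, cl = cl %||% def$cl, v = v %||% def$v,
            f = f %||% def$f, ka = ka %||% def$ka, mw = mw %||% def$mw)
  if (p$cl <= 0 || p$v <= 0 || p$ka <= 0 || p$mw <= 0)
    coag_error("cl, v, ka, mw must be > 0", "coag_validation_error")
  if (p$f <= 0 || p$f > 1)
    coag_error("bioavailability f must be in (0, 1]", "coag_validation_error")
  structure(p, class = "pk_parameters")
}

#' PK parameters taken from a parameter table's `param` rows
#' @param net a `coag_network` whose params may carry
#'   `<drug>_cl_L_h`, `<drug>_v_L`, `<drug>_f`, `<drug>_ka_per_h`,
#'   `<drug>_mw`.
#' @param drug drug name.
#' @return a `pk_parameters` object.
#' @export
default_pk <- function(net, drug = c("warfarin", "rivaroxaban")) {
  drug <- match.arg(drug)
  g <- function(suffix) {
    v <- net$params[[paste0(drug, "_", suffix)]]
    if (is.null(v)) NULL else as.numeric(v)
  }
  pk_parameters(drug, cl = g("cl_L_h"), v = g("v_L"), f = g("f"),
                ka = g("ka_per_h"), mw = g("mw"))
}

#' Dosing schedule
#'
#' @param drug drug name.
#' @param dose_mg amount per administration (mg).
#' @param interval_h dosing interval (h).
#' @param duration_days treatment length (days).
#' @return a `dose_regimen` object.
#' @export
dose_regimen <- function(drug = c("warfarin", "rivaroxaban"), dose_mg,
                         interval_h = 24, duration_days = 20) {
  drug <- match.arg(drug)
  if (dose_mg < 0) coag_error("dose_mg must be >= 0", "coag_validation_error")
  if (interval_h <= 0) coag_error("interval_h must be > 0", "coag_validation_error")
  if (duration_days <= 0) coag_error("duration_days must be > 0", "coag_validation_error")
  structure(list(drug = drug, dose_mg = dose_mg, interval_h = interval_h,
                 duration_days = duration_days, route = "oral"),
            class = "dose_regimen")
}

dose_times_h <- function(regimen) {
  seq(0, regimen$duration_days * 24 - 1e-9, by = regimen$interval_h)
}

#' CYP2C9 genotype adjustment of warfarin clearance
#'
#' *1 leaves clearance unchanged, *2 reduces it by 30%, *3 by 80%.
#' Rivaroxaban is not a CYP2C9 substrate in this model, so the transform is
#' the identity for it.
#'
#' @param pk a `pk_parameters` object.
#' @param allele `"*1"`, `"*2"` or `"*3"`.
#' @return adjusted `pk_parameters`.
#' @export
#' @examples
#' apply_cyp2c9(pk_parameters("warfarin", cl = 0.2), "*3")$cl  # 0.04
apply_cyp2c9 <- function(pk, allele) {
  fac <- c("*1" = 1, "*2" = 0.70, "*3" = 0.20)[allele]
  if (is.na(fac))
    coag_error(paste0("unknown CYP2C9 allele: ", allele), "coag_validation_error")
  if (pk$drug == "warfarin") pk$cl <- pk$cl * unname(fac)
  pk
}

#' Phenprocoumon dose expressed as warfarin-equivalent
#'
#' Linear conversion anchored at 3 mg phenprocoumon = 5 mg warfarin.
#'
#' @param dose_mg phenprocoumon dose (mg).
#' @return warfarin-equivalent dose (mg).
#' @export
phenprocoumon_to_warfarin <- function(dose_mg) {
  if (any(dose_mg < 0))
    coag_error("dose must be >= 0", "coag_validation_error")
  dose_mg * 5 / 3
}

pk_forcing <- function(pk, regimen) {
  ke <- pk$cl / pk$v
  dose_nM <- pk$f * regimen$dose_mg * 1e6 / pk$mw / pk$v
  coef <- if (abs(pk$ka - ke) > 1e-12 * pk$ka)
    dose_nM * pk$ka / (pk$ka - ke)
  else
    dose_nM * pk$ka  # limiting-form coefficient, see the ODE core
  list(drug = pk$drug, ke_per_h = ke, ka_per_h = pk$ka, coef_nM = coef,
       dose_times_h = dose_times_h(regimen))
}

#' Plasma drug concentration under a multi-dose regimen
#'
#' Superposition of one-compartment first-order-absorption doses:
#' C(t) = sum over doses at tau <= t of
#' F D ka / (V (ka - ke)) (exp(-ke (t - tau)) - exp(-ka (t - tau))),
#' in nM after the mg to nmol conversion; the ka = ke case uses the
#' limiting form F D ka / V (t - tau) exp(-ke (t - tau)).
#'
#' @param pk a `pk_parameters` object.
#' @param regimen a `dose_regimen`.
#' @param t time(s) since the first dose (h), `t >= 0`.
#' @return concentration(s) in nM.
#' @export
concentration_profile <- function(pk, regimen, t) {
  if (any(t < 0)) coag_error("t must be >= 0", "coag_validation_error")
  fc <- pk_forcing(pk, regimen)
  ke <- fc$ke_per_h; ka <- fc$ka_per_h
  taus <- fc$dose_times_h
  vapply(t, function(ti) {
    dt <- ti - taus
    dt <- dt[dt >= 0]
    if (!length(dt)) return(0)
    if (abs(ka - ke) > 1e-12 * ka)
      sum(fc$coef_nM * (exp(-ke * dt) - exp(-ka * dt)))
    else
      sum(fc$coef_nM * dt * exp(-ke * dt))
  }, numeric(1))
}
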