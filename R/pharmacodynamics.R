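#' Genotype profile of one patient
#'
#' @param cyp2c9 `"*1"`, `"*2"` or `"*3"`.
#' @param vkorc1 `"GG"`, `"GA"` or `"AA"`.
#' @return a `genotype_profile`.
#' @export
genotype_profile <- function(cyp2c9 = "*1", vkorc1 = "GG") {
  if (!cyp2c9 %in% c("*1", "*2", "*3"))
    coag_error(paste0("unknown CYP2C9 allele: ", cyp2c9), "coag_validation_error")
  if (!vkorc1 %in% c("GG", "GA", "AA"))
    coag_error(paste0("unknown VKORC1 genotype: ", vkorc1), "coag_validation_error")
  structure(list(cyp2c9 = cyp2c9, vkorc1 = vkorc1), class = "genotype_profile")
}

#' Available vitamin K under a VKORC1 genotype
#'
#' The G3673A variant reduces vitamin-K-epoxide-reductase activity; the
#' model represents it by capping the vitamin K available to the system:
#' unchanged for GG, reduced by 22% for GA (one functional allele plus one
#' allele at 44% reduced activity, allele-averaged) and by 44% for AA.
#'
#' @param vk_normal normal available vitamin K (nM), > 0.
#' @param genotype `"GG"`, `"GA"` or `"AA"`.
#' @return available vitamin K (nM).
#' @export
#' @examples
#' apply_vkorc1(100, "GA")  # 78
apply_vkorc1 <- function(vk_normal, genotype) {
  if (any(vk_normal <= 0))
    coag_error("vk_normal must be > 0", "coag_validation_error")
  fac <- c(GG = 1, GA = 1 - heterozygote_reduction(0.44), AA = 1 - 0.44)[genotype]
  if (any(is.na(fac)))
    coag_error(paste0("unknown VKORC1 genotype: ", genotype),
               "coag_validation_error")
  vk_normal * unname(fac)
}

#' Heterozygote reduction from a per-allele effect
#'
#' One fully functional allele plus one allele with fractional activity
#' loss `variant_allele_effect` gives the allele-averaged reduction
#' `variant_allele_effect / 2`.
#'
#' @param variant_allele_effect fraction in [0, 1].
#' @return fractional reduction for the heterozygote.
#' @export
heterozygote_reduction <- function(variant_allele_effect) {
  if (any(variant_allele_effect < 0) || any(variant_allele_effect > 1))
    coag_error("variant_allele_effect must be in [0, 1]", "coag_validation_error")
  variant_allele_effect / 2
}

#' Drug-action constants
#'
#' @param warfarin_imax maximal fractional inhibition of vitamin-K
#'   regeneration (0, 1].
#' @param warfarin_ic50 warfarin concentration of half-maximal inhibition
#'   (nM).
#' @param rivaroxaban_ki reversible factor-Xa inhibition constant (nM).
#' @param vk_normal normal available vitamin K (nM).
#' @return a `drug_action_params` list.
#' @export
drug_action_params <- function(warfarin_imax = 1, warfarin_ic50 = 1500,
                               rivaroxaban_ki = 30, vk_normal = 100) {
  if (warfarin_imax <= 0 || warfarin_imax > 1)
    coag_error("warfarin_imax must be in (0, 1]", "coag_validation_error")
  if (warfarin_ic50 <= 0 || rivaroxaban_ki <= 0 || vk_normal <= 0)
    coag_error("ic50, ki, vk_normal must be > 0", "coag_validation_error")
  structure(list(warfarin_imax = warfarin_imax, warfarin_ic50 = warfarin_ic50,
                 rivaroxaban_ki = rivaroxaban_ki, vk_normal = vk_normal),
            class = "drug_action_params")
}

#' Drug-action constants from a parameter table
#' @param net a `coag_network`.
#' @return a `drug_action_params` list built from the table's `param` rows.
#' @export
default_drug_action <- function(net) {
  p <- net$params
  drug_action_params(
    warfarin_imax = as.numeric(p$warfarin_imax %||% 1),
    warfarin_ic50 = as.numeric(p$warfarin_ic50_nM %||% 1500),
    rivaroxaban_ki = as.numeric(p$rivaroxaban_ki_nM %||% 30),
    vk_normal = as.numeric(p$vk_normal_nM %||% 100))
}

#' Warfarin inhibition of vitamin-K regeneration
#'
#' Hyperbolic (Hill = 1) inhibition: imax C / (IC50 + C). The effective
#' epoxide-to-vitamin-K regeneration rate is scaled by (1 - inhibition),
#' which lowers the available vitamin K and with it the synthesis of the
#' vitamin-K-dependent factors II, VII, IX, X, PC and PS.
#'
#' @param c_warfarin warfarin plasma concentration (nM), >= 0.
#' @param params a `drug_action_params`.
#' @return fractional inhibition in [0, imax].
#' @export
warfarin_vkor_inhibition <- function(c_warfarin, params = drug_action_params()) {
  if (any(c_warfarin < 0))
    coag_error("c_warfarin must be >= 0", "coag_validation_error")
  params$warfarin_imax * c_warfarin / (params$warfarin_ic50 + c_warfarin)
}

#' Rivaroxaban scaling of factor Xa catalytic activity
#'
#' Instantaneous reversible competitive inhibition: the active fraction
#' 1 / (1 + C / Ki) multiplies every Xa-carried kcat (free Xa and the
#' prothrombinase complex) in both the in-vivo and in-vitro systems.
#'
#' @param c_riva rivaroxaban concentration (nM), >= 0.
#' @param ki inhibition constant (nM), > 0.
#' @return active fraction in (0, 1].
#' @export
rivaroxaban_xa_scaling <- function(c_riva, ki = 30) {
  if (any(c_riva < 0)) coag_error("c_riva must be >= 0", "coag_validation_error")
  if (ki <= 0) coag_error("ki must be > 0", "coag_validation_error")
  1 / (1 + c_riva / ki)
}
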