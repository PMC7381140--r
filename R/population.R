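#' Virtual population specification
#'
#' Encodes the stated cohort: genotype frequencies from the model
#' development dataset (CYP2C9 *1/*2/*3 = 72/19/9%, VKORC1 GG/GA/AA =
#' 53/36/11%) and a 20% log-normal inter-individual variability on the
#' production rates of factors II, V, VII, IX, X, XI, XII, XIII, PC and PS
#' and on the PK parameters.
#'
#' @param n population size (>= 1).
#' @param cyp2c9_freqs named probabilities over `*1`, `*2`, `*3`.
#' @param vkorc1_freqs named probabilities over `GG`, `GA`, `AA`.
#' @param cv coefficient of variation of the variability term.
#' @param seed RNG seed making the population a pure function of the spec.
#' @param variability_targets species whose production rates vary.
#' @param pk_targets PK fields that vary (`cl`, `v` by default; whether the
#'   variability also covers F and ka is not stated, so they are excluded
#'   by default but accepted here).
#' @return a `population_spec`.
#' @export
population_spec <- function(n,
                            cyp2c9_freqs = c("*1" = 0.72, "*2" = 0.19, "*3" = 0.09),
                            vkorc1_freqs = c(GG = 0.53, GA = 0.36, AA = 0.11),
                            cv = 0.20, seed = 1L,
                            variability_targets = c("II", "V", "VII", "IX", "X",
                                                    "XI", "XII", "XIII", "PC", "PS"),
                            pk_targets = c("cl", "v")) {
  if (n < 1) coag_error("population size must be >= 1", "coag_validation_error")
  if (cv < 0) coag_error("cv must be >= 0", "coag_validation_error")
  chk <- function(fr, lv, what) {
    if (!setequal(names(fr), lv))
      coag_error(paste0(what, " frequencies must be named over ",
                        paste(lv, collapse = ", ")), "coag_validation_error")
    if (abs(sum(fr) - 1) > 1e-9)
      coag_error(paste0(what, " frequencies must sum to 1"),
                 "coag_validation_error")
    fr[lv]
  }
  cyp2c9_freqs <- chk(cyp2c9_freqs, c("*1", "*2", "*3"), "CYP2C9")
  vkorc1_freqs <- chk(vkorc1_freqs, c("GG", "GA", "AA"), "VKORC1")
  if (any(!pk_targets %in% c("cl", "v", "f", "ka")))
    coag_error("pk_targets must be among cl, v, f, ka", "coag_validation_error")
  structure(list(n = as.integer(n), cyp2c9_freqs = cyp2c9_freqs,
                 vkorc1_freqs = vkorc1_freqs, cv = cv, seed = as.integer(seed),
                 variability_targets = variability_targets,
                 pk_targets = pk_targets),
            class = "population_spec")
}

#' Sample genotypes at the stated frequencies
#'
#' Independent categorical draws per patient and locus, deterministic
#' under the spec's seed.
#'
#' @param spec a `population_spec`.
#' @return list of [genotype_profile()] of length `spec$n`.
#' @export
sample_genotypes <- function(spec) {
  with_local_seed(spec$seed, {
    cyp <- sample(names(spec$cyp2c9_freqs), spec$n, replace = TRUE,
                  prob = spec$cyp2c9_freqs)
    vko <- sample(names(spec$vkorc1_freqs), spec$n, replace = TRUE,
                  prob = spec$vkorc1_freqs)
    lapply(seq_len(spec$n), function(i) genotype_profile(cyp[i], vko[i]))
  })
}

#' Log-normal variability multipliers with unit mean
#'
#' Multipliers are drawn log-normally with E[m] = 1 and coefficient of
#' variation `cv` (sigma^2 = log(1 + cv^2), mu = -sigma^2 / 2); `cv = 0`
#' returns exact ones. Positivity is guaranteed by the log-normal support.
#'
#' @param n number of multipliers.
#' @param cv coefficient of variation (>= 0).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return numeric vector of length `n`.
#' @export
sample_variability <- function(n, cv = 0.20, seed = NULL) {
  if (cv < 0) coag_error("cv must be >= 0", "coag_validation_error")
  draw <- function() {
    if (cv == 0) return(rep(1, n))
    s2 <- log(1 + cv^2)
    rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Build a reproducible virtual population
#'
#' Per patient: a genotype drawn at the stated frequencies plus independent
#' unit-mean log-normal multipliers for each variability-target production
#' rate and each varying PK parameter. Genotype transforms
#' ([apply_cyp2c9()], [apply_vkorc1()]) are applied downstream when the
#' patient is simulated; the population is a pure function of
#' `(spec, network version)`.
#'
#' @param spec a `population_spec`.
#' @param net the base `coag_network` (targets must exist in it).
#' @param pk base `pk_parameters` (used only to validate `pk_targets`).
#' @return list of `virtual_patient` objects with fields `patient_id`,
#'   `genotype`, `production_multipliers`, `pk_multipliers`.
#' @export
build_population <- function(spec, net, pk = NULL) {
  miss <- setdiff(spec$variability_targets, net$species$id)
  if (length(miss))
    coag_error(paste0("variability target species missing from network: ",
                      paste(miss, collapse = ", ")), "coag_schema_error")
  genos <- sample_genotypes(spec)
  with_local_seed(spec$seed + 1L, {
    lapply(seq_len(spec$n), function(i) {
      pm <- setNames(sample_variability(length(spec$variability_targets), spec$cv),
                     spec$variability_targets)
      km <- setNames(sample_variability(length(spec$pk_targets), spec$cv),
                     spec$pk_targets)
      structure(list(patient_id = i, genotype = genos[[i]],
                     production_multipliers = pm, pk_multipliers = km),
                class = "virtual_patient")
    })
  })
}

#' Population manifest as a data frame
#' @param population output of [build_population()].
#' @return data frame with one row per patient (id, genotypes,
#'   multipliers).
#' @export
population_manifest <- function(population) {
  do.call(rbind, lapply(population, function(p) {
    row <- data.frame(patient_id = p$patient_id,
                      cyp2c9 = p$genotype$cyp2c9,
                      vkorc1 = p$genotype$vkorc1,
                      stringsAsFactors = FALSE)
    for (nm in names(p$production_multipliers))
      row[[paste0("mult_", nm)]] <- unname(p$production_multipliers[nm])
    for (nm in names(p$pk_multipliers))
      row[[paste0("pk_", nm)]] <- unname(p$pk_multipliers[nm])
    row
  }))
}
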