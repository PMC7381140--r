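#' Load a coagulation network from a parameter table
#'
#' The parameter table is a tab-separated text file with three record types.
#' `species` rows declare one compartment each: id, role (one of `zymogen`,
#' `active`, `complex`, `cofactor`, `vitamin`, `drug`, `fibrin-related`),
#' baseline plasma concentration (nM), first-order degradation constant
#' (1/h) and a 0/1 flag marking vitamin-K-dependent synthesis. `reaction`
#' rows declare the kinetics: Michaelis-Menten activation
#' (`mm_activation`: catalyst, substrate, product, kcat in 1/s, Km in nM),
#' 1:1 complex formation (`complex_formation`: two substrates combine and
#' are removed, bimolecular k in 1/(nM s)) or `first_order` conversion
#' (k in 1/s). `param` rows hold scalar model constants (drug action,
#' vitamin-K coupling, default PK). Lines starting with `#` are comments;
#' the first non-comment line must be `version<TAB><id>`. Missing fields
#' are written as `.`.
#'
#' Reaction `tag` values select special behaviour declaratively:
#' `vkor` marks the vitamin-K-epoxide regeneration step inhibited by
#' warfarin, `xa_site` marks catalytic activities carried by factor Xa
#' (scaled by rivaroxaban), `contact` marks the contact-phase reactions
#' active during aPTT preincubation.
#'
#' @param path path to the parameter table (TSV).
#' @return an object of class `coag_network`: a list with `species` and
#'   `reactions` data frames, a `params` named list, and the table
#'   `version` string.
#' @export
#' @examples
#' net <- load_network(coagsim_example_table())
#' nrow(net$species)
load_network <- function(path) {
  if (!file.exists(path)) coag_error(paste0("parameter table not found: ", path),
                                     "coag_schema_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) coag_error("empty parameter table", "coag_schema_error")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  head <- fields[[1]]
  if (head[1] != "version" || length(head) < 2)
    coag_error("first record must be 'version<TAB><id>'", "coag_schema_error")
  version <- head[2]

  num <- function(x) {
    x[x == "." | x == ""] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  chr <- function(x) ifelse(x == "." | x == "", NA_character_, x)

  sp_rows <- list(); rx_rows <- list(); params <- list()
  for (i in seq_along(fields)[-1]) {
    f <- fields[[i]]
    type <- f[1]
    if (type == "species") {
      if (length(f) != 6)
        coag_error(sprintf("species row %d: expected 6 fields, got %d", i, length(f)),
                   "coag_schema_error")
      sp_rows[[length(sp_rows) + 1L]] <- data.frame(
        id = f[2], role = f[3], baseline_nM = num(f[4]),
        kdeg_per_h = num(f[5]), vk_dep = as.integer(num(f[6])),
        stringsAsFactors = FALSE)
    } else if (type == "reaction") {
      if (length(f) != 10)
        coag_error(sprintf("reaction row %d: expected 10 fields, got %d", i, length(f)),
                   "coag_schema_error")
      rx_rows[[length(rx_rows) + 1L]] <- data.frame(
        kind = f[2], catalyst = chr(f[3]), substrate_a = chr(f[4]),
        substrate_b = chr(f[5]), product = chr(f[6]),
        kcat_per_s = num(f[7]), km_nM = num(f[8]), k = num(f[9]),
        tag = chr(f[10]), stringsAsFactors = FALSE)
    } else if (type == "param") {
      if (length(f) != 3)
        coag_error(sprintf("param row %d: expected 3 fields", i), "coag_schema_error")
      v <- suppressWarnings(as.numeric(f[3]))
      params[[f[2]]] <- if (is.na(v)) f[3] else v
    } else {
      coag_error(sprintf("row %d: unknown record type '%s'", i, type),
                 "coag_schema_error")
    }
  }
  if (!length(sp_rows)) coag_error("table declares no species", "coag_schema_error")
  species <- do.call(rbind, sp_rows)
  reactions <- if (length(rx_rows)) do.call(rbind, rx_rows) else
    data.frame(kind = character(), catalyst = character(),
               substrate_a = character(), substrate_b = character(),
               product = character(), kcat_per_s = numeric(),
               km_nM = numeric(), k = numeric(), tag = character(),
               stringsAsFactors = FALSE)

  species$production_rate <- species$kdeg_per_h * species$baseline_nM

  net <- structure(list(species = species, reactions = reactions,
                        params = params, version = version),
                   class = "coag_network")
  validate_network(net)
  net$species$production_rate <- derived_productions(net)
  net
}

#' Path to the shipped default coagulation parameter table
#'
#' @param file table filename; the default is the calibrated cascade used
#'   throughout the package.
#' @return absolute path to the table inside the installed package.
#' @export
coagsim_example_table <- function(file = "coag_network_v1.tsv") {
  system.file("extdata", file, package = "coagsim", mustWork = TRUE)
}

#' Validate a coagulation network
#'
#' Checks the structural invariants: unique species ids, known roles and
#' reaction kinds, all reaction participants declared, non-negative rate
#' constants and baselines, zero baselines for active and complex species,
#' and completeness of each reaction's required kinetic fields.
#'
#' @param net a `coag_network`.
#' @return the network, invisibly; errors (class `coag_schema_error` or
#'   `coag_validation_error`) otherwise.
#' @export
validate_network <- function(net) {
  sp <- net$species; rx <- net$reactions
  if (anyDuplicated(sp$id))
    coag_error(paste0("duplicate species id: ",
                      paste(unique(sp$id[duplicated(sp$id)]), collapse = ", ")),
               "coag_validation_error")
  roles <- c("zymogen", "active", "complex", "cofactor", "vitamin", "drug",
             "fibrin-related")
  bad <- setdiff(unique(sp$role), roles)
  if (length(bad))
    coag_error(paste0("unknown species role: ", paste(bad, collapse = ", ")),
               "coag_validation_error")
  if (any(is.na(sp$baseline_nM)) || any(sp$baseline_nM < 0))
    coag_error("species baseline_nM must be >= 0", "coag_validation_error")
  if (any(is.na(sp$kdeg_per_h)) || any(sp$kdeg_per_h < 0))
    coag_error("species kdeg_per_h must be >= 0", "coag_validation_error")
  act <- sp$role %in% c("active", "complex")
  if (any(act & sp$baseline_nM != 0))
    coag_error(paste0("active/complex species must start at zero: ",
                      paste(sp$id[act & sp$baseline_nM != 0], collapse = ", ")),
               "coag_validation_error")

  if (nrow(rx)) {
    kinds <- c("mm_activation", "complex_formation", "first_order")
    if (any(!rx$kind %in% kinds))
      coag_error("unknown reaction kind", "coag_validation_error")
    refd <- function(col, label) {
      v <- rx[[col]]
      miss <- setdiff(v[!is.na(v)], sp$id)
      if (length(miss))
        coag_error(sprintf("reaction %s references undeclared species: %s",
                           label, paste(miss, collapse = ", ")),
                   "coag_schema_error")
    }
    refd("catalyst", "catalyst"); refd("substrate_a", "substrate_a")
    refd("substrate_b", "substrate_b"); refd("product", "product")

    for (i in seq_len(nrow(rx))) {
      r <- rx[i, ]
      if (r$kind == "mm_activation") {
        if (is.na(r$catalyst) || is.na(r$substrate_a) || is.na(r$product) ||
            is.na(r$kcat_per_s) || is.na(r$km_nM))
          coag_error(sprintf("mm_activation row %d: needs catalyst, substrate_a, product, kcat, km", i),
                     "coag_schema_error")
        if (r$kcat_per_s < 0 || r$km_nM <= 0)
          coag_error(sprintf("mm_activation row %d: kcat must be >= 0 and km > 0", i),
                     "coag_validation_error")
      } else if (r$kind == "complex_formation") {
        if (is.na(r$substrate_a) || is.na(r$substrate_b) || is.na(r$product) ||
            is.na(r$k))
          coag_error(sprintf("complex_formation row %d: needs two substrates, product, k", i),
                     "coag_schema_error")
        if (r$k < 0)
          coag_error(sprintf("complex_formation row %d: negative rate", i),
                     "coag_validation_error")
      } else {
        if (is.na(r$substrate_a) || is.na(r$k))
          coag_error(sprintf("first_order row %d: needs substrate_a and k", i),
                     "coag_schema_error")
        if (r$k < 0)
          coag_error(sprintf("first_order row %d: negative rate", i),
                     "coag_validation_error")
      }
    }
    if (sum(!is.na(rx$tag) & rx$tag == "vkor") > 1)
      coag_error("at most one reaction may carry the 'vkor' tag",
                 "coag_validation_error")
  }
  invisible(net)
}

#' Write a network back to the parameter-table format
#'
#' `load_network(save_network(net, f))` is an identity on the network
#' content (round-trip invariant).
#'
#' @param net a `coag_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  fmt <- function(x) ifelse(is.na(x), ".", format(x, digits = 15, scientific = FALSE,
                                                  trim = TRUE))
  out <- c(paste0("version\t", net$version))
  sp <- net$species
  out <- c(out, sprintf("species\t%s\t%s\t%s\t%s\t%s", sp$id, sp$role,
                        fmt(sp$baseline_nM), fmt(sp$kdeg_per_h), fmt(sp$vk_dep)))
  rx <- net$reactions
  if (nrow(rx))
    out <- c(out, sprintf("reaction\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                          rx$kind, fmt2(rx$catalyst), fmt2(rx$substrate_a),
                          fmt2(rx$substrate_b), fmt2(rx$product),
                          fmt(rx$kcat_per_s), fmt(rx$km_nM), fmt(rx$k),
                          fmt2(rx$tag)))
  for (k in names(net$params))
    out <- c(out, sprintf("param\t%s\t%s", k,
                          format(net$params[[k]], digits = 15, scientific = FALSE)))
  writeLines(out, path)
  invisible(path)
}

fmt2 <- function(x) ifelse(is.na(x), ".", x)

# Zero-order production rates implied by the baselines: p = kdeg * C*, with
# the vitamin-K pool balanced against cycle flux (its epoxide sink) so that
# the drug-free state is an exact fixed point of the full system.
derived_productions <- function(net) {
  sp <- net$species
  p <- sp$kdeg_per_h * sp$baseline_nM
  names(p) <- sp$id
  vk <- vk_cycle_indices(net)
  if (!is.null(vk)) {
    VK0 <- sp$baseline_nM[vk$i_vk]
    kox <- vk$kox_h; kreg <- vk$kreg_h
    kdeg_vko <- sp$kdeg_per_h[vk$i_vko]
    vko_ss <- kox * VK0 / (kreg + kdeg_vko)
    p[vk$i_vk] <- sp$kdeg_per_h[vk$i_vk] * VK0 + kox * VK0 - kreg * vko_ss
    p[vk$i_vko] <- 0
  }
  unname(p)
}

# locate the vitamin-K cycle structurally: the 'vkor'-tagged first-order
# reaction regenerates VK (product) from its epoxide (substrate); the
# reverse first-order reaction is the carboxylation/oxidation sink
vk_cycle_indices <- function(net) {
  rx <- net$reactions
  if (!nrow(rx)) return(NULL)
  i_reg <- which(rx$kind == "first_order" & !is.na(rx$tag) & rx$tag == "vkor")
  if (!length(i_reg)) return(NULL)
  vk_id <- rx$product[i_reg]
  vko_id <- rx$substrate_a[i_reg]
  i_ox <- which(rx$kind == "first_order" & !is.na(rx$substrate_a) &
                rx$substrate_a == vk_id & !is.na(rx$product) & rx$product == vko_id)
  if (!length(i_ox))
    coag_error("vkor-tagged regeneration present but no matching oxidation step",
               "coag_validation_error")
  list(i_vk = match(vk_id, net$species$id),
       i_vko = match(vko_id, net$species$id),
       vk_id = vk_id, vko_id = vko_id,
       kox_h = rx$k[i_ox] * 3600, kreg_h = rx$k[i_reg] * 3600)
}

#' Apply genotype and inter-individual variability to a network
#'
#' VKORC1 genotype caps the available vitamin K: the vitamin-K baseline (and
#' hence its production) is scaled by 1.00 / 0.78 / 0.56 for GG / GA / AA.
#' Production multipliers scale the zero-order synthesis of the named
#' species (and therefore their drug-free steady-state levels, since
#' C* = p / kdeg).
#'
#' @param net a `coag_network`.
#' @param genotype a [genotype_profile()] or `NULL`.
#' @param production_multipliers named positive numeric vector over species
#'   ids, or `NULL`.
#' @return the individualized `coag_network`.
#' @export
individualize_network <- function(net, genotype = NULL,
                                  production_multipliers = NULL) {
  sp <- net$species
  if (!is.null(production_multipliers)) {
    miss <- setdiff(names(production_multipliers), sp$id)
    if (length(miss))
      coag_error(paste0("variability target not in network: ",
                        paste(miss, collapse = ", ")), "coag_schema_error")
    if (any(production_multipliers <= 0))
      coag_error("production multipliers must be > 0", "coag_validation_error")
    i <- match(names(production_multipliers), sp$id)
    sp$baseline_nM[i] <- sp$baseline_nM[i] * production_multipliers
  }
  if (!is.null(genotype)) {
    vk <- vk_cycle_indices(net)
    if (!is.null(vk))
      sp$baseline_nM[vk$i_vk] <-
        apply_vkorc1(sp$baseline_nM[vk$i_vk], genotype$vkorc1)
  }
  net$species <- sp
  net$species$production_rate <- derived_productions(net)
  net
}

#' Drug-free steady-state plasma for a network
#'
#' Builds the non-clotting steady state: every zymogen, cofactor and
#' fibrinogen pool at its baseline with production = kdeg * baseline
#' enforced, all activated factors and complexes at zero, and the
#' vitamin-K epoxide pool balanced against the cycle flux.
#'
#' @param net a (possibly individualized) `coag_network`.
#' @return a `plasma_state`: named concentration vector (nM) with the table
#'   version and draw time attached as attributes.
#' @export
steady_state_init <- function(net) {
  sp <- net$species
  bad <- sp$kdeg_per_h == 0 & sp$production_rate > 0
  if (any(bad))
    coag_error(paste0("no finite steady state (kdeg = 0, production > 0): ",
                      paste(sp$id[bad], collapse = ", ")),
               "coag_validation_error")
  conc <- sp$baseline_nM
  names(conc) <- sp$id
  conc[sp$role %in% c("active", "complex")] <- 0
  vk <- vk_cycle_indices(net)
  if (!is.null(vk)) {
    kdeg_vko <- sp$kdeg_per_h[vk$i_vko]
    conc[vk$i_vko] <- vk$kox_h * conc[vk$i_vk] / (vk$kreg_h + kdeg_vko)
  }
  plasma_state(conc, table_version = net$version, time_of_draw_h = 0)
}

#' Construct a plasma state
#'
#' @param concentrations named non-negative numeric vector over all network
#'   species (nM).
#' @param table_version version string of the generating table.
#' @param time_of_draw_h simulated time of the blood draw (h).
#' @return a `plasma_state`.
#' @export
plasma_state <- function(concentrations, table_version = "unversioned",
                         time_of_draw_h = 0) {
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations))))
    coag_error("plasma state concentrations must be named", "coag_validation_error")
  if (any(concentrations < 0))
    coag_error("plasma state concentrations must be >= 0", "coag_validation_error")
  structure(concentrations, table_version = table_version,
            time_of_draw_h = time_of_draw_h, class = "plasma_state")
}

#' @export
print.coag_network <- function(x, ...) {
  cat(sprintf("<coag_network %s: %d species, %d reactions, %d params>\n",
              x$version, nrow(x$species), nrow(x$reactions), length(x$params)))
  invisible(x)
}

#' @export
print.plasma_state <- function(x, ...) {
  cat(sprintf("<plasma_state at t = %g h, table %s>\n",
              attr(x, "time_of_draw_h"), attr(x, "table_version")))
  print(unclass(x)[seq_len(min(8, length(x)))])
  if (length(x) > 8) cat(sprintf("... %d more species\n", length(x) - 8))
  invisible(x)
}
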