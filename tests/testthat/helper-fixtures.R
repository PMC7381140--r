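# Fixtures are built in code: small networks written to tempfiles through
# the table schema, plus a naive per-reaction R oracle for the compiled RHS.

default_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_network(coagsim_example_table())
    cache
  }
})

write_table <- function(lines, version = "toy-1") {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(paste0("version\t", version), lines), path)
  path
}

# enzyme / substrate / product Michaelis-Menten toy
toy_mm_table <- function() {
  write_table(c(
    "species\tE\tcofactor\t5\t0\t0",
    "species\tS\tzymogen\t50\t0\t0",
    "species\tP\tactive\t0\t0\t0",
    "reaction\tmm_activation\tE\tS\t.\tP\t2\t50\t.\t."))
}

# closed A + B -> A:B complex-formation toy (no degradation)
toy_complex_table <- function() {
  write_table(c(
    "species\tA\tzymogen\t2\t0\t0",
    "species\tB\tzymogen\t3\t0\t0",
    "species\tAB\tcomplex\t0\t0\t0",
    "reaction\tcomplex_formation\t.\tA\tB\tAB\t.\t.\t0.1\t."))
}

# single-species pure decay
toy_decay_table <- function(kdeg_h = 3600 * 0.25) {
  # kdeg chosen so the in-vitro (per-second) rate is 0.25/s
  write_table(c(
    sprintf("species\tX\tfibrin-related\t10\t%g\t0", kdeg_h)))
}

# independent oracle: literal per-reaction loop over the network definition,
# mirroring the documented rate law (non-negative state part for reaction
# rates, raw state for degradation)
naive_rhs <- function(net, y, mode = "in_vivo",
                      c_warf = 0, c_riva = 0, vk_ref = NULL) {
  sp <- net$species
  rx <- net$reactions
  yp <- pmax(y, 0)
  scale_t <- if (mode == "in_vivo") 3600 else 1
  kdeg <- if (mode == "in_vivo") sp$kdeg_per_h else sp$kdeg_per_h / 3600
  prod <- if (mode == "in_vivo") sp$production_rate else rep(0, nrow(sp))

  p <- net$params
  inh <- if (c_warf > 0) {
    imax <- as.numeric(p$warfarin_imax %||% 1)
    ic50 <- as.numeric(p$warfarin_ic50_nM %||% 1500)
    imax * c_warf / (ic50 + c_warf)
  } else 0
  xa_scale <- if (c_riva > 0) {
    ki <- as.numeric(p$rivaroxaban_ki_nM %||% 30)
    1 / (1 + c_riva / ki)
  } else 1

  vk <- coagsim:::vk_cycle_indices(net)
  phi <- 1
  if (!is.null(vk) && any(sp$vk_dep > 0)) {
    km <- as.numeric(p$vk_km_nM %||% 4); h <- as.numeric(p$vk_hill %||% 2)
    if (is.null(vk_ref)) vk_ref <- sp$baseline_nM[vk$i_vk]
    f <- function(v) v^h / (km^h + v^h)
    phi <- f(yp[vk$i_vk]) / f(vk_ref)
  }

  dy <- ifelse(sp$vk_dep > 0, prod * phi, prod) - kdeg * y
  id <- function(s) match(s, sp$id)
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    tag <- if (is.na(r$tag)) "" else r$tag
    if (r$kind == "mm_activation") {
      kcat <- r$kcat_per_s * scale_t * (if (tag == "xa_site") xa_scale else 1)
      v <- kcat * yp[id(r$catalyst)] * yp[id(r$substrate_a)] /
        (r$km_nM + yp[id(r$substrate_a)])
      dy[id(r$substrate_a)] <- dy[id(r$substrate_a)] - v
      dy[id(r$product)] <- dy[id(r$product)] + v
    } else if (r$kind == "complex_formation") {
      v <- r$k * scale_t * yp[id(r$substrate_a)] * yp[id(r$substrate_b)]
      dy[id(r$substrate_a)] <- dy[id(r$substrate_a)] - v
      dy[id(r$substrate_b)] <- dy[id(r$substrate_b)] - v
      dy[id(r$product)] <- dy[id(r$product)] + v
    } else {
      k <- r$k * scale_t * (if (tag == "vkor") 1 - inh else 1)
      v <- k * yp[id(r$substrate_a)]
      dy[id(r$substrate_a)] <- dy[id(r$substrate_a)] - v
      if (!is.na(r$product)) dy[id(r$product)] <- dy[id(r$product)] + v
    }
  }
  unname(dy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small valid network for property tests
random_network <- function(n_zym = 4, n_rx = 5) {
  ids <- c(paste0("Z", seq_len(n_zym)), "E1", "E2", "C1", "P1")
  lines <- c(
    sprintf("species\tZ%d\tzymogen\t%.4f\t%.4f\t0", seq_len(n_zym),
            runif(n_zym, 10, 200), runif(n_zym, 0.001, 0.1)),
    "species\tE1\tcofactor\t8\t0\t0",
    "species\tE2\tactive\t0\t0.5\t0",
    "species\tC1\tcomplex\t0\t0.2\t0",
    "species\tP1\tactive\t0\t0\t0")
  rx <- character(n_rx)
  for (i in seq_len(n_rx)) {
    kind <- sample(c("mm_activation", "complex_formation", "first_order"), 1)
    if (kind == "mm_activation") {
      rx[i] <- sprintf("reaction\tmm_activation\t%s\t%s\t.\t%s\t%.4f\t%.2f\t.\t.",
                       sample(c("E1", "E2"), 1),
                       sample(paste0("Z", seq_len(n_zym)), 1),
                       sample(c("E2", "P1"), 1),
                       runif(1, 0.01, 2), runif(1, 10, 500))
    } else if (kind == "complex_formation") {
      ab <- sample(paste0("Z", seq_len(n_zym)), 2)
      rx[i] <- sprintf("reaction\tcomplex_formation\t.\t%s\t%s\tC1\t.\t.\t%.5f\t.",
                       ab[1], ab[2], runif(1, 1e-4, 0.01))
    } else {
      rx[i] <- sprintf("reaction\tfirst_order\t.\t%s\t.\tP1\t.\t.\t%.5f\t.",
                       sample(paste0("Z", seq_len(n_zym)), 1),
                       runif(1, 1e-4, 0.1))
    }
  }
  load_network(write_table(c(lines, rx), version = "random"))
}

# fine fixed-step RK4 for small ODE oracles (independent of the package
# integrator)
rk4 <- function(f, y0, t_end, dt) {
  y <- y0; t <- 0
  while (t < t_end - 1e-12) {
    h <- min(dt, t_end - t)
    k1 <- f(t, y); k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2); k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

make_patient <- function(id = 1, cyp2c9 = "*1", vkorc1 = "GG",
                         production_multipliers = NULL,
                         pk_multipliers = numeric(0)) {
  structure(list(patient_id = id,
                 genotype = genotype_profile(cyp2c9, vkorc1),
                 production_multipliers = production_multipliers,
                 pk_multipliers = pk_multipliers),
            class = "virtual_patient")
}
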