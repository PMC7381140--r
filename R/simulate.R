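#' Compile a network into the flat form consumed by the ODE core
#'
#' Converts rate constants to the active time base (hours in `in_vivo`,
#' seconds in `in_vitro`), zeroes production in vitro (closed test tube),
#' resolves species indices and attaches drug-action context.
#'
#' @param net a `coag_network`.
#' @param mode `"in_vivo"` or `"in_vitro"`.
#' @param context list of overrides: `c_warf` / `c_riva` constant drug
#'   concentrations (nM, in-vitro), `pk` forcing (list with `drug`,
#'   `ke_per_h`, `ka_per_h`, `coef_nM`, `dose_times_h`), `vk_ref`
#'   (drug-free vitamin K reference, defaults to the network baseline),
#'   `reactions_subset` (integer reaction rows to keep, used by the aPTT
#'   preincubation).
#' @return an opaque list for the compiled core.
#' @keywords internal
#' @export
compile_network <- function(net, mode = c("in_vivo", "in_vitro"),
                            context = list()) {
  mode <- match.arg(mode)
  sp <- net$species
  rx <- net$reactions
  if (!is.null(context$reactions_subset))
    rx <- rx[context$reactions_subset, , drop = FALSE]

  n <- nrow(sp)
  idx <- function(ids) {
    i <- match(ids, sp$id)
    ifelse(is.na(i), 0L, i) - 1L  # -1 marks absent
  }

  to_h <- 3600
  if (mode == "in_vivo") {
    prod <- sp$production_rate
    kdeg <- sp$kdeg_per_h
    kcat <- rx$kcat_per_s * to_h
    k <- rx$k * to_h
  } else {
    prod <- rep(0, n)
    kdeg <- sp$kdeg_per_h / to_h
    kcat <- rx$kcat_per_s
    k <- rx$k
  }

  kindmap <- c(mm_activation = 0L, complex_formation = 1L, first_order = 2L)
  tag <- ifelse(is.na(rx$tag), "", rx$tag)

  par <- net$params
  getpar <- function(key, default) {
    v <- context[[key]]
    if (!is.null(v)) return(v)
    v <- par[[key]]
    if (!is.null(v)) return(v)
    default
  }

  vk <- vk_cycle_indices(net)
  idx_vk <- if (is.null(vk)) -1L else vk$i_vk - 1L
  vk_ref <- context$vk_ref
  if (is.null(vk_ref)) vk_ref <- if (is.null(vk)) 1 else sp$baseline_nM[vk$i_vk]

  pk <- context$pk
  pk_active <- !is.null(pk)

  list(
    n = n,
    prod = as.numeric(prod),
    kdeg = as.numeric(kdeg),
    vk_dep = as.integer(sp$vk_dep),
    r_kind = unname(kindmap[rx$kind]),
    r_cat = idx(rx$catalyst),
    r_subA = idx(rx$substrate_a),
    r_subB = idx(rx$substrate_b),
    r_prod = idx(rx$product),
    r_kcat = ifelse(is.na(kcat), 0, kcat),
    r_km = ifelse(is.na(rx$km_nM), 1, rx$km_nM),
    r_k = ifelse(is.na(k), 0, k),
    r_vkor = as.integer(tag == "vkor"),
    r_xa = as.integer(tag == "xa_site"),
    idx_vk = idx_vk,
    vk_ref = as.numeric(vk_ref),
    km_vk = as.numeric(getpar("vk_km_nM", 4)),
    hill_vk = as.numeric(getpar("vk_hill", 2)),
    has_vkdep = any(sp$vk_dep > 0) && idx_vk >= 0,
    imax = as.numeric(getpar("warfarin_imax", 1)),
    ic50 = as.numeric(getpar("warfarin_ic50_nM", 1500)),
    ki = as.numeric(getpar("rivaroxaban_ki_nM", 30)),
    c_warf = as.numeric(context$c_warf %||% 0),
    c_riva = as.numeric(context$c_riva %||% 0),
    pk_active = pk_active,
    pk_drug = if (pk_active && identical(pk$drug, "warfarin")) 1L else 2L,
    pk_ke = if (pk_active) pk$ke_per_h else 0,
    pk_ka = if (pk_active) pk$ka_per_h else 0,
    pk_coef = if (pk_active) pk$coef_nM else 0,
    pk_dose_times = if (pk_active) as.numeric(pk$dose_times_h) else numeric(0),
    species = sp$id
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derivative function of a compiled network
#'
#' Returns the right-hand side f(t, y) of the ODE system: for each species,
#' production (vitamin-K-scaled where flagged) minus first-order
#' degradation, plus the Michaelis-Menten activation terms
#' kcat [catalyst] [S] / (Km + [S]), the 1:1 complex-formation terms
#' k [A][B] (removing both partners) and first-order conversions.
#'
#' @inheritParams compile_network
#' @return a function `(t, y) -> dy` (rates in nM per hour in vivo, nM per
#'   second in vitro).
#' @export
#' @examples
#' net <- load_network(coagsim_example_table())
#' f <- build_rhs(net, "in_vivo")
#' max(abs(f(0, as.numeric(steady_state_init(net)))))  # fixed point
build_rhs <- function(net, mode = c("in_vivo", "in_vitro"), context = list()) {
  cn <- compile_network(net, mode, context)
  function(t, y) {
    if (length(y) != cn$n)
      coag_error(sprintf("state vector length %d does not match network size %d",
                         length(y), cn$n), "coag_dimension_error")
    as.numeric(cpp_rhs(cn, t, as.numeric(y)))
  }
}

#' Integrate a network with the stiff solver
#'
#' Uses a linearly-implicit Rosenbrock(2,3) method with adaptive steps and
#' keeps every accepted step together with its derivative, so the returned
#' trajectory supports C1 cubic-Hermite interpolation at arbitrary times.
#' Integration restarts at the supplied `breaks` (dose times), where the
#' forcing has derivative discontinuities.
#'
#' @param net a `coag_network`.
#' @param state0 named non-negative state vector or `plasma_state`.
#' @param duration integration length (hours in vivo, seconds in vitro).
#' @param mode `"in_vivo"` or `"in_vitro"`.
#' @param context see [compile_network()].
#' @param rtol,atol relative / absolute solver tolerances.
#' @param breaks interior restart times (same base as `duration`).
#' @param max_steps solver step budget per segment.
#' @return a `coag_trajectory`.
#' @export
simulate_network <- function(net, state0, duration,
                             mode = c("in_vivo", "in_vitro"),
                             context = list(), rtol = 1e-6, atol = 1e-9,
                             breaks = numeric(0), max_steps = 200000L) {
  mode <- match.arg(mode)
  cn <- compile_network(net, mode, context)
  y0 <- as.numeric(state0)
  nm <- names(state0)
  if (is.null(nm)) coag_error("state0 must be named", "coag_validation_error")
  if (!identical(nm, cn$species)) {
    i <- match(cn$species, nm)
    if (any(is.na(i)))
      coag_error("state0 does not cover every network species",
                 "coag_dimension_error")
    y0 <- y0[i]
  }
  if (any(y0 < 0)) coag_error("state0 must be non-negative", "coag_validation_error")
  if (duration <= 0) coag_error("duration must be > 0", "coag_validation_error")

  edges <- sort(unique(c(0, breaks[breaks > 0 & breaks < duration], duration)))
  ts <- list(); ys <- list(); fs <- list()
  y <- y0
  for (s in seq_len(length(edges) - 1)) {
    out <- cpp_simulate(cn, y, edges[s], edges[s + 1], rtol, atol,
                        hmax = edges[s + 1] - edges[s], max_steps = max_steps)
    if (!isTRUE(out$ok))
      coag_error(sprintf("stiff solver failed at t = %.6g (%s)",
                         out$t_last, out$message), "coag_solver_error")
    keep <- if (s == 1) seq_along(out$t) else -1L  # drop duplicated segment edge
    ts[[s]] <- out$t[keep]
    ys[[s]] <- out$y[keep, , drop = FALSE]
    fs[[s]] <- out$f[keep, , drop = FALSE]
    y <- out$y[nrow(out$y), ]
  }
  states <- do.call(rbind, ys)
  if (min(states) < -1e-6)
    coag_error(sprintf("solver produced concentration %.3g nM below -1e-6 (misconfiguration?)",
                       min(states)), "coag_solver_error")
  colnames(states) <- cn$species
  derivs <- do.call(rbind, fs)
  structure(list(time = unlist(ts), states = states, derivs = derivs,
                 species = cn$species, mode = mode),
            class = "coag_trajectory")
}

#' Interpolate a trajectory at arbitrary time points
#'
#' Cubic-Hermite interpolation on the solver's accepted steps; negative
#' round-off excursions are clamped to zero for reporting.
#'
#' @param traj a `coag_trajectory`.
#' @param times numeric vector inside the integration window.
#' @param species optional character vector of species ids to return.
#' @return matrix `length(times) x species` of concentrations (nM).
#' @export
interpolate_trajectory <- function(traj, times, species = NULL) {
  tt <- traj$time
  if (any(times < tt[1] - 1e-12) || any(times > tt[length(tt)] + 1e-9))
    coag_error("interpolation time outside the trajectory window",
               "coag_validation_error")
  times <- pmin(pmax(times, tt[1]), tt[length(tt)])
  j <- findInterval(times, tt, rightmost.closed = TRUE)
  j[j < 1] <- 1L
  j[j >= length(tt)] <- length(tt) - 1L
  h <- tt[j + 1] - tt[j]
  s <- (times - tt[j]) / h
  cols <- if (is.null(species)) seq_along(traj$species) else {
    ci <- match(species, traj$species)
    if (any(is.na(ci)))
      coag_error(paste0("unknown species: ",
                        paste(species[is.na(ci)], collapse = ", ")),
                 "coag_schema_error")
    ci
  }
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  out <- matrix(0, length(times), length(cols))
  for (k in seq_along(cols)) {
    c0 <- traj$states[j, cols[k]]; c1 <- traj$states[j + 1, cols[k]]
    d0 <- traj$derivs[j, cols[k]]; d1 <- traj$derivs[j + 1, cols[k]]
    out[, k] <- h00 * c0 + h10 * h * d0 + h01 * c1 + h11 * h * d1
  }
  out[out < 0] <- 0
  colnames(out) <- traj$species[cols]
  out
}

#' Final state of a trajectory as a plasma state
#' @param traj a `coag_trajectory`.
#' @param table_version version string to attach.
#' @return a `plasma_state` at the trajectory end time.
#' @export
final_state <- function(traj, table_version = "unversioned") {
  y <- traj$states[nrow(traj$states), ]
  y[y < 0] <- 0
  plasma_state(setNames(y, traj$species), table_version = table_version,
               time_of_draw_h = traj$time[length(traj$time)])
}

#' @export
print.coag_trajectory <- function(x, ...) {
  cat(sprintf("<coag_trajectory (%s): %d species, %d steps, t in [%g, %g]>\n",
              x$mode, length(x$species), length(x$time), x$time[1],
              x$time[length(x$time)]))
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param x a `coag_trajectory`.
#' @param row.names,optional unused, present for the generic.
#' @param times evaluation grid; defaults to the solver's accepted steps.
#' @param ... unused.
#' @return data frame with columns `time`, `species`, `concentration_nM`.
#' @export
as.data.frame.coag_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                          times = NULL, ...) {
  if (is.null(times)) {
    m <- x$states
    m[m < 0] <- 0
    times <- x$time
  } else {
    m <- interpolate_trajectory(x, times)
  }
  data.frame(time = rep(times, times = length(x$species)),
             species = rep(x$species, each = length(times)),
             concentration_nM = as.vector(m))
}
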