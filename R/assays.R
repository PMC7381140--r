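#' In-vitro assay configuration
#'
#' @param tf_trigger tissue factor added for the PT test (nM).
#' @param ca_trigger contact activator for the aPTT preincubation (nM).
#' @param preincubation_s contact preincubation length (s).
#' @param clot_auc_threshold cumulative fibrin exposure defining the clot
#'   (nM s): the clot time is the earliest t with
#'   integral of fibrin from 0 to t >= threshold.
#' @param isi international sensitivity index (INR exponent).
#' @param pt_standard_s clot time of normal standard plasma (s); `NULL`
#'   computes and caches it per table version.
#' @param max_assay_s censoring horizon (s).
#' @return an `assay_config` list.
#' @export
assay_config <- function(tf_trigger = 300, ca_trigger = 300,
                         preincubation_s = 180, clot_auc_threshold = 1500,
                         isi = 1, pt_standard_s = NULL, max_assay_s = 300) {
  vals <- c(tf_trigger, ca_trigger, preincubation_s, clot_auc_threshold,
            isi, max_assay_s)
  if (any(vals <= 0))
    coag_error("all assay settings must be > 0", "coag_validation_error")
  structure(list(tf_trigger = tf_trigger, ca_trigger = ca_trigger,
                 preincubation_s = preincubation_s,
                 clot_auc_threshold = clot_auc_threshold, isi = isi,
                 pt_standard_s = pt_standard_s, max_assay_s = max_assay_s),
            class = "assay_config")
}

#' Clot time from a fibrin concentration trajectory
#'
#' The clot time is the earliest t at which the area under the fibrin
#' concentration-time curve reaches the threshold. The cumulative integral
#' is accumulated by trapezoids on a fine grid and the crossing is refined
#' by local subdivision to a time tolerance of 1e-3 s.
#'
#' @param fibrin_trajectory either a function `t -> fibrin (nM)` accepting
#'   a vector, or a two-column data frame / matrix (time_s, fibrin_nM).
#' @param threshold clot threshold (nM s).
#' @param max_assay_s censoring horizon (s).
#' @return list with `clot_time_s` (NA if censored) and `censored` flag.
#' @export
#' @examples
#' detect_clot_time(function(t) rep(100, length(t)), 1500, 60)$clot_time_s  # 15
detect_clot_time <- function(fibrin_trajectory, threshold = 1500,
                             max_assay_s = 300) {
  if (threshold <= 0) coag_error("threshold must be > 0", "coag_validation_error")
  f <- if (is.function(fibrin_trajectory)) fibrin_trajectory else {
    m <- as.data.frame(fibrin_trajectory)
    if (ncol(m) < 2) coag_error("trajectory needs (time, concentration) columns",
                                "coag_validation_error")
    tt <- m[[1]]; cc <- m[[2]]
    if (is.unsorted(tt)) coag_error("trajectory times must be sorted",
                                    "coag_validation_error")
    function(x) approx(tt, cc, xout = pmin(pmax(x, min(tt)), max(tt)),
                       rule = 2)$y
  }

  grid <- seq(0, max_assay_s, by = 0.01)
  vals <- f(grid)
  if (any(vals < -1e-9))
    coag_error("negative fibrin concentration in trajectory",
               "coag_validation_error")
  vals[vals < 0] <- 0
  dt <- diff(grid)
  cum <- c(0, cumsum(dt * (vals[-1] + vals[-length(vals)]) / 2))
  hit <- which(cum >= threshold)
  if (!length(hit)) return(list(clot_time_s = NA_real_, censored = TRUE))
  i <- hit[1]
  if (i == 1) return(list(clot_time_s = 0, censored = FALSE))

  # refine inside [grid[i-1], grid[i]] on a 1e-4 s subgrid
  sub <- seq(grid[i - 1], grid[i], by = 1e-4)
  sv <- pmax(f(sub), 0)
  scum <- cum[i - 1] + c(0, cumsum(diff(sub) * (sv[-1] + sv[-length(sv)]) / 2))
  k <- which(scum >= threshold)[1]
  if (is.na(k) || k == 1) return(list(clot_time_s = sub[1], censored = FALSE))
  # linear interpolation of the crossing within one 1e-4 s cell
  t0 <- sub[k - 1]; t1 <- sub[k]
  c0 <- scum[k - 1]; c1 <- scum[k]
  ct <- if (c1 > c0) t0 + (threshold - c0) / (c1 - c0) * (t1 - t0) else t1
  list(clot_time_s = ct, censored = FALSE)
}

fibrin_species_id <- function(net) {
  id <- net$params$fibrin_species %||% "Fibrin"
  if (!id %in% net$species$id)
    coag_error(paste0("fibrin species '", id, "' not in network"),
               "coag_schema_error")
  id
}

in_vitro_context <- function(plasma, net) {
  ctx <- list()
  if ("rivaroxaban" %in% names(plasma)) ctx$c_riva <- unname(plasma[["rivaroxaban"]])
  if ("warfarin" %in% names(plasma)) ctx$c_warf <- unname(plasma[["warfarin"]])
  ctx
}

run_assay_sim <- function(state, net, config, ctx) {
  simulate_network(net, state, duration = config$max_assay_s,
                   mode = "in_vitro", context = ctx)
}

#' International normalized ratio
#'
#' INR = (PT_test / PT_standard) ^ ISI.
#'
#' @param pt_test_s measured clot time (s), > 0.
#' @param pt_standard_s clot time of normal standard plasma (s), > 0.
#' @param isi international sensitivity index.
#' @return the INR (dimensionless).
#' @export
compute_inr <- function(pt_test_s, pt_standard_s, isi = 1) {
  if (any(pt_test_s <= 0) || any(pt_standard_s <= 0))
    coag_error("clot times must be > 0", "coag_validation_error")
  (pt_test_s / pt_standard_s)^isi
}

.pt_standard_cache <- new.env(parent = emptyenv())

#' Clot time of normal standard plasma
#'
#' Runs the PT test on the unmodified table's drug-free steady state and
#' caches the result per table version (the INR formula needs a
#' standard-plasma reference).
#'
#' @param net a `coag_network` (unmodified shipped or user table).
#' @param config an `assay_config`.
#' @return PT of standard plasma (s).
#' @export
pt_standard <- function(net, config = assay_config()) {
  key <- paste0(net$version, "|", config$tf_trigger, "|",
                config$clot_auc_threshold, "|", config$max_assay_s)
  hit <- .pt_standard_cache[[key]]
  if (!is.null(hit)) return(hit)
  plasma <- steady_state_init(net)
  res <- run_pt_raw(plasma, net, config)
  if (res$censored)
    coag_error("standard plasma does not clot: parameter table misconfigured",
               "coag_config_error")
  assign(key, res$clot_time_s, envir = .pt_standard_cache)
  res$clot_time_s
}

# shortcut-mode contact activation: impose the post-preincubation split of
# the XI pool (XIa and residual XI fractions of the drawn XI(0); the
# remaining moiety is treated as consumed by inhibitors)
aptt_initial_state <- function(state, net) {
  if (!all(c("XI", "XIa") %in% names(state)))
    coag_error("network needs XI and XIa species; aPTT test undefined",
               "coag_schema_error")
  xi0 <- state[["XI"]]
  state[["XIa"]] <- as.numeric(net$params$aptt_xia_frac %||% 0.148) * xi0
  state[["XI"]] <- as.numeric(net$params$aptt_xi_frac %||% 0.339) * xi0
  state
}

run_pt_raw <- function(plasma, net, config) {
  state <- as.numeric(plasma); names(state) <- names(plasma)
  if (!"TF" %in% names(state))
    coag_error("network has no TF species; PT test undefined", "coag_schema_error")
  state[["TF"]] <- config$tf_trigger
  traj <- run_assay_sim(state, net, config, in_vitro_context(plasma, net))
  fid <- fibrin_species_id(net)
  fib <- function(t) interpolate_trajectory(traj, t, fid)[, 1]
  c(detect_clot_time(fib, config$clot_auc_threshold, config$max_assay_s),
    list(trajectory = traj))
}

#' In-silico prothrombin time test
#'
#' Adds the tissue-factor trigger (default 300 nM) to the plasma sample,
#' integrates the closed in-vitro system and locates the clot time by the
#' cumulative fibrin-exposure criterion; the INR is computed against the
#' standard plasma of the unmodified table.
#'
#' @param plasma a `plasma_state` (drug-free standard or an in-vivo draw).
#' @param net the `coag_network` the plasma was drawn under (an
#'   individualized network is fine; the INR reference always comes from
#'   `config$pt_standard_s` or the unmodified `reference_net`).
#' @param config an `assay_config`.
#' @param reference_net network used for the standard-plasma PT when
#'   `config$pt_standard_s` is `NULL`; defaults to `net`.
#' @return an `assay_result` list: `assay`, `clot_time_s`, `censored`,
#'   `inr`.
#' @export
run_pt <- function(plasma, net, config = assay_config(), reference_net = net) {
  res <- run_pt_raw(plasma, net, config)
  std <- config$pt_standard_s %||% pt_standard(reference_net, config)
  inr <- if (res$censored) NA_real_ else
    compute_inr(res$clot_time_s, std, config$isi)
  structure(list(assay = "PT", clot_time_s = res$clot_time_s,
                 censored = res$censored, inr = inr,
                 pt_standard_s = std), class = "assay_result")
}

#' In-silico activated partial thromboplastin time test
#'
#' In the default `shortcut` mode the contact-activation product is imposed
#' directly: XIa is set to 0.148 x XI(0) and XI to 0.339 x XI(0) (the
#' levels reached after a 3-min preincubation with 300 nM contact
#' activator; the remaining XI moiety is treated as consumed), all other
#' drawn concentrations are kept, and the closed system is integrated to
#' the clot criterion. `full_preincubation` mode instead adds the contact
#' activator and simulates the 180 s preincubation with only the
#' contact-phase reactions active before releasing the full cascade; it
#' exists to validate the shortcut fractions and is not the normative
#' path.
#'
#' @param plasma a `plasma_state` containing XI.
#' @param net the `coag_network`.
#' @param config an `assay_config`.
#' @param mode `"shortcut"` or `"full_preincubation"`.
#' @return an `assay_result` list: `assay`, `clot_time_s`, `censored`.
#' @export
run_aptt <- function(plasma, net, config = assay_config(),
                     mode = c("shortcut", "full_preincubation")) {
  mode <- match.arg(mode)
  state <- as.numeric(plasma); names(state) <- names(plasma)
  if (!"XI" %in% names(state))
    coag_error("network has no XI species; aPTT test undefined",
               "coag_schema_error")
  ctx <- in_vitro_context(plasma, net)
  if (mode == "shortcut") {
    state <- aptt_initial_state(state, net)
  } else {
    if (!"CA" %in% names(state))
      coag_error("network has no CA species; full preincubation undefined",
                 "coag_schema_error")
    state[["CA"]] <- config$ca_trigger
    contact <- which(!is.na(net$reactions$tag) & net$reactions$tag == "contact")
    if (!length(contact))
      coag_error("no contact-tagged reactions for preincubation",
                 "coag_schema_error")
    pre <- simulate_network(net, state, duration = config$preincubation_s,
                            mode = "in_vitro",
                            context = c(ctx, list(reactions_subset = contact)))
    state <- final_state(pre, attr(plasma, "table_version"))
    state <- setNames(as.numeric(state), names(state))
  }
  traj <- run_assay_sim(state, net, config, ctx)
  fid <- fibrin_species_id(net)
  fib <- function(t) interpolate_trajectory(traj, t, fid)[, 1]
  res <- detect_clot_time(fib, config$clot_auc_threshold, config$max_assay_s)
  structure(list(assay = "aPTT", clot_time_s = res$clot_time_s,
                 censored = res$censored, inr = NA_real_),
            class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  if (x$censored)
    cat(sprintf("<%s: censored (no clot)>\n", x$assay))
  else if (x$assay == "PT")
    cat(sprintf("<PT: %.2f s, INR %.3f>\n", x$clot_time_s, x$inr))
  else
    cat(sprintf("<aPTT: %.2f s>\n", x$clot_time_s))
  invisible(x)
}
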