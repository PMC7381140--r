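test_that("clot-time detector handles closed-form trajectories", {
  # constant 100 nM: AUC 1500 at t = 15
  r <- detect_clot_time(function(t) rep(100, length(t)), 1500, 60)
  expect_false(r$censored)
  expect_equal(r$clot_time_s, 15, tolerance = 1e-3)
  # linear ramp 10 t: 5 t^2 = 1500 -> t = sqrt(300)
  r <- detect_clot_time(function(t) 10 * t, 1500, 60)
  expect_equal(r$clot_time_s, sqrt(300), tolerance = 1e-3)
  # no fibrin: censored
  r <- detect_clot_time(function(t) rep(0, length(t)), 1500, 60)
  expect_true(r$censored)
  expect_true(is.na(r$clot_time_s))
  # negative fibrin is a validation error
  expect_error(detect_clot_time(function(t) -t, 1500, 60),
               class = "coag_validation_error")
})

test_that("detector matches a brute-force fine-grid oracle", {
  set.seed(7)
  for (rep in 1:10) {
    knots_t <- sort(c(0, runif(6, 0, 60), 60))
    knots_c <- runif(8, 0, 400)
    f <- function(t) approx(knots_t, knots_c, xout = t, rule = 2)$y
    thr <- runif(1, 200, 4000)
    got <- detect_clot_time(f, thr, 60)
    # oracle: dense trapezoid on a 1e-4 s grid
    g <- seq(0, 60, by = 1e-4)
    v <- f(g)
    cum <- c(0, cumsum(diff(g) * (v[-1] + v[-length(v)]) / 2))
    i <- which(cum >= thr)[1]
    if (is.na(i)) {
      expect_true(got$censored)
    } else {
      expect_false(got$censored)
      expect_equal(got$clot_time_s, g[i], tolerance = 1e-2)
    }
  }
})

test_that("INR formula follows (PT_test / PT_standard)^ISI", {
  expect_equal(compute_inr(12, 12, 1), 1)
  expect_equal(compute_inr(24, 12, 1), 2)
  expect_equal(compute_inr(24, 12, 2), 4)
  expect_error(compute_inr(0, 12, 1), class = "coag_validation_error")
})

test_that("PT on standard plasma is self-consistent with INR = 1", {
  net <- default_net()
  plasma <- steady_state_init(net)
  res <- run_pt(plasma, net)
  expect_false(res$censored)
  expect_equal(res$inr, 1, tolerance = 1e-6)
  expect_equal(res$clot_time_s, res$pt_standard_s)
  # afibrinogenemic plasma never clots, and censored PT carries no INR
  p0 <- plasma; p0[["Fg"]] <- 0
  res0 <- run_pt(p0, net)
  expect_true(res0$censored)
  expect_true(is.na(res0$inr))
})

test_that("aPTT shortcut imposes the 0.148 / 0.339 split of XI(0)", {
  net <- default_net()
  st <- setNames(as.numeric(steady_state_init(net)), net$species$id)
  st[["XI"]] <- 100
  st2 <- coagsim:::aptt_initial_state(st, net)
  expect_equal(st2[["XIa"]], 14.8)
  expect_equal(st2[["XI"]], 33.9)
  # untouched elsewhere
  others <- setdiff(names(st), c("XI", "XIa"))
  expect_equal(st2[others], st[others])
})

test_that("aPTT runs on normal plasma and responds to rivaroxaban", {
  net <- default_net()
  plasma <- steady_state_init(net)
  base <- run_aptt(plasma, net)
  expect_false(base$censored)
  expect_gt(base$clot_time_s, 10)
  expect_lt(base$clot_time_s, 60)
  expect_true(is.na(base$inr))

  # monotone over a rivaroxaban concentration grid
  times <- vapply(c(0, 20, 60, 150), function(cr) {
    p <- plasma; p[["rivaroxaban"]] <- cr
    run_aptt(p, net)$clot_time_s
  }, numeric(1))
  expect_true(all(diff(times) > 0))
})

test_that("PT is monotone over a warfarin-equivalent factor-depletion grid", {
  net <- default_net()
  std <- pt_standard(net)
  pts <- vapply(c(1, 0.6, 0.35, 0.2), function(s) {
    ni <- individualize_network(net, NULL,
                                setNames(rep(s, 6),
                                         c("II", "VII", "IX", "X", "PC", "PS")))
    run_pt(steady_state_init(ni), ni,
           assay_config(pt_standard_s = std))$clot_time_s
  }, numeric(1))
  expect_true(all(diff(pts) > 0))
})

test_that("full preincubation roughly reproduces the shortcut fractions", {
  # informative check: the contact phase alone should activate an
  # appreciable part of the XI pool and consume most of it
  net <- default_net()
  plasma <- steady_state_init(net)
  xi0 <- plasma[["XI"]]
  st <- setNames(as.numeric(plasma), names(plasma))
  st[["CA"]] <- 300
  contact <- which(!is.na(net$reactions$tag) & net$reactions$tag == "contact")
  pre <- simulate_network(net, st, duration = 180, mode = "in_vitro",
                          context = list(reactions_subset = contact))
  end <- final_state(pre)
  expect_gt(end[["XIa"]] / xi0, 0.05)
  expect_lt(end[["XIa"]] / xi0, 0.45)
  expect_lt(end[["XI"]] / xi0, 0.75)
  # and the full-mode assay produces a finite clot time
  full <- run_aptt(plasma, net, mode = "full_preincubation")
  expect_false(full$censored)
})

test_that("assay config validates", {
  expect_error(assay_config(tf_trigger = 0), class = "coag_validation_error")
  expect_error(assay_config(isi = -1), class = "coag_validation_error")
})
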