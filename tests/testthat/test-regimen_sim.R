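test_that("0 mg regimen returns the baseline state", {
  net <- default_net()
  pk <- default_pk(net, "warfarin")
  pl <- simulate_patient(make_patient(), net, pk,
                         dose_regimen("warfarin", 0, duration_days = 20))
  base <- steady_state_init(net)
  rel <- abs(pl[names(base)] - base) / pmax(base, 1e-9)
  expect_lt(max(rel[base > 0]), 1e-3)
})

test_that("warfarin depletes factor VII below baseline at steady state", {
  net <- default_net()
  pk <- default_pk(net, "warfarin")
  base <- steady_state_init(net)
  pl <- simulate_patient(make_patient(), net, pk, dose_regimen("warfarin", 5))
  expect_lt(pl[["VII"]], base[["VII"]])
  expect_gt(pl[["warfarin"]], 0)
})

test_that("day-20 draw is at steady state (draw-day insensitivity)", {
  net <- default_net()
  pk <- default_pk(net, "warfarin")
  reg <- dose_regimen("warfarin", 5, duration_days = 27)
  std <- pt_standard(net)
  cfg <- assay_config(pt_standard_s = std)
  inr_at <- function(day) {
    pl <- simulate_patient(make_patient(), net, pk, reg, draw_day = day)
    run_pt(pl, net, cfg)$inr
  }
  i20 <- inr_at(20); i27 <- inr_at(27)
  expect_lt(abs(i27 - i20) / i20, 0.02)
})

test_that("a *3/AA patient responds more than the *1/GG twin", {
  net <- default_net()
  pk <- default_pk(net, "warfarin")
  reg <- dose_regimen("warfarin", 5)
  mult <- setNames(rep(1, 10), c("II", "V", "VII", "IX", "X", "XI", "XII",
                                 "XIII", "PC", "PS"))
  wt <- simulate_patient(make_patient(1, "*1", "GG", mult), net, pk, reg)
  vr <- simulate_patient(make_patient(2, "*3", "AA", mult), net, pk, reg)
  expect_lt(vr[["II"]], wt[["II"]])
})

test_that("regimen must reach the draw day", {
  net <- default_net()
  pk <- default_pk(net, "warfarin")
  expect_error(simulate_patient(make_patient(), net, pk,
                                dose_regimen("warfarin", 5, duration_days = 10),
                                draw_day = 20),
               class = "coag_validation_error")
})

test_that("run_scenario is deterministic and n = 1 works", {
  net <- default_net()
  spec <- population_spec(1, seed = 42)
  reg <- dose_regimen("warfarin", 5)
  r1 <- run_scenario(spec, reg, assay_config(), net)
  r2 <- run_scenario(spec, reg, assay_config(), net)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$endpoint, "INR")
  expect_false(r1$failed)
})

test_that("rivaroxaban results are exactly genotype-invariant", {
  net <- default_net()
  pk <- default_pk(net, "rivaroxaban")
  reg <- dose_regimen("rivaroxaban", 20)
  mult <- setNames(rep(1, 10), c("II", "V", "VII", "IX", "X", "XI", "XII",
                                 "XIII", "PC", "PS"))
  res <- vapply(list(c("*1", "GG"), c("*3", "AA"), c("*2", "GA")), function(g) {
    pl <- simulate_patient(make_patient(1, g[1], g[2], mult), net, pk, reg)
    run_aptt(pl, net)$clot_time_s
  }, numeric(1))
  expect_identical(res[1], res[2])
  expect_identical(res[1], res[3])
})

test_that("genotype effects order the endpoint at fixed dose", {
  net <- default_net()
  pk <- default_pk(net, "warfarin")
  reg <- dose_regimen("warfarin", 5)
  std <- pt_standard(net)
  cfg <- assay_config(pt_standard_s = std)
  inr_for <- function(cyp, vko) {
    pat <- make_patient(1, cyp, vko)
    pl <- simulate_patient(pat, net, pk, reg)
    ni <- individualize_network(net, pat$genotype, NULL)
    run_pt(pl, ni, cfg)$inr
  }
  # CYP2C9 ordering *3 > *2 > *1 within GG
  i1 <- inr_for("*1", "GG"); i2 <- inr_for("*2", "GG"); i3 <- inr_for("*3", "GG")
  expect_gt(i3, i2); expect_gt(i2, i1)
  # VKORC1 ordering AA > GA > GG within *1
  a <- inr_for("*1", "AA"); g <- inr_for("*1", "GA")
  expect_gt(a, g); expect_gt(g, i1)
})

test_that("stratified summary aggregates by dose and genotype", {
  # synthetic results exercise the aggregation contract cheaply
  res <- expand.grid(cyp2c9 = c("*1", "*2"), vkorc1 = c("GG", "GA"),
                     rep = 1:5, stringsAsFactors = FALSE)
  res$dose_mg <- 5; res$drug <- "warfarin"; res$endpoint <- "INR"
  res$patient_id <- seq_len(nrow(res))
  res$value <- 2 + (res$cyp2c9 == "*2") + 0.5 * (res$vkorc1 == "GA") +
    0.01 * res$rep
  res$censored <- FALSE; res$failed <- FALSE
  s <- suppressWarnings(genotype_stratified_summary(res))
  expect_equal(nrow(s), 4)
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
  m <- function(c9, vk) s$median[s$cyp2c9 == c9 & s$vkorc1 == vk]
  expect_gt(m("*2", "GG"), m("*1", "GG"))
  expect_gt(m("*1", "GA"), m("*1", "GG"))
  expect_error(genotype_stratified_summary(res[0, ]),
               class = "coag_validation_error")
})
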