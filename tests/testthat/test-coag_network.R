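test_that("shipped table loads with the full cascade", {
  net <- default_net()
  expect_s3_class(net, "coag_network")
  expect_gte(nrow(net$species), 30)
  # extrinsic, intrinsic, common pathway, vitamin K cycle all represented
  expect_true(all(c("TF", "VII", "X", "CA", "XII", "XI", "IX", "VIII",
                    "II", "V", "Fg", "Fibrin", "VK", "VKO", "PC", "PS")
                  %in% net$species$id))
  expect_identical(net$version, "coag-v1")
})

test_that("toy table loads and schema errors are specific", {
  net <- load_network(toy_mm_table())
  expect_equal(nrow(net$species), 3)
  expect_equal(nrow(net$reactions), 1)

  bad <- write_table(c(
    "species\tE\tcofactor\t5\t0\t0",
    "reaction\tmm_activation\tE\tXQ\t.\tE\t1\t10\t.\t."))
  expect_error(load_network(bad), "XQ", class = "coag_schema_error")

  dup <- write_table(c(
    "species\tE\tcofactor\t5\t0\t0",
    "species\tE\tcofactor\t5\t0\t0"))
  expect_error(load_network(dup), "duplicate", class = "coag_validation_error")

  neg <- write_table(c(
    "species\tE\tcofactor\t5\t0\t0",
    "species\tS\tzymogen\t50\t0\t0",
    "species\tP\tactive\t0\t0\t0",
    "reaction\tmm_activation\tE\tS\t.\tP\t-2\t50\t.\t."))
  expect_error(load_network(neg), class = "coag_validation_error")

  act <- write_table("species\tP\tactive\t5\t0\t0")
  expect_error(load_network(act), "zero", class = "coag_validation_error")
})

test_that("save -> load round trip is identity", {
  net <- default_net()
  path <- tempfile(fileext = ".tsv")
  save_network(net, path)
  net2 <- load_network(path)
  expect_equal(net2$species, net$species, tolerance = 1e-12)
  expect_equal(net2$reactions, net$reactions, tolerance = 1e-12)
  expect_identical(net2$version, net$version)
  expect_equal(net2$params[order(names(net2$params))],
               net$params[order(names(net$params))], tolerance = 1e-12)
})

test_that("rhs implements the documented rate laws", {
  # MM: 2 * 5 * 50 / (50 + 50) = 5 nM/s consumed from S
  net <- load_network(toy_mm_table())
  f <- build_rhs(net, "in_vitro")
  dy <- f(0, c(E = 5, S = 50, P = 0))
  expect_equal(dy, c(0, -5, 5))

  # complex formation: k[A][B] = 0.1 * 2 * 3 = 0.6, removed 1:1
  netc <- load_network(toy_complex_table())
  dyc <- build_rhs(netc, "in_vitro")(0, c(A = 2, B = 3, AB = 0))
  expect_equal(dyc, c(-0.6, -0.6, 0.6))
  # mass-action consistency on the rate vector itself
  expect_equal(dyc[3], -dyc[1])
  expect_equal(dyc[3], -dyc[2])

  # turnover balance: production 1 nM/h, kdeg 0.01/h, C = 100 -> rate 0
  nett <- load_network(write_table("species\tW\tzymogen\t100\t0.01\t0"))
  expect_equal(build_rhs(nett, "in_vivo")(0, c(W = 100)), 0)

  # dimension guard
  expect_error(f(0, c(1, 2)), class = "coag_dimension_error")
})

test_that("compiled rhs matches the naive per-reaction oracle", {
  set.seed(42)
  for (rep in 1:6) {
    net <- random_network()
    y <- runif(nrow(net$species), 0, 150)
    names(y) <- net$species$id
    for (mode in c("in_vivo", "in_vitro")) {
      got <- build_rhs(net, mode)(0, y)
      want <- naive_rhs(net, y, mode)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # and on the full shipped cascade, including drug action terms
  net <- default_net()
  y <- steady_state_init(net)
  y[["warfarin"]] <- 800; y[["rivaroxaban"]] <- 40
  y[["Xa"]] <- 5; y[["IIa"]] <- 2; y[["VK"]] <- 30
  got <- build_rhs(net, "in_vitro",
                   context = list(c_warf = 800, c_riva = 40))(0, as.numeric(y))
  want <- naive_rhs(net, as.numeric(y), "in_vitro", c_warf = 800, c_riva = 40)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("steady_state_init enforces turnover balance and zero actives", {
  nett <- load_network(write_table("species\tW\tzymogen\t80\t0.05\t0"))
  expect_equal(nett$species$production_rate, 4)  # p = kdeg * C*

  net <- default_net()
  st <- steady_state_init(net)
  act <- net$species$id[net$species$role %in% c("active", "complex")]
  expect_true(all(st[act] == 0))

  # in-vivo drug-free rate vector is a fixed point
  f <- build_rhs(net, "in_vivo")
  expect_lt(max(abs(f(0, as.numeric(st)))), 1e-9)

  # kdeg = 0 with production > 0 has no steady state
  bad <- load_network(write_table("species\tW\tzymogen\t80\t0\t0"))
  bad$species$production_rate <- 1
  expect_error(steady_state_init(bad), class = "coag_validation_error")
})

test_that("pure decay matches the closed form", {
  net <- load_network(toy_decay_table())  # 0.25/s in vitro
  traj <- simulate_network(net, c(X = 10), duration = 20, mode = "in_vitro",
                           rtol = 1e-8, atol = 1e-12)
  tt <- c(0.5, 1, 2, 5, 10, 19.5)
  got <- interpolate_trajectory(traj, tt, "X")[, 1]
  expect_equal(got, 10 * exp(-0.25 * tt), tolerance = 1e-6)
})

test_that("closed complex-formation toy conserves moieties", {
  net <- load_network(toy_complex_table())
  traj <- simulate_network(net, c(A = 2, B = 3, AB = 0), duration = 30,
                           mode = "in_vitro", rtol = 1e-8, atol = 1e-12)
  tot_a <- traj$states[, "A"] + traj$states[, "AB"]
  tot_b <- traj$states[, "B"] + traj$states[, "AB"]
  expect_lt(max(abs(tot_a - 2)) / 2, 1e-6)
  expect_lt(max(abs(tot_b - 3)) / 3, 1e-6)
  expect_gte(min(traj$states), -1e-9)
})

test_that("drug-free in-vivo integration holds the baseline for 20 days", {
  net <- default_net()
  st <- steady_state_init(net)
  traj <- simulate_network(net, st, duration = 480, mode = "in_vivo")
  end <- final_state(traj)
  zym <- net$species$id[net$species$role %in% c("zymogen", "vitamin") |
                          net$species$id == "Fg"]
  drift <- abs(end[zym] - st[zym]) / pmax(st[zym], 1e-12)
  expect_lt(max(drift), 1e-3)
  expect_gte(min(traj$states), -1e-9)
})

test_that("individualize_network applies genotype and multipliers", {
  net <- default_net()
  ni <- individualize_network(net, genotype_profile("*1", "AA"),
                              c(II = 1.2))
  expect_equal(ni$species$baseline_nM[ni$species$id == "VK"],
               0.56 * net$species$baseline_nM[net$species$id == "VK"])
  expect_equal(ni$species$baseline_nM[ni$species$id == "II"],
               1.2 * net$species$baseline_nM[net$species$id == "II"])
  # production re-derived so the individualized state is still a fixed point
  f <- build_rhs(ni, "in_vivo", context = list(
    vk_ref = ni$species$baseline_nM[ni$species$id == "VK"]))
  expect_lt(max(abs(f(0, as.numeric(steady_state_init(ni))))), 1e-9)
  expect_error(individualize_network(net, NULL, c(NOPE = 1)),
               class = "coag_schema_error")
})
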