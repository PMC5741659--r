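test_that("mass-action rates follow the power law of substrate stoichiometry", {
  net <- reaction_network(list(
    reaction(c(S1 = 1, S2 = 1), c(S3 = 1), k = 2, name = "r1"),
    reaction(c(S3 = 2), c(S4 = 1), k = 1, name = "r2")))
  v <- mass_action_rates(net, c(S1 = 0.5, S2 = 3, S3 = 2, S4 = 0))
  expect_equal(unname(v["r1"]), 2 * 0.5 * 3)  # 3.0
  expect_equal(unname(v["r2"]), 1 * 2^2)
  v0 <- mass_action_rates(net, c(S1 = 0, S2 = 3, S3 = 0, S4 = 0))
  expect_equal(unname(v0), c(0, 0))
  expect_error(mass_action_rates(net, c(S1 = -1, S2 = 1, S3 = 1, S4 = 1)),
               "negative")
})

test_that("Michaelis-Menten rates satisfy the canonical limits", {
  mm <- function(Vf, Vr, KmS, KmP) reaction_network(list(
    reaction(c(S = 1), c(P = 1), law = "michaelis_menten",
             Vf = Vf, Vr = Vr, Km = c(S = KmS, P = KmP), name = "r")))
  # half saturation
  net <- mm(2, 0, 1.5, 1)
  expect_equal(unname(michaelis_menten_rates(net, c(S = 1.5, P = 0))), 1)
  # saturation asymptote
  expect_equal(unname(michaelis_menten_rates(net, c(S = 1.5e6, P = 0))), 2,
               tolerance = 1e-4)
  # reversible equilibrium: Vf s/KmS = Vr p/KmP -> v = 0
  net2 <- mm(2, 1, 1, 2)
  p_eq <- 2 * 0.7 / 1 * 2 / 1  # solves Vf*s/KmS = Vr*p/KmP at s = 0.7
  expect_equal(unname(michaelis_menten_rates(net2, c(S = 0.7, P = p_eq))), 0,
               tolerance = 1e-12)
  expect_error(reaction(c(S = 1), c(P = 1), law = "michaelis_menten",
                        Vf = 1, Km = c(S = -1)), "Km")
})

test_that("enzyme-complex expansion produces the elementary scheme", {
  net <- reaction_network(list(reaction(c(S = 1), c(P = 1), k = 1, name = "rx")))
  ex <- expand_enzyme_complexes(net, k_on = 100, k_off = 100, k_cat = 1)
  expect_length(ex$reactions, 3)
  expect_length(ex$species, 4)  # gains E and C
  # binding followed by catalysis recovers S -> P with the enzyme recycled
  net_st <- rowSums(ex$N[, c("rx_bind", "rx_cat")])
  expect_equal(unname(net_st[c("S", "P")]), c(-1, 1))
  expect_equal(unname(net_st[c("E_rx", "C_rx")]), c(0, 0))

  # enzyme moiety conserved along a trajectory
  tr <- simulate_network(ex, c(S = 2, P = 0, E_rx = 0.1, C_rx = 0),
                         times = seq(0, 50, length.out = 21))
  etot <- tr$states[, "E_rx"] + tr$states[, "C_rx"]
  expect_lt(max(abs(etot - etot[1])) / etot[1], 1e-8)

  # name collision
  net2 <- reaction_network(list(reaction(c(S = 1), c(C_rx = 1), k = 1, name = "rx")))
  expect_error(expand_enzyme_complexes(net2), "collision")
})

test_that("expanded scheme matches the Michaelis-Menten QSSA flux within 2%", {
  net <- reaction_network(list(reaction(c(S = 1), c(P = 1), k = 1, name = "rx")))
  ex <- expand_enzyme_complexes(net, k_on = 100, k_off = 100, k_cat = 1)
  Etot <- 0.01
  Km <- (100 + 1) / 100
  for (s0 in c(0.2, 0.5, 1, 2, 5)) {
    tr <- simulate_network(ex, c(S = s0, P = 0, E_rx = Etot, C_rx = 0),
                           times = c(0, 0.25, 0.5))
    flux <- 1 * tr$states[3, "C_rx"]
    expect_equal(unname(flux), Etot * s0 / (Km + s0), tolerance = 0.02)
  }
})

test_that("reversible reactions split into equivalent irreversible pairs", {
  net <- reaction_network(list(
    reaction(c(A = 1), c(B = 1), kf = 1, kb = 0.5, reversible = TRUE, name = "r1")))
  ir <- reversible_to_irreversible(net)
  expect_length(ir$reactions, 2)
  # 11 reversible reactions become 22 irreversible ones
  many <- reaction_network(lapply(1:11, function(i)
    reaction(setNames(1, paste0("x", i)), setNames(1, paste0("x", i + 1)),
             kf = 1, kb = 1, reversible = TRUE, name = paste0("r", i))))
  expect_length(reversible_to_irreversible(many)$reactions, 22)
  expect_error(reversible_to_irreversible(reaction_network(list(
    reaction(c(A = 1), c(B = 1), kf = 1, kb = NULL, reversible = TRUE)))), "kf and kb")

  # trajectory equivalence of net-rate and split formulations
  times <- seq(0, 10, length.out = 21)
  x0 <- c(A = 2, B = 0.1)
  t1 <- simulate_network(net, x0, times)
  t2 <- simulate_network(ir, x0, times)
  expect_lt(max(abs(t1$states - t2$states)), 1e-6)
})

test_that("simulation preserves steady states and conserved moieties", {
  net <- fixture_toy_cycle()
  # exact steady state stays put: solve k1 x1 x2 = k2 x3 = k3 x4
  x <- c(S1 = 2, S2 = 3, S3 = 1 * 2 * 3 / 2, S4 = 1 * 2 * 3 / 3)
  tr <- simulate_network(net, x, times = seq(0, 100, length.out = 11))
  expect_lt(max(abs(sweep(tr$states, 2, x))), 1e-8)

  # conserved moieties from an independent SVD left-null basis
  set.seed(60)
  x0 <- runif(4, 0.5, 5); names(x0) <- net$species
  tr2 <- simulate_network(net, x0, times = seq(0, 200, length.out = 21))
  W <- oracle_left_null(stoich_matrix(net))
  expect_gt(ncol(W), 0)
  mo <- tr2$states %*% W
  drift <- apply(mo, 2, function(col) max(abs(col - col[1])) / max(1, abs(col[1])))
  expect_lt(max(drift), 1e-8)

  # relaxation ends with all three rates equal
  final <- tr2$states[nrow(tr2$states), ]
  ss <- stoichcor:::steady_state(net, final)
  v <- mass_action_rates(net, ss$x)
  expect_lt(max(v) - min(v), 1e-6)
  expect_error(simulate_network(net, x0, times = c(0, 0)), "increasing")
})

test_that("fixtures have the documented structure", {
  toy <- fixture_toy_cycle()
  expect_equal(dim(stoich_matrix(toy)), c(4, 3))
  expect_equal(unname(colSums(stoich_matrix(toy))), c(-1, 0, 1))
  for (kin in c("mass_action", "enzyme_complex", "michaelis_menten")) {
    net <- fixture_tca_mini(kin)
    expect_true(all(sprintf("M%02d", 1:11) %in% net$species))
  }
  expect_length(fixture_tca_mini("mass_action")$reactions, 10)
  expect_length(fixture_tca_mini("enzyme_complex")$reactions, 30)

  # steady state of the toy cycle couples r1 and r3: k1 x1 x2 = k3 x4
  ss <- stoichcor:::steady_state(toy, c(S1 = 1, S2 = 2, S3 = 0.5, S4 = 0.7))
  expect_true(ss$converged)
  k <- c(1, 2, 3)
  expect_equal(k[1] * ss$x["S1"] * ss$x["S2"], k[3] * ss$x["S4"],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ensembles are reproducible and pass the steady-state tolerance", {
  net <- fixture_toy_cycle()
  e1 <- sample_ensemble(net, n_draws = 10, seed = 9)
  e2 <- sample_ensemble(net, n_draws = 10, seed = 9)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_equal(dim(e1), c(10, 5))
  for (i in seq_len(nrow(e1))) {
    x <- unlist(e1[i, net$species])
    resid <- max(abs(stoich_matrix(net) %*% mass_action_rates(net, x)))
    expect_lte(resid, 1e-9 * (1 + max(abs(x))))
  }
  # rate-ratio constancy across the ensemble (coupled rates)
  rates <- t(apply(as.matrix(e1[net$species]), 1, function(x)
    mass_action_rates(net, setNames(x, net$species))))
  gamma <- rates[, 1] / rates[, 2]
  expect_lt(stats::sd(gamma) / mean(gamma), 1e-6)

  tc <- sample_ensemble(net, n_draws = 3, seed = 9, mode = "timecourse")
  expect_equal(nrow(tc), 3 * 21)
  expect_equal(attr(tc, "meta_cols"), c("draw", "time"))
})

test_that("model files round-trip structure, parameters and rates", {
  net <- fixture_tca_mini("michaelis_menten")
  path <- withr::local_tempfile(fileext = ".txt")
  write_network_model(net, path)
  back <- read_network_model(path)
  expect_equal(stoich_matrix(back), stoich_matrix(net))
  set.seed(61)
  x <- runif(11, 0.1, 2); names(x) <- net$species
  expect_equal(network_rates(back, x), network_rates(net, x), tolerance = 1e-12)
  expect_equal(back$ranges, net$ranges)

  toy <- fixture_toy_cycle()
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_network_model(toy, p2)
  back2 <- read_network_model(p2)
  expect_equal(stoich_matrix(back2), stoich_matrix(toy))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("A + ; law=mass_action ; k=1", bad)
  expect_error(read_network_model(bad), "malformed")
})

test_that("trajectories convert to tibbles and plot", {
  net <- fixture_toy_cycle()
  tr <- simulate_network(net, c(S1 = 1, S2 = 1, S3 = 1, S4 = 1),
                         times = seq(0, 10, length.out = 5))
  tb <- tibble::as_tibble(tr)
  expect_equal(dim(tb), c(5, 5))
  expect_equal(tb$time, tr$times)
  expect_s3_class(autoplot(tr), "ggplot")
})
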