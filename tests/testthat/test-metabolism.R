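chain_model <- function() {
  metabolic_model(
    c("A", "B"),
    list(list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = 10, gpr = "",
              is_exchange = TRUE),
         list(id = "R1", stoich = c(A = -1, B = 1), lb = 0, ub = 100,
              gpr = "g1", is_exchange = FALSE),
         list(id = "BIO", stoich = c(B = -1), lb = 0, ub = 1000, gpr = "",
              is_exchange = FALSE)),
    biomass = "BIO")
}

test_that("FBA solves the chain and diamond toy models", {
  expect_equal(fba(chain_model())$growth, 10)

  # closing the single internal reaction kills growth
  b <- model_bounds(chain_model())
  b$vmax[b$reaction == "R1"] <- 0
  expect_equal(fba(chain_model(), b)$growth, 0)

  dia <- fx_diamond()
  fs <- fba(dia)
  expect_equal(fs$growth, 10)
  expect_equal(unname(fs$v["R2"] + fs$v["R3"]), 10)
  # steady state and bounds hold at the optimum
  S <- as.matrix(ebaflux:::met_stoich_matrix(dia))
  expect_lt(max(abs(S %*% fs$v)), 1e-6)
})

test_that("FVA ranges: redundancy keeps slack, obligatory steps collapse", {
  dia <- fx_diamond()
  fb <- fva(dia, biomass_fraction = 1)
  expect_equal(fb$vmin[fb$reaction == "R2"], 0)
  expect_equal(fb$vmax[fb$reaction == "R2"], 10)

  ch <- fva(chain_model(), biomass_fraction = 1)
  expect_equal(ch$vmin, ch$vmax)  # unique pathway: every range is a point

  # blocked reaction has range [0, 0] even with no biomass requirement
  blocked <- metabolic_model(
    c("A", "B", "C"),
    list(list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = 10, gpr = "",
              is_exchange = TRUE),
         list(id = "R1", stoich = c(A = -1, B = 1), lb = 0, ub = 100, gpr = ""),
         list(id = "RX", stoich = c(C = -1), lb = 0, ub = 100, gpr = ""),
         list(id = "BIO", stoich = c(B = -1), lb = 0, ub = 1000, gpr = "")),
    biomass = "BIO")
  fbk <- fva(blocked, biomass_fraction = 0)
  expect_equal(fbk$vmin[fbk$reaction == "RX"], 0)
  expect_equal(fbk$vmax[fbk$reaction == "RX"], 0)
})

test_that("FVA sandwich: FBA flux lies inside the FVA range", {
  for (s in 1:5) {
    met <- generate_toy_metabolic_model(n_internal = 4 + s %% 3,
                                        redundancy = s %% 2, seed = s)
    fs <- fba(met$model)
    fb <- fva(met$model, biomass_fraction = 1)
    expect_true(all(fs$v >= fb$vmin - 1e-6 & fs$v <= fb$vmax + 1e-6))
  }
})

test_that("the simplex agrees with scipy's HiGHS on random instances", {
  for (s in 1:8) {
    inst <- random_lp_instance(1000 + s)
    mine <- lp_solve(inst$obj, inst$S, numeric(nrow(inst$S)), inst$lb, inst$ub)
    oracle <- scipy_lp(inst$obj, inst$S, inst$lb, inst$ub)
    expect_equal(oracle$status, 0)
    expect_equal(mine$status, "optimal")
    expect_lt(abs(mine$objval - oracle$obj), 1e-6)
  }
})

test_that("reaction_activity follows AND=min / OR=max semantics", {
  expect_equal(reaction_activity(parse_gpr("g1 and g2"), c(g1 = 0.5, g2 = 1.0)), 0.5)
  expect_equal(reaction_activity(parse_gpr("g1 or g2"), c(g1 = 0.5, g2 = 1.0)), 1.0)
  tree <- parse_gpr("(g1 and g2) or g3")
  expect_equal(reaction_activity(tree, c(g1 = 0.2, g2 = 0.8, g3 = 0.1)), 0.2)
  expect_equal(reaction_activity(tree, c(g1 = 0.2)), 1)       # missing default 1
  expect_equal(reaction_activity(NULL, c(g1 = 0)), 1)
  expect_equal(reaction_activity(parse_gpr("g1 or g2"), c(g1 = 0.5, g2 = 0.7),
                                 or_mode = "sum"), 1.2)
})

test_that("TRAME gates, scales and caps the flux envelope", {
  m <- chain_model()
  reg <- fx_tiny_model()
  # rename so the chain's enzyme is a model gene
  reg$genes <- c("TF1", "g1"); names(reg$beta0) <- reg$genes
  rownames(reg$beta) <- reg$genes
  names(reg$y_min) <- names(reg$y_max) <- names(reg$y_wt) <-
    names(reg$sigma_wt) <- reg$genes
  fb <- fva(m)

  # y_hat at WT: identity
  y <- reg$y_wt
  out <- trame_bounds(fb, m, y, reg)
  expect_equal(out, fb)

  # inside the n*sigma gate: still identity
  y2 <- reg$y_wt; y2["g1"] <- y2["g1"] + 0.15   # sigma 0.1, n = 2
  expect_equal(trame_bounds(fb, m, y2, reg), fb)

  # -1 log2 beyond the gate halves vmax
  y3 <- reg$y_wt; y3["g1"] <- y3["g1"] - 1
  out3 <- trame_bounds(fb, m, y3, reg)
  expect_equal(out3$vmax[out3$reaction == "R1"],
               fb$vmax[fb$reaction == "R1"] / 2)

  # +10 log2 is capped at p_cap
  y4 <- reg$y_wt; y4["g1"] <- y4["g1"] + 10
  fb3 <- fb; fb3$vmax[fb3$reaction == "R1"] <- 3
  out4 <- trame_bounds(fb3, m, y4, reg, params = list(n = 2, p_cap = 10))
  expect_equal(out4$vmax[out4$reaction == "R1"], 30)

  # n = Inf gates everything: identity for any profile
  expect_equal(trame_bounds(fb, m, y4, reg, params = list(n = Inf, p_cap = 10)), fb)

  # monotone: lower expression never widens any bound magnitude
  prev <- NULL
  for (shift in c(0, -1, -2, -4)) {
    yv <- reg$y_wt; yv["g1"] <- yv["g1"] + shift
    cur <- trame_bounds(fb, m, yv, reg)
    if (!is.null(prev)) {
      expect_true(all(abs(cur$vmax) <= abs(prev$vmax) + 1e-12))
      expect_true(all(abs(cur$vmin) <= abs(prev$vmin) + 1e-12))
    }
    prev <- cur
  }
})

test_that("essentiality separates single-path from OR-redundant enzymes", {
  fx <- fx_world()
  for (g in fx$met$truth$essential) {
    expect_equal(essentiality(fx$met$model, fx$model, NULL, g), "essential")
  }
  for (g in fx$met$truth$non_essential) {
    expect_equal(essentiality(fx$met$model, fx$model, NULL, g), "non_essential")
  }
  # gene with no metabolic or regulatory role
  idle <- setdiff(fx$model$genes, c(fx$met$truth$enzymes, fx$model$tf_set))[1]
  expect_equal(essentiality(fx$met$model, fx$model, NULL, idle), "non_essential")
  expect_error(essentiality(fx$met$model, fx$model, NULL, "nope"),
               "absent from regulatory model")
})
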