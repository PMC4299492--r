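test_that("generators are deterministic under a fixed seed", {
  g1 <- generate_trn(40, 6, seed = 8)
  g2 <- generate_trn(40, 6, seed = 8)
  expect_identical(g1, g2)
  expect_false(identical(g1$network, generate_trn(40, 6, seed = 9)$network))

  c1 <- simulate_compendium(g1$truth, n_wt = 4, noise_sd = 0.1, seed = 3)
  c2 <- simulate_compendium(g1$truth, n_wt = 4, noise_sd = 0.1, seed = 3)
  expect_identical(c1$values, c2$values)

  s1 <- generate_sts(g1$truth, 4, seed = 2)
  expect_identical(s1$entries, generate_sts(g1$truth, 4, seed = 2)$entries)
  expect_equal(nrow(generate_sts(g1$truth, 0, seed = 2)$entries), 0L)
})

test_that("the stated world holds: stability, signs, mid-range fixed point", {
  gen <- generate_trn(100, 12, seed = 21)
  tr <- gen$truth
  B_tt <- tr$beta[tr$tf_set, , drop = FALSE]
  expect_lt(max(Mod(eigen(B_tt, only.values = TRUE)$values)), 0.9)
  # coefficient signs respect edge annotation
  for (i in seq_len(nrow(gen$network))) {
    b <- tr$beta[gen$network$target[i], gen$network$regulator[i]]
    if (gen$network$sign[i] == "+") expect_gt(b, 0)
    if (gen$network$sign[i] == "-") expect_lt(b, 0)
  }
  expect_true(all(tr$y_star > 0 & tr$y_star < 14))
  # n_tfs = 1 gives a star (single regulator)
  star <- generate_trn(20, 1, mean_out_degree = 5, seed = 4)
  expect_equal(unique(star$network$regulator), star$truth$tf_set)
})

test_that("preferential attachment yields heavier degree tails than ER", {
  # out-degree overdispersion relative to a matched uniform-attachment draw
  ratios <- vapply(1:5, function(s) {
    pa <- generate_trn(200, 20, mean_out_degree = 5, seed = 600 + s)
    pa_deg <- table(factor(pa$network$regulator, levels = pa$truth$tf_set))
    er_deg <- with_seed(700 + s,
                        table(factor(sample(pa$truth$tf_set, nrow(pa$network),
                                            replace = TRUE),
                                     levels = pa$truth$tf_set)))
    var(as.numeric(pa_deg)) / max(var(as.numeric(er_deg)), 1e-9)
  }, 0)
  expect_gt(mean(ratios), 1.5)
})

test_that("noise-free WT arrays sit exactly at the fixed point", {
  gen <- generate_trn(30, 5, seed = 13)
  comp <- simulate_compendium(gen$truth, n_wt = 2, noise_sd = 0, seed = 1)
  expect_equal(comp$values[, 1], gen$truth$y_star, tolerance = 1e-10)
  expect_identical(comp$values[, 1], comp$values[, 2])

  # knockout override pins the gene at the floor in the emitted matrix
  sc <- perturbation_scenario(knockouts = gen$truth$genes[10])
  comp2 <- simulate_compendium(gen$truth, n_wt = 1, scenarios = list(sc),
                               noise_sd = 0, seed = 1)
  expect_equal(comp2$values[gen$truth$genes[10], 2], 0)
  expect_equal(comp2$meta$class[2], "genetic")
  expect_equal(comp2$meta$perturbed_genes[[2]], gen$truth$genes[10])
})

test_that("toy metabolic model records its own analytic truth", {
  gen <- generate_trn(50, 6, seed = 17)
  met0 <- generate_toy_metabolic_model(gen$truth, n_internal = 4,
                                       redundancy = 0, seed = 17)
  expect_equal(fba(met0$model)$growth, met0$truth$optimal_growth)
  expect_equal(length(met0$truth$non_essential), 0L)
  expect_setequal(met0$truth$essential,
                  unlist(lapply(met0$model$reactions, function(r)
                    gpr_genes(r$gpr_tree))))

  met1 <- generate_toy_metabolic_model(gen$truth, n_internal = 4,
                                       redundancy = 1, seed = 17)
  expect_equal(length(met1$truth$non_essential), 2L)
  # closing any essential reaction's bound kills growth; isozymes do not
  for (g in met1$truth$non_essential) {
    b <- model_bounds(met1$model)
    hit <- vapply(met1$model$reactions, function(r)
      g %in% gpr_genes(r$gpr_tree), logical(1))
    b$vmax[hit] <- 0
    expect_equal(fba(met1$model, b)$growth, met1$truth$optimal_growth)
  }
})

test_that("generated kappa signs drive the TF constraint in-direction", {
  gen <- generate_trn(40, 8, seed = 19)
  sys <- generate_sts(gen$truth, 6, seed = 19)
  m <- truth_to_model(gen$truth)
  expr <- sys$entries[sys$entries$type != "activity_only", ]
  for (i in seq_len(nrow(expr))) {
    v <- tf_expression_constraint(sys, m, expr$tf[i], expr$effector[i], 1)
    base <- m$y_wt[[expr$tf[i]]]
    if (expr$kappa[i] > 0) expect_gte(v, base) else expect_lte(v, base)
  }
})

test_that("generated artifacts feed the whole pipeline without id friction", {
  d <- withr::local_tempdir()
  gen <- generate_trn(40, 6, seed = 23)
  sys <- generate_sts(gen$truth, 3, seed = 23)
  met <- generate_toy_metabolic_model(gen$truth, seed = 23)
  scen <- lapply(gen$truth$tf_set, function(tf)
    perturbation_scenario(knockouts = tf))
  comp <- simulate_compendium(gen$truth, n_wt = 5, scenarios = scen,
                              noise_sd = 0.05, seed = 23, system = sys)
  write_network(gen$network, file.path(d, "net.tsv"))
  write_expression(comp, file.path(d, "e.tsv"), file.path(d, "m.tsv"))
  write_sts(sys, file.path(d, "sts.tsv"))
  write_metabolic_model(met$model, file.path(d, "met.json"))

  net <- read_network(file.path(d, "net.tsv"))
  comp2 <- read_expression(file.path(d, "e.tsv"), file.path(d, "m.tsv"))
  model <- fit_regulatory_model(net, comp2, ridge = 0)
  sys2 <- read_sts(file.path(d, "sts.tsv"))
  met2 <- read_metabolic_model(file.path(d, "met.json"))
  gp <- predict_growth(model, sys2, met2, perturbation_scenario())
  expect_gt(gp$mu, 0.8)
  aid <- comp2$meta$array_id[comp2$meta$class == "genetic"][1]
  pred <- predict_expression(model, sys2, perturbation_scenario(
    knockouts = comp2$meta$perturbed_genes[[match(aid, comp2$meta$array_id)]]))
  rec <- evaluate_array(pred$y_hat, comp2$values[, aid], comp2, net,
                        comp2$meta$perturbed_genes[[match(aid, comp2$meta$array_id)]],
                        n_null = 100, seed = 1, exclude_array = aid)
  expect_true(rec$well_predicted)
})
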