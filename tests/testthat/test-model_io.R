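test_that("read_network filters tiers, merges duplicates, rejects bad signs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("regulator\ttarget\tsign\tevidence",
               "tf1\tg1\t+\tconfirmed",
               "tf1\tg2\t-\tstrong",
               "tf2\tg1\t+\tweak"), f)
  expect_equal(nrow(read_network(f, "strong")), 2L)
  expect_equal(nrow(read_network(f, "weak")), 3L)

  # duplicate edge with conflicting signs collapses to +/-
  writeLines(c("tf1\tg1\t+\tstrong", "tf1\tg1\t-\tweak"), f)
  net <- read_network(f, "weak")
  expect_equal(nrow(net), 1L)
  expect_equal(net$sign, "+/-")
  expect_equal(net$evidence, "strong")   # best tier wins

  writeLines(c("tf1\tg1\tactivates\tstrong"), f)
  expect_error(read_network(f), "line 1.*activates")
})

test_that("evidence filtering is monotone over tiers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  with_seed(7, {
    n <- 30
    writeLines(sprintf("tf%d\tg%d\t%s\t%s", sample(5, n, TRUE), sample(20, n, TRUE),
                       sample(c("+", "-", "+/-"), n, TRUE),
                       sample(c("confirmed", "strong", "weak", "inferred"), n, TRUE)),
               f)
  })
  key <- function(net) paste(net$regulator, net$target)
  tiers <- c("confirmed", "strong", "weak", "inferred")
  nets <- lapply(tiers, function(t) suppressWarnings(read_network(f, t)))
  for (i in 1:3) expect_true(all(key(nets[[i]]) %in% key(nets[[i + 1]])))
})

test_that("network round-trips through TSV", {
  net <- fx_world()$gen$network
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  expect_equal(as.data.frame(read_network(f, "inferred")), as.data.frame(net))
})

test_that("read_expression joins metadata and flags bad input", {
  d <- withr::local_tempdir()
  mat <- file.path(d, "expr.tsv"); meta <- file.path(d, "meta.tsv")
  writeLines(c("gene_id\ta1\ta2", "g1\t1.5\t2.0", "g2\t3.0\t4.0", "g3\t5.0\t6.0"), mat)
  writeLines(c("array_id\tclass\tperturbation_kind\tperturbed_genes\teffectors",
               "a1\twild_type\tnone\t\t",
               "a2\tgenetic\tknockout\tg2\t"), meta)
  tab <- read_expression(mat, meta)
  expect_equal(dim(tab$values), c(3L, 2L))
  expect_equal(tab$meta$class, c("wild_type", "genetic"))
  expect_equal(tab$meta$perturbed_genes[[2]], "g2")

  # array missing from metadata defaults to wild_type with a warning
  writeLines(c("array_id\tclass\tperturbation_kind\tperturbed_genes\teffectors",
               "a1\twild_type\tnone\t\t"), meta)
  expect_warning(tab2 <- read_expression(mat, meta), "a2")
  expect_equal(tab2$meta$class[2], "wild_type")

  writeLines(c("gene_id\ta1\ta2", "g1\t1.5\tNA", "g2\t3.0\t4.0", "g3\t1\t1"), mat)
  expect_error(suppressWarnings(read_expression(mat, meta)), "g1.*a2")

  writeLines(c("gene_id\ta1\ta2", "g1\t1\t2", "g1\t3\t4", "g3\t1\t1"), mat)
  expect_error(suppressWarnings(read_expression(mat, meta)), "duplicate gene")
})

test_that("expression table round-trips with metadata intact", {
  comp <- fx_world()$compendium
  d <- withr::local_tempdir()
  write_expression(comp, file.path(d, "e.tsv"), file.path(d, "m.tsv"))
  back <- read_expression(file.path(d, "e.tsv"), file.path(d, "m.tsv"))
  expect_equal(back$values, comp$values, tolerance = 1e-9)
  expect_equal(back$meta$class, comp$meta$class)
  expect_equal(back$meta$perturbed_genes, comp$meta$perturbed_genes,
               ignore_attr = TRUE)
})

test_that("GPR parsing produces the documented trees and rejects garbage", {
  tree <- parse_gpr("(g1 and g2) or g3")
  expect_equal(tree$op, "or")
  expect_equal(tree$args[[1]]$op, "and")
  expect_equal(tree$args[[1]]$args[[1]]$gene, "g1")
  expect_equal(tree$args[[2]]$gene, "g3")
  expect_setequal(gpr_genes(tree), c("g1", "g2", "g3"))
  expect_null(parse_gpr(""))
  expect_error(parse_gpr("g1 and"), "parse error")
  expect_error(parse_gpr("(g1 or g2"), "parse error")
})

test_that("metabolic model JSON round-trips and validates", {
  model <- fx_diamond()
  f <- withr::local_tempfile(fileext = ".json")
  write_metabolic_model(model, f)
  back <- read_metabolic_model(f)
  expect_equal(length(back$reactions), 4L)
  expect_equal(back$biomass, "BIO")
  expect_equal(reaction_ids(back), reaction_ids(model))
  for (i in seq_along(model$reactions)) {
    expect_equal(back$reactions[[i]]$stoich, model$reactions[[i]]$stoich)
    expect_equal(back$reactions[[i]]$lb, model$reactions[[i]]$lb)
  }

  expect_error(metabolic_model("A", list(list(id = "R1", stoich = c(A = 1),
                                              lb = 5, ub = 2, gpr = "")),
                               biomass = "R1"), "lower bound")
  expect_error(metabolic_model("A", list(list(id = "R1", stoich = c(ZZ = 1),
                                              lb = 0, ub = 2, gpr = "")),
                               biomass = "R1"), "undeclared metabolite")
})

test_that("minimal SBML reader agrees with the JSON dialect", {
  sbml <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
 <model id="toy">
  <listOfParameters>
   <parameter id="lb0" value="0"/><parameter id="ub10" value="10"/>
   <parameter id="ub1000" value="1000"/>
  </listOfParameters>
  <listOfSpecies>
   <species id="A"/><species id="B"/>
  </listOfSpecies>
  <listOfGeneProducts xmlns="http://www.sbml.org/sbml/level3/version1/fbc/version2">
   <geneProduct id="G_g1" label="g1"/><geneProduct id="G_g2" label="g2"/>
  </listOfGeneProducts>
  <listOfReactions>
   <reaction id="EX_A" lowerFluxBound="lb0" upperFluxBound="ub10">
    <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>
   </reaction>
   <reaction id="R1" lowerFluxBound="lb0" upperFluxBound="ub10">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>
    <geneProductAssociation>
     <or><geneProductRef geneProduct="G_g1"/><geneProductRef geneProduct="G_g2"/></or>
    </geneProductAssociation>
   </reaction>
   <reaction id="BIO" lowerFluxBound="lb0" upperFluxBound="ub1000">
    <listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>
   </reaction>
  </listOfReactions>
  <listOfObjectives>
   <objective id="obj"><listOfFluxObjectives>
    <fluxObjective reaction="BIO" coefficient="1"/>
   </listOfFluxObjectives></objective>
  </listOfObjectives>
 </model>
</sbml>', sbml)
  model <- read_sbml_model(sbml)
  expect_equal(reaction_ids(model), c("EX_A", "R1", "BIO"))
  expect_equal(model$biomass, "BIO")
  expect_equal(model$reactions[[2]]$stoich, c(A = -1, B = 1))
  expect_setequal(gpr_genes(model$reactions[[2]]$gpr_tree), c("g1", "g2"))
  expect_equal(fba(model)$growth, 10)
})

test_that("GO annotation round-trips", {
  ann <- fx_world()$annotation
  f <- withr::local_tempfile(fileext = ".tsv")
  write_go_annotation(ann, f)
  back <- read_go_annotation(f)
  expect_equal(names(back$terms), names(ann$terms))
  expect_equal(back$terms[[3]]$genes, ann$terms[[3]]$genes)
  expect_equal(back$universe, ann$universe)
})

test_that("regulatory model serialization round-trips", {
  m <- fx_exact()$model
  f <- withr::local_tempfile(fileext = ".json")
  write_regulatory_model(m, f)
  back <- read_regulatory_model(f)
  expect_equal(back$genes, m$genes)
  expect_equal(back$beta0, m$beta0)
  expect_equal(as.matrix(back$beta), as.matrix(m$beta), tolerance = 1e-12)
  expect_equal(back$y_wt, m$y_wt)
})

test_that("scenario JSON round-trips", {
  sc <- perturbation_scenario(knockouts = "g1", overexpressions = "g2",
                              rewirings = data.frame(target = "g3", donor = "g4"),
                              effectors = data.frame(id = "eff1", delta = -1.5),
                              exchange_overrides = data.frame(reaction = "EX_A",
                                                              lb = 0, ub = 3))
  f <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, f)
  back <- read_scenario(f)
  expect_equal(back$knockouts, "g1")
  expect_equal(back$rewirings$donor, "g4")
  expect_equal(back$effectors$delta, -1.5)
  expect_equal(back$exchange_overrides$ub, 3)
})
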