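test_that("herb litter input converts frame harvests to areal carbon", {
  s <- data.frame(dry_mass_g = 100, frame_area_m2 = 0.25,
                  compartment = "herb")
  # 100 g * 0.475 / 0.25 m2 = 190 g C m-2 = 1.9 t C ha-1
  expect_equal(herb_litter_input(s)$mean, 1.9, tolerance = 1e-12)
  s$dry_mass_g <- 0
  expect_equal(herb_litter_input(s)$mean, 0)
  s$dry_mass_g <- 100
  expect_equal(herb_litter_input(s, c_fraction = 1)$mean, 4,
               tolerance = 1e-12)  # identity fraction: dry areal density
  s$compartment <- "fine_root"
  expect_error(herb_litter_input(s), "compartment")
})

test_that("tree litter input scales collector catches to annual areal carbon", {
  area <- pi * 0.34^2
  expect_equal(area, 0.3632, tolerance = 1e-4)
  # 130.7 g C per collector -> 261.4 g dry at 50% C
  s <- data.frame(dry_mass_g = 261.4, compartment = "tree_litter")
  expect_equal(tree_litter_input(s)$mean, 3.6, tolerance = 1e-2)
  s$dry_mass_g <- 0
  expect_equal(tree_litter_input(s)$mean, 0)
  expect_error(tree_litter_input(s, collector_area_m2 = 0), "positive")
})

test_that("root litter input is stock times turnover", {
  expect_equal(root_litter_input(0.79, 0.8), 0.632, tolerance = 1e-12)
  expect_equal(round(root_litter_input(0.79, 0.8), 1), 0.6)
  expect_equal(round(root_litter_input(1.56, 0.8), 1), 1.2)
  expect_equal(root_litter_input(1.2, 0), 0)
  expect_error(root_litter_input(-1, 0.8), "non-negative")
})

test_that("NEP closes the budget and is monotone in its terms", {
  expect_equal(compute_nep(rh = 5.0, biomass_increment = 3.8,
                           tree_litter = 1.8, herb_litter = 0.3,
                           root_litter = 1.2), 2.1, tolerance = 1e-12)
  expect_equal(compute_nep(rh = 7.0, herb_litter = 1.2, root_litter = 0.3),
               -5.5, tolerance = 1e-12)
  expect_equal(compute_nep(rh = 0), 0)
  expect_error(compute_nep(rh = NULL), "required")
  set.seed(5)
  for (i in 1:30) {
    x <- runif(5, 0, 6)
    nep <- compute_nep(rh = x[1], biomass_increment = x[2],
                       tree_litter = x[3], herb_litter = x[4],
                       root_litter = x[5])
    # exact closure
    expect_equal(nep + x[1] - x[2] - x[3] - x[4] - x[5], 0,
                 tolerance = 1e-12)
    # decreasing in rh, increasing in inputs
    expect_lt(compute_nep(x[1] + 1, x[2], x[3], x[4], x[5]), nep)
    expect_gt(compute_nep(x[1], x[2] + 1, x[3], x[4], x[5]), nep)
  }
})

test_that("budget assembly enforces conservation and names missing components", {
  rs <- list(A = 9, B = 8)
  parts <- list(A = partition_estimate(40, "trenching"),
                B = partition_estimate(20, "clipping"))
  lit <- list(A = list(tree = 1.5, herb = 0.3, root = 1),
              B = list(tree = 0, herb = 1, root = 0.4))
  b <- assemble_budget(c("A", "B"), rs, parts, lit,
                       increments = list(A = 3.5))
  expect_s3_class(b, "carbon_budget")
  expect_equal(nrow(b), 2)
  expect_identical(b$ra + b$rh, b$rs_annual)
  expect_equal(b$biomass_increment, c(3.5, 0))
  expect_error(assemble_budget(c("A", "B"), rs, parts["A"], lit),
               "partition estimate for section 'B'")
  expect_error(assemble_budget(c("A", "B"), rs["A"], parts, lit),
               "soil respiration for section 'B'")
})

test_that("report rounding happens only at the formatting layer", {
  rs <- list(A = 8.88)
  parts <- list(A = 44.4)
  lit <- list(A = list(tree = 1.76, herb = 0.32, root = 1.248))
  b <- assemble_budget("A", rs, parts, lit, increments = list(A = 3.8))
  expect_equal(b$rs_annual, 8.88)  # unrounded in the budget object
  tab <- format_budget_table(b)
  expect_equal(tab$A[tab$component == "Soil respiration Rs [t C/ha/yr]"], 8.9)
  expect_equal(tab$A[tab$component == "Autotrophic [%]"], 44)
})
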