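test_that("single-pair ratios and accessibility match hand evaluation", {
  dem <- demand_sites(data.frame(site_id = "r1", x = 0, y = 0, population = 100))
  sup <- supply_sites(data.frame(site_id = "p1", x = 0, y = 0,
                                 supply_scale = 10, weight = 2))
  cm <- cost_matrix(matrix(0, 1, 1), mode = "walk",
                    demand_ids = "r1", supply_ids = "p1")
  dec <- decay_spec("gaussian", 39)
  r <- supply_demand_ratios(dem, sup, cm, dec)
  expect_equal(unname(r), 10 * 2 / 100)
  # second step: A = R * G(0) = S*W/D
  a <- accessibility(dem, sup, cm, dec)
  expect_equal(unname(a$values), 0.2)

  # without weights the ratio drops W
  r0 <- supply_demand_ratios(dem, sup, cm, dec, use_weights = FALSE)
  expect_equal(unname(r0), 0.1)
})

test_that("a park beyond the threshold has an empty catchment and ratio 0", {
  dem <- demand_sites(data.frame(site_id = "r1", x = 0, y = 0, population = 100))
  sup <- supply_sites(data.frame(site_id = "p1", x = 0, y = 0,
                                 supply_scale = 10, weight = 2))
  cm <- cost_matrix(matrix(50, 1, 1), mode = "walk",
                    demand_ids = "r1", supply_ids = "p1")
  dec <- decay_spec("gaussian", 39)
  expect_warning(r <- supply_demand_ratios(dem, sup, cm, dec), "empty catchment")
  expect_identical(unname(r), 0)
  suppressWarnings(a <- accessibility(dem, sup, cm, dec))
  expect_identical(unname(a$values), 0)
})

test_that("duplicating a supply site doubles accessibility (additivity)", {
  dem <- demand_sites(data.frame(site_id = "r1", x = 0, y = 0, population = 2))
  sup1 <- supply_sites(data.frame(site_id = "p1", x = 0, y = 0,
                                  supply_scale = 4, weight = 1))
  sup2 <- supply_sites(data.frame(site_id = c("p1", "p2"), x = 0, y = 0,
                                  supply_scale = 4, weight = 1))
  dec <- decay_spec("gaussian", 39)
  a1 <- accessibility(dem, sup1,
                      cost_matrix(matrix(0, 1, 1), "m", demand_ids = "r1",
                                  supply_ids = "p1"), dec)
  a2 <- accessibility(dem, sup2,
                      cost_matrix(matrix(0, 1, 2), "m", demand_ids = "r1",
                                  supply_ids = c("p1", "p2")), dec)
  expect_equal(unname(a1$values), 2)
  expect_equal(unname(a2$values), 4)
})

test_that("engine equals the literal double-loop oracle on random instances", {
  set.seed(101)
  for (rep in 1:10) {
    inst <- random_instance(sample(5:50, 1), sample(2:10, 1), max_cost = 60)
    dec <- decay_spec("gaussian", 39)
    got <- accessibility(inst$demand, inst$supply, inst$costs, dec)
    want <- fca_oracle(inst$demand, inst$supply, inst$costs, 39, "gaussian")
    expect_equal(got$ratios, want$ratios, tolerance = 1e-12)
    expect_equal(got$values, want$values, tolerance = 1e-12)
  }
})

test_that("unit weights with indicator decay reduce to classic 2SFCA", {
  dec <- decay_spec("indicator", 39)
  got <- accessibility(toy_demand(), toy_supply(), toy_costs(), dec,
                       use_weights = FALSE)
  # hand-computed: R_p1 = 10/(100+200), R_p2 = 20/(200+300)
  expect_equal(got$ratios, c(p1 = 1 / 30, p2 = 0.04), tolerance = 1e-15)
  expect_equal(got$values,
               c(r1 = 1 / 30, r2 = 1 / 30 + 0.04, r3 = 0.04),
               tolerance = 1e-15)
})

test_that("all-unit weights equal the unweighted model on the same inputs", {
  set.seed(77)
  inst <- random_instance(20, 5)
  sup1 <- inst$supply
  sup1$weight <- rep(1, nrow(sup1))
  dec <- decay_spec("gaussian", 39)
  expect_equal(accessibility(inst$demand, sup1, inst$costs, dec,
                             use_weights = TRUE)$values,
               accessibility(inst$demand, sup1, inst$costs, dec,
                             use_weights = FALSE)$values)
})

test_that("conservation: total weighted accessibility equals total weighted supply", {
  set.seed(5)
  for (kind in c("gaussian", "indicator")) {
    for (uw in c(TRUE, FALSE)) {
      inst <- random_instance(40, 8, max_cost = 35) # all catchments nonempty
      dec <- decay_spec(kind, 39)
      a <- accessibility(inst$demand, inst$supply, inst$costs, dec, uw)
      lhs <- sum(inst$demand$population * a$values)
      rhs <- sum(inst$supply$supply_scale *
                   (if (uw) inst$supply$weight else 1))
      expect_equal(lhs, rhs, tolerance = 1e-9)
    }
  }
})

test_that("accessibility is homogeneous in weights and inverse in populations", {
  set.seed(9)
  inst <- random_instance(25, 6)
  dec <- decay_spec("gaussian", 39)
  base <- accessibility(inst$demand, inst$supply, inst$costs, dec)$values
  supc <- inst$supply; supc$weight <- supc$weight * 3
  expect_equal(accessibility(inst$demand, supc, inst$costs, dec)$values,
               3 * base, tolerance = 1e-12)
  demc <- inst$demand; demc$population <- demc$population * 4
  expect_equal(accessibility(demc, inst$supply, inst$costs, dec)$values,
               base / 4, tolerance = 1e-12)
})

test_that("raising one park's weight never hurts, and helps only inside its catchment", {
  set.seed(13)
  inst <- random_instance(30, 5, max_cost = 80) # some pairs beyond threshold
  dec <- decay_spec("gaussian", 39)
  base <- suppressWarnings(
    accessibility(inst$demand, inst$supply, inst$costs, dec)$values)
  j <- 3
  supc <- inst$supply
  supc$weight[j] <- supc$weight[j] * 2
  bumped <- suppressWarnings(
    accessibility(inst$demand, supc, inst$costs, dec)$values)
  g <- gaussian_decay(unclass(inst$costs)[, j], 39)
  inside <- g > 0
  expect_true(all(bumped >= base - 1e-12))
  expect_true(all(bumped[inside] > base[inside]))
  expect_equal(bumped[!inside], base[!inside], tolerance = 1e-12)
})

test_that("combine_modes takes convex combinations with mode-share weights", {
  ids <- c("a", "b")
  mk <- function(v, mode) {
    parkaccess:::accessibility_field(setNames(v, ids), mode = mode)
  }
  mix4 <- mode_mix(c("m1", "m2", "m3", "m4"), rep(0.25, 4))
  fields <- list(m1 = mk(c(1, 5), "m1"), m2 = mk(c(2, 5), "m2"),
                 m3 = mk(c(3, 5), "m3"), m4 = mk(c(4, 5), "m4"))
  comb <- combine_modes(fields, mix4)
  expect_equal(unname(comb$values), c(2.5, 5))
  # combined value bounded by per-mode min/max
  expect_true(all(comb$values >= 1 & comb$values <= 5))

  # urban mode split: driving share alone
  mix <- default_mode_mix()
  f2 <- list(driving = mk(c(1, 1), "driving"), transit = mk(c(0, 0), "transit"),
             riding = mk(c(0, 0), "riding"), walking = mk(c(0, 0), "walking"))
  expect_equal(unname(combine_modes(f2, mix)$values), c(0.257, 0.257))

  expect_error(combine_modes(f2[1:3], mix), "no accessibility field")
})

test_that("multimodal pipeline reduces to single-mode and respects convexity", {
  set.seed(21)
  inst <- random_instance(20, 4)
  dec <- decay_spec("gaussian", 39)
  one <- run_scm_g2sfca(inst$demand, inst$supply, list(test = inst$costs),
                        dec, mode_mix("test", 1))
  expect_equal(one$combined$values,
               accessibility(inst$demand, inst$supply, inst$costs, dec)$values)
  # identical matrices for every mode: combined equals the single-mode field
  mix <- default_mode_mix()
  costs <- lapply(setNames(mix$modes, mix$modes), function(m) {
    cost_matrix(unclass(inst$costs), mode = m,
                demand_ids = inst$demand$site_id,
                supply_ids = inst$supply$site_id)
  })
  multi <- run_scm_g2sfca(inst$demand, inst$supply, costs, dec, mix)
  expect_equal(multi$combined$values, one$combined$values, tolerance = 1e-12)
  # per-mode ratios retained
  expect_named(multi$per_mode, mix$modes)
  expect_length(multi$per_mode$driving$ratios, 4)
  expect_error(run_scm_g2sfca(inst$demand, inst$supply, costs[-1], dec, mix),
               "missing cost matrix")
})

test_that("dimension and id mismatches are rejected", {
  inst <- random_instance(5, 3)
  dec <- decay_spec("gaussian", 39)
  bad <- cost_matrix(matrix(1, 4, 3), "m",
                     demand_ids = sprintf("d%03d", 1:4),
                     supply_ids = inst$supply$site_id)
  expect_error(accessibility(inst$demand, inst$supply, bad, dec), "5 demand")
  badnames <- cost_matrix(matrix(1, 5, 3), "m",
                          demand_ids = sprintf("x%03d", 1:5),
                          supply_ids = inst$supply$site_id)
  expect_error(accessibility(inst$demand, inst$supply, badnames, dec),
               "dimnames")
  expect_error(demand_sites(data.frame(site_id = "a", x = 0, y = 0,
                                       population = -1)), "population")
})

test_that("mode shares renormalize with a warning when off by more than 1e-6", {
  expect_warning(mm <- mode_mix(c("a", "b"), c(30, 70)), "renormalizing")
  expect_equal(mm$shares, c(0.3, 0.7))
  expect_silent(mode_mix(c("a", "b"), c(0.3, 0.7)))
  expect_error(mode_mix(c("a", "a"), c(0.5, 0.5)), "duplicate")
})
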