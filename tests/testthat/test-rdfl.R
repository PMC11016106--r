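test_that("urban probability follows the population-density law", {
  expect_equal(urban_probability(0), 1)
  expect_equal(urban_probability(9), 1 - 0.333 * log10(10))  # 0.667
  expect_equal(urban_probability(1500), 0)
  expect_equal(urban_probability(1000), 0)                   # cutoff inclusive
  # near-continuity at the cutoff under base-10 log
  expect_lt(urban_probability(999.99), 2e-3)
  expect_error(urban_probability(-1), ">= 0")
  # monotone non-increasing
  pd <- sort(runif(50, 0, 2000))
  expect_true(all(diff(urban_probability(pd)) <= 1e-12))
})

test_that("causal attribution is a step window of half-width five years", {
  expect_equal(causal_attribution(0), 1)
  expect_equal(causal_attribution(3), 1)
  expect_equal(causal_attribution(-5), 1)
  expect_equal(causal_attribution(5), 1)
  expect_equal(causal_attribution(7), 0)
  expect_equal(causal_attribution(-6), 0)
  w <- causal_window(half_width = 2, outside_value = 0.25)
  expect_equal(causal_attribution(3, w), 0.25)
})

test_that("wildfire and landcover probabilities multiply per event", {
  expect_equal(wildfire_probability(2010, integer()), 1)
  expect_equal(wildfire_probability(2010, 2008), 0)    # dt = 2 inside window
  expect_equal(wildfire_probability(2015, 2001), 1)    # dt = 14 outside
  expect_equal(wildfire_probability(2010, c(2001, 2019)), 1)
  expect_equal(wildfire_probability(2010, c(2001, 2012)), 0)
  expect_equal(landcover_probability(2012, 2009), 0)
  expect_equal(landcover_probability(2019, 2001), 1)
  expect_equal(landcover_probability(2012, integer()), 1)
  # each extra in-window event can only decrease the probability
  w <- causal_window(inside_value = 0.6)
  p1 <- wildfire_probability(2010, 2010, w)
  p2 <- wildfire_probability(2010, c(2010, 2011), w)
  expect_lte(p2, p1)
})

test_that("anthropic transitions are exactly the three human-driven changes", {
  expect_equal(nrow(anthropic_transitions(rep("NHV", 19))), 0)
  h <- c(rep("NHV", 10), rep("AN", 9))
  tr <- anthropic_transitions(h)
  expect_equal(tr$year, 2011)
  expect_equal(tr$from, "NHV"); expect_equal(tr$to, "AN")
  # reverse (recovery) transitions are river-driven, not anthropic
  expect_equal(nrow(anthropic_transitions(c("NLV", "NHV", "NHV"))), 0)
  expect_equal(nrow(anthropic_transitions(c("AN", "NHV"))), 0)
  expect_equal(nrow(anthropic_transitions(c("UV", "NHV", "UV"))), 0)
  tr2 <- anthropic_transitions(c("NHV", "NLV", "AN"))
  expect_equal(tr2$year, c(2002, 2003))
  expect_error(anthropic_transitions(c("NHV", "XX")), "macro-class")
})

test_that("IGBP mapping is total over the 17 classes and matches the groups", {
  m <- macroclass_mapping()
  expect_setequal(names(m), as.character(1:17))
  expect_equal(unname(m[c("2", "6", "10", "11")]), rep("NHV", 4))
  expect_equal(unname(m[c("8", "9")]), rep("NLV", 2))
  expect_equal(unname(m[c("12", "13", "14")]), rep("AN", 3))
  expect_equal(unname(m[c("15", "16", "17")]), rep("UV", 3))
  # file round trip
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# mapping", paste(names(m), m)), f)
  expect_identical(read_macroclass_mapping(f), m)
})

test_that("combined probability map honors the scene's causal structure", {
  sc <- mixed_scene(seed = 7)
  pm <- combine_probabilities(sc$loss_year, sc$pop_density, sc$fire_years,
                              sc$landcover)
  expect_true(all(pm$p_combined >= 0 & pm$p_combined <= 1))
  expect_true(all(pm$p_combined[sc$loss_year$values == 0] == 0))
  expect_equal(mean(pm$p_combined[sc$truth_cause == "river"]), 1)
  expect_equal(max(pm$p_combined[sc$truth_cause %in%
                                   c("urban", "wildfire", "landcover")]), 0)
  # product never exceeds any factor
  expect_true(all(pm$p_combined <= pm$p_urban + 1e-12))
  expect_true(all(pm$p_combined <= pm$p_wildfire + 1e-12))
  expect_true(all(pm$p_combined <= pm$p_landcover + 1e-12))
})

test_that("coarse confounder layers are expanded by containing-block lookup", {
  sp <- grid_spec(4, 4, 30)
  ly <- matrix(0L, 4, 4); ly[2, 2] <- 2010L; ly[3, 3] <- 2010L
  pd_coarse <- matrix(c(2000, 0, 0, 0), 2, 2)  # top-left block urbanized
  fires <- array(0L, c(4, 4, 20), dimnames = list(NULL, NULL, 2000:2019))
  lc <- array("NHV", c(4, 4, 19), dimnames = list(NULL, NULL, 2001:2019))
  pm <- combine_probabilities(ly, pd_coarse, fires, lc)
  expect_equal(pm$p_combined[2, 2], 0)   # inherits the coarse PD block
  expect_equal(pm$p_combined[3, 3], 1)
})

test_that("rdfl_area converts probability into annual area correctly", {
  sp <- grid_spec(10, 10, 30)
  p <- matrix(0, 10, 10)
  expect_equal(rdfl_area(p, sp)$a_rdfl, 0)
  p[5, 5] <- 1
  ra <- rdfl_area(p, sp, T_years = 20)
  expect_equal(ra$L[5, 5], 9e-4 / 20)    # 4.5e-5 km^2/yr
  expect_equal(ra$a_rdfl, 4.5e-5)
  # brute-force summation oracle on a random map
  p <- matrix(runif(100), 10, 10)
  ra <- rdfl_area(p, sp, T_years = 20)
  expect_equal(ra$a_rdfl, sum(9e-4 * p / 20), tolerance = 1e-12)
  expect_error(rdfl_area(p, sp, T_years = 0), "T_years")
})
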