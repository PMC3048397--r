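toy_net <- function() {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("1,0", "1,1"), tf)
  read_incidence(tf)
}

test_that("analyze_network wires the side-specific null models correctly", {
  rec <- analyze_network(toy_net(), name = "toy", trials = 300, seed = 1)
  # both sides: support = opposite side size 2, mean = 3/2
  expect_equal(rec$S_P, 2)
  expect_equal(rec$S_A, 2)
  expect_equal(rec$L, 3)
  expect_equal(rec$size_class, "small")
  expect_s3_class(rec$plant_fit, "maxent_fit")
  expect_s3_class(rec$animal_fit, "maxent_fit")
  df <- as.data.frame(rec)
  expect_equal(nrow(df), 2)
  expect_setequal(df$side, c("plant", "animal"))
})

test_that("size classes split at 135 and 140 taxa", {
  expect_equal(bimaxent:::size_class(134), "small")
  expect_equal(bimaxent:::size_class(135), "excluded")
  expect_equal(bimaxent:::size_class(140), "excluded")
  expect_equal(bimaxent:::size_class(141), "large")
})

test_that("null-drawn animal distributions are usually classified good", {
  # only the animal side is MaxEnt by construction; the generator's plant
  # side is emergent (binomial-like) and is not asserted here
  nets <- lapply(1:30, function(s) generate_network(40, 40, 0.15, seed = 300 + s))
  names(nets) <- paste0("null", 1:30)
  recs <- survey_networks(nets, trials = 600, seed = 7)
  df <- as.data.frame(recs)
  expect_gte(mean(df$good_fit[df$side == "animal"]), 0.85)
})

test_that("an injected super-generalist broadens the animal distribution", {
  set.seed(12)
  w <- replicate(12, {
    net <- generate_network(50, 60, 0.12, mode = "hub_injected",
                            mode_params = list(hub_degree_fraction = 0.85))
    rec <- analyze_network(net, trials = 800)
    rec$animal_fit$W95
  })
  expect_gt(mean(w > 0), 0.8)  # consistently broader than the null
  expect_gt(mean(w), 0.3)
})

test_that("surveys are reproducible and tabulate into strata correctly", {
  nets <- lapply(1:6, function(s) generate_network(15, 15, 0.25, seed = s))
  names(nets) <- paste0("n", 1:6)
  r1 <- survey_networks(nets, trials = 200, seed = 5)
  r2 <- survey_networks(nets, trials = 200, seed = 5)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  tab <- tabulate_fits(r1, stratify_by = "web_type")
  expect_setequal(tab$side, c("plant", "animal"))
  expect_true(all(tab$n == 6))
  expect_equal(tab$fraction, tab$good / tab$n)
})

test_that("stratum fractions reproduce known good/total ratios exactly", {
  # records engineered so 43 of 51 plant-side fits are good
  fake_fit <- function(good) structure(
    list(f_G = if (good) 0.5 else 0.99, W = 0, W95 = 0, trials = 1L,
         seed = 1L, good_fit = good), class = "maxent_fit")
  recs <- lapply(1:51, function(i) structure(
    list(name = paste0("m", i), web_type = "mutualistic", S = 30, S_P = 15,
         S_A = 15, L = 60, C_B = 60 / 225, size_class = "small",
         plant_fit = fake_fit(i <= 43), animal_fit = fake_fit(i <= 41)),
    class = "survey_record"))
  tab <- tabulate_fits(structure(recs, class = "survey_records"),
                       stratify_by = "web_type")
  pl <- tab[tab$side == "plant", ]
  an <- tab[tab$side == "animal", ]
  expect_equal(pl$good, 43)
  expect_equal(round(pl$fraction, 2), 0.84)
  expect_equal(round(an$fraction, 2), 0.80)
})

test_that("Fisher exact matches full enumeration for small margins", {
  set.seed(30)
  for (r in 1:25) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    expect_equal(fisher_exact_2x2(a, b, c_, d),
                 fisher_enum_oracle(a, b, c_, d), tolerance = 1e-9,
                 label = sprintf("table (%d,%d;%d,%d)", a, b, c_, d))
  }
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "margin")
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("binomial sign test gives exact tail probabilities", {
  expect_equal(binomial_sign_test(5, 5), 1 / 32)
  expect_equal(binomial_sign_test(13, 17), sum(choose(17, 13:17)) / 2^17)
  expect_equal(binomial_sign_test(4, 8, tail = "two"), 1)
  expect_equal(binomial_sign_test(0, 6, tail = "one"), 1)
  expect_error(binomial_sign_test(9, 8), "k <= n")
})

test_that("W95-vs-S regression recovers known geometry", {
  fake_rec <- function(name, S, W95p) structure(
    list(name = name, web_type = "synthetic", S = S, S_P = S / 2, S_A = S / 2,
         L = S, C_B = 0.1, size_class = "small",
         plant_fit = structure(list(f_G = 0.5, W = 0, W95 = W95p,
                                    trials = 1L, seed = 1L, good_fit = TRUE),
                               class = "maxent_fit"),
         animal_fit = structure(list(f_G = 0.5, W = 0, W95 = 0, trials = 1L,
                                     seed = 1L, good_fit = TRUE),
                                class = "maxent_fit")),
    class = "survey_record")
  # collinear points -> R2 = 1
  rc <- structure(lapply(1:4, function(i) fake_rec(paste0("c", i), 10 * i,
                                                   2 * i)),
                  class = "survey_records")
  expect_equal(suppressWarnings(regress_w95_on_S(rc, side = "plant"))$R2, 1,
               tolerance = 1e-12)
  # points (1,1), (2,2), (3,2): R2 = 0.75 by closed-form OLS
  rt <- structure(list(fake_rec("a", 1, 1), fake_rec("b", 2, 2),
                       fake_rec("c", 3, 2)), class = "survey_records")
  fit <- regress_w95_on_S(rt, side = "plant")
  expect_equal(fit$R2, 0.75, tolerance = 1e-12)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_error(regress_w95_on_S(structure(list(fake_rec("a", 1, 1)),
                                          class = "survey_records"),
                                side = "plant"), "at least 3")
})

test_that("regression p-values are calibrated when W95 is independent of S", {
  fake_rec <- function(name, S, W95a) structure(
    list(name = name, web_type = "synthetic", S = S, S_P = S / 2, S_A = S / 2,
         L = S, C_B = 0.1, size_class = "small",
         plant_fit = structure(list(f_G = 0.5, W = 0, W95 = 0, trials = 1L,
                                    seed = 1L, good_fit = TRUE),
                               class = "maxent_fit"),
         animal_fit = structure(list(f_G = 0.5, W = 0, W95 = W95a,
                                     trials = 1L, seed = 1L, good_fit = TRUE),
                                class = "maxent_fit")),
    class = "survey_record")
  set.seed(60)
  Ss <- seq(20, 120, length.out = 12)
  ps <- replicate(200, {
    recs <- structure(mapply(fake_rec, paste0("r", seq_along(Ss)), Ss,
                             rnorm(12), SIMPLIFY = FALSE),
                      class = "survey_records")
    regress_w95_on_S(recs, side = "animal")$p_slope
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
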