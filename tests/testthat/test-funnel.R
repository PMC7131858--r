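test_that("one-decimal percentages use half-up rounding", {
  expect_equal(percent(5615, 22289), 25.2)
  expect_equal(percent(544, 2342), 23.2)
  expect_equal(percent(0, 7), 0)
  expect_equal(percent(1, 8), 12.5)
  # half-up, not banker's: 0.25% rounds to 0.3%
  expect_equal(percent(1, 400), 0.3)
  expect_equal(percent(3, 400), 0.8)
  expect_error(percent(1, 0), "denominator")
  expect_error(percent(-1, 10), "negative")
})

test_that("percent agrees with exact rational half-up on random pairs", {
  set.seed(97)
  d <- sample(1:1e6, 400, replace = TRUE)
  n <- vapply(d, function(x) sample(0:x, 1), 1L)
  got <- percent(n, d)
  # independent integer derivation: quotient and remainder of 1000 n / d
  q <- (1000 * n) %/% d
  r <- (1000 * n) %% d
  want <- (q + (2 * r >= d)) / 10
  expect_equal(got, want)
})

test_that("age bands are disjoint and exhaustive", {
  expect_identical(age_band(c(34, 35, 44, 45, 74), scheme = "spoke"),
                   c("<35", "35-39", "40-44", "45-49", "70-74"))
  expect_identical(age_band(c(24, 25, 29), scheme = "fine"),
                   c("<25", "25-29", "25-29"))
  ages <- 18:74
  bands <- age_band(ages, scheme = "spoke")
  expect_false(anyNA(bands))
  expect_identical(length(unique(bands)), 9L)
})

test_that("an empty-history record stops at the first stage", {
  res <- run_pipeline(list(list(pedigree = ped_trio(), source = "gp")),
                      funnel_params(seed = 4))
  st <- res$stats$stages
  expect_identical(st$count[st$stage == "records"], 1L)
  expect_true(all(st$count[st$stage != "records"] == 0L))
  expect_identical(res$decisions$basis, "none")
})

test_that("a hand-counted fixture population reproduces its stage counts", {
  # 10 records: 3 empty-history, 3 spoke-eligible (mother BC 38) with known
  # risk ratios 1.5 / 2.5 / 3.5, 3 hub-direct (proband BC 34, alive), and
  # 1 spoke-eligible that only reaches profile 2
  mk_spoke <- function(ratio) list(pedigree = ped_trio(
    list(diagnosis("breast", 38))), source = "specialist",
    risk_ratio = ratio)
  mk_direct <- function() {
    ped <- pedigree(list(
      individual("p", "female", age = 40, alive = "yes",
                 diagnoses = list(diagnosis("breast", 34)))),
      proband_id = "p")
    list(pedigree = ped, source = "gp", risk_ratio = 5,
         genetic_result = genetic_test_result("BRCA1", "C5"))
  }
  pop <- c(
    replicate(3, list(pedigree = ped_trio(), source = "gp"),
              simplify = FALSE),
    lapply(c(1.5, 2.5, 3.5), mk_spoke),
    replicate(3, mk_direct(), simplify = FALSE),
    list(mk_spoke(2.0)))
  res <- run_pipeline(pop, funnel_params(seed = 1))
  st <- stats::setNames(res$stats$stages$count, res$stats$stages$stage)
  expect_identical(st, c(records = 10L, triage_eligible = 7L, arrived = 7L,
                         evaluated = 7L, hub_evaluated = 4L,
                         test_eligible = 3L, tested = 3L, carriers = 3L))
  br <- stats::setNames(res$stats$branches$count, res$stats$branches$label)
  expect_identical(br[["profile_low"]], 1L)
  expect_identical(br[["profile_intermediate"]], 2L)
  expect_identical(br[["profile_high"]], 1L)
  # the high-risk spoke record has no family-history criterion: evaluated
  # at the Hub but not tested
  expect_identical(sum(res$decisions$hub_attended &
                         !res$decisions$test_eligible), 1L)
  expect_identical(sum(res$decisions$basis == "profile3_mutation"), 3L)
})

test_that("the pipeline is deterministic for a fixed seed", {
  cfg <- synth_config(n_probands = 150, seed = 42)
  pop <- generate_population(cfg)
  p <- funnel_params(p_attend_spoke = 0.3, p_complete_spoke = 0.95,
                     p_attend_hub = 0.6, p_accept_test = 0.8, seed = 9)
  res1 <- run_pipeline(pop, p)
  res2 <- run_pipeline(pop, p)
  expect_identical(res1$decisions, res2$decisions)
  expect_identical(res1$stats$stages, res2$stats$stages)
})

test_that("funnel counts are conserved at every branch", {
  cfg <- synth_config(n_probands = 600, seed = 5)
  pop <- generate_population(cfg)
  res <- run_pipeline(pop, funnel_params(p_attend_spoke = 0.5,
                                         p_attend_hub = 0.7, seed = 2))
  st <- stats::setNames(res$stats$stages$count, res$stats$stages$stage)
  br <- stats::setNames(res$stats$branches$count, res$stats$branches$label)
  # monotone main path
  expect_true(all(diff(unname(st)) <= 0))
  # evaluated + refused = attended at the Spoke
  expect_identical(br[["spoke_evaluated"]] + br[["spoke_refused"]],
                   br[["spoke_attended"]])
  # low + intermediate + high = evaluated at the Spoke
  expect_identical(br[["profile_low"]] + br[["profile_intermediate"]] +
                     br[["profile_high"]], br[["spoke_evaluated"]])
  # the two Hub entry routes partition Hub evaluations
  d <- res$decisions
  expect_identical(
    sum(d$hub_attended),
    sum(d$hub_attended & d$route == "hub_direct") +
      sum(d$hub_attended & d$route == "spoke"))
})

test_that("with full attendance and high ratios, grid-eligible reach the Hub", {
  set.seed(61)
  pop <- list()
  for (i in 1:15) {
    fam <- random_family()
    pop[[i]] <- list(pedigree = fam$ped, source = "specialist",
                     risk_ratio = 4)
  }
  res <- run_pipeline(pop, funnel_params(seed = 1))
  d <- res$decisions
  expect_true(all(d$hub_attended[d$route != "none"]))
})

test_that("unknown source labels are rejected", {
  expect_error(
    run_pipeline(list(list(pedigree = ped_trio(), source = "walk_in"))),
    "unknown source")
})

test_that("stratified tabulation has consistent margins", {
  d <- data.frame(age = c(47, 47, 62, 33), source = c(
    "screening_program", "gp", "specialist", "gp"))
  tab <- tabulate_decisions(d)
  expect_identical(as.integer(tab["Total", "Total"]), 4L)
  expect_identical(as.integer(tab["45-49", "Total"]), 2L)
  expect_identical(as.integer(tab["<35", "gp"]), 1L)
  # order independence
  tab2 <- tabulate_decisions(d[c(3, 1, 4, 2), ])
  expect_identical(tab, tab2)
  # single record
  tab1 <- tabulate_decisions(d[1, , drop = FALSE])
  expect_identical(as.integer(tab1["Total", "Total"]), 1L)
})

test_that("the shipped program tables load and reconcile internally", {
  tabs <- era_program_tables()
  arr <- tabs$spoke_arrivals
  body <- arr[arr$age_band != "Total", ]
  tot <- arr[arr$age_band == "Total", ]
  for (col in c("gp", "specialist", "screening_program", "total",
                "refused", "low_risk", "intermediate_risk", "high_risk")) {
    expect_identical(sum(body[[col]]), tot[[col]],
                     label = paste("column", col))
  }
  expect_identical(sum(tabs$gene_tests$total[
    tabs$gene_tests$age_band != "Total"]), 2342L)
})
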