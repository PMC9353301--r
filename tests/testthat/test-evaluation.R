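toy_reference <- function() {
  reference_ddi(
    drug_a = c("a", "a", "b"),
    drug_b = c("x", "y", "x"),
    grade = c("potential", "no_interaction", "do_not_coadminister")
  )
}

test_that("signal pairs classify as documented / nonsignificant / not covered", {
  pairs <- data.frame(drug_a = c("a", "a", "c"), drug_b = c("x", "y", "z"),
    stringsAsFactors = FALSE)
  cs <- compare_reference(pairs, toy_reference())
  expect_equal(cs$n_signal_pairs, 3)
  expect_equal(cs$n_documented, 1)
  expect_equal(cs$n_reference_nonsignificant, 1)
  expect_equal(cs$n_not_covered, 1)
  expect_equal(cs$n_documented + cs$n_reference_nonsignificant +
    cs$n_not_covered, cs$n_signal_pairs)
})

test_that("reference pairs are unordered and conflicting grades are rejected", {
  ref <- reference_ddi("x", "a", "potential")  # reversed orientation
  cs <- compare_reference(
    data.frame(drug_a = "a", drug_b = "x", stringsAsFactors = FALSE), ref)
  expect_equal(cs$n_documented, 1)
  # same unordered pair listed twice with different grades
  expect_error(
    reference_ddi(c("a", "x"), c("x", "a"),
      c("potential", "no_interaction")),
    "conflicting"
  )
  # duplicated identical rows are tolerated
  expect_silent(reference_ddi(c("a", "x"), c("x", "a"),
    c("potential", "potential")))
})

test_that("an empty signal set yields an all-zero summary", {
  cs <- compare_reference(
    data.frame(drug_a = character(0), drug_b = character(0)),
    toy_reference())
  expect_equal(cs$n_signal_pairs, 0)
  expect_equal(cs$n_documented, 0)
})

test_that("a 10-pair fixture counts its documented pairs by hand", {
  ref <- reference_ddi(
    drug_a = paste0("c", 1:6),
    drug_b = paste0("m", 1:6),
    grade = c("potential", "potential_weak", "do_not_coadminister",
      "potential", "no_interaction", "no_interaction")
  )
  pairs <- data.frame(
    drug_a = paste0("c", 1:10), drug_b = paste0("m", 1:10),
    stringsAsFactors = FALSE
  )
  cs <- compare_reference(pairs, ref)
  expect_equal(cs$n_documented, 4)
  expect_equal(cs$n_reference_nonsignificant, 2)
  expect_equal(cs$n_not_covered, 4)
})

test_that("with zero qualifying simulations the empirical p is 1/(n+1)", {
  # reference covers exactly the observed pairs, drawn from a large
  # universe: no random set can match the observed overlap
  covid <- paste0("c", 1:6)
  comed <- c(paste0("m", 1:40), covid)
  observed <- data.frame(drug_a = c("c1", "c2"), drug_b = c("m1", "m2"),
    stringsAsFactors = FALSE)
  ref <- reference_ddi(observed$drug_a, observed$drug_b,
    c("potential", "potential"))
  ep <- monte_carlo_empirical_p(observed, covid, comed, ref,
    n_sims = 1000, seed = 3)
  expect_equal(ep$observed_overlap, 2)
  expect_equal(ep$r, 0)
  expect_equal(ep$p, 1 / 1001)
  expect_lt(ep$p, 0.001)
})

test_that("a saturated reference forces p = 1", {
  covid <- c("c1", "c2")
  comed <- c("m1", "m2", "m3")
  grid <- expand.grid(a = covid, b = comed, stringsAsFactors = FALSE)
  ref <- reference_ddi(grid$a, grid$b, rep("potential", nrow(grid)))
  observed <- data.frame(drug_a = c("c1", "c2"), drug_b = c("m1", "m2"))
  ep <- monte_carlo_empirical_p(observed, covid, comed, ref,
    n_sims = 200, seed = 5)
  expect_equal(ep$p, 1)
})

test_that("the empirical p is reproducible, bounded, and seed-driven", {
  covid <- paste0("c", 1:3)
  comed <- paste0("m", 1:8)
  ref <- reference_ddi(c("c1", "c2"), c("m1", "m5"),
    c("potential", "potential_weak"))
  observed <- data.frame(drug_a = c("c1", "c3"), drug_b = c("m1", "m2"))
  e1 <- monte_carlo_empirical_p(observed, covid, comed, ref, 500, seed = 11)
  e2 <- monte_carlo_empirical_p(observed, covid, comed, ref, 500, seed = 11)
  e3 <- monte_carlo_empirical_p(observed, covid, comed, ref, 500, seed = 12)
  expect_identical(e1, e2)
  expect_gte(min(e1$p, e3$p), 1 / 501)
  expect_lte(max(e1$p, e3$p), 1)
})

test_that("the p-value is invariant to relabeling drug identifiers", {
  covid <- paste0("c", 1:3)
  comed <- paste0("m", 1:8)
  ref <- reference_ddi(c("c1", "c2"), c("m1", "m5"),
    c("potential", "potential"))
  observed <- data.frame(drug_a = c("c1", "c2"), drug_b = c("m1", "m5"))
  relabel <- function(x) paste0("Z_", x)
  e1 <- monte_carlo_empirical_p(observed, covid, comed, ref, 400, seed = 9)
  e2 <- monte_carlo_empirical_p(
    data.frame(drug_a = relabel(observed$drug_a),
      drug_b = relabel(observed$drug_b)),
    relabel(covid), relabel(comed),
    reference_ddi(relabel(c("c1", "c2")), relabel(c("m1", "m5")),
      c("potential", "potential")),
    400, seed = 9)
  expect_equal(e1$p, e2$p)
})

test_that("oversized observed sets raise a configuration error", {
  ref <- reference_ddi("c1", "m1", "potential")
  observed <- data.frame(drug_a = c("c1", "c1", "c1"),
    drug_b = c("m1", "m2", "m3"))
  expect_error(
    monte_carlo_empirical_p(observed, "c1", c("m1", "m2"), ref, 10, 1),
    "exceed"
  )
})

test_that("empirical p matches exhaustive enumeration on a tiny universe", {
  # 2 covid drugs x 3 comeds -> 6 unordered pairs; draws of 2 distinct
  # pairs are uniform over the C(6,2) = 15 subsets
  covid <- c("c1", "c2")
  comed <- c("m1", "m2", "m3")
  ref <- reference_ddi(c("c1", "c1"), c("m1", "m2"),
    c("potential", "do_not_coadminister"))
  observed <- data.frame(drug_a = c("c1", "c2"), drug_b = c("m1", "m1"))
  obs_overlap <- 1  # (c1,m1) documented; (c2,m1) absent

  universe <- expand.grid(a = covid, b = comed, stringsAsFactors = FALSE)
  keys <- paste(pmin(universe$a, universe$b), pmax(universe$a, universe$b))
  doc <- c("c1 m1", "c1 m2")
  subsets <- combn(keys, 2)
  q_exact <- mean(colSums(matrix(subsets %in% doc, nrow = 2)) >= obs_overlap)

  n <- 100000
  ep <- monte_carlo_empirical_p(observed, covid, comed, ref,
    n_sims = n, seed = 17)
  expect_equal(ep$observed_overlap, obs_overlap)
  mc_se <- sqrt(q_exact * (1 - q_exact) / n)
  expect_lt(abs(ep$p - (q_exact * n + 1) / (n + 1)), 4 * mc_se)
})

test_that("the JSON report round-trips the p-value fields", {
  ref <- toy_reference()
  observed <- data.frame(drug_a = "a", drug_b = "x")
  ep <- monte_carlo_empirical_p(observed, c("a", "b"), c("x", "y", "z"),
    ref, 100, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_empirical_p(ep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$p, ep$p)
  expect_equal(back$r, ep$r)
  expect_equal(back$observed_overlap, ep$observed_overlap)
})
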