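test_that("delta-solubility classes partition the line, left-closed", {
  # isopropyl acetate vs its acetanilide gap: x = 11.20 - 2.73 = 8.47
  expect_equal(delta_solubility_class(2.73, 11.20, 1)$class, 2L)
  expect_equal(delta_solubility_class(2.73, 11.20, 1)$delta, 8.47)
  # boundaries land in the left-closed interval
  expect_equal(delta_solubility_class(5, 5, 1)$class, 1L)     # x = 0
  expect_equal(delta_solubility_class(0, 1, 1)$class, 2L)     # x = 1
  expect_equal(delta_solubility_class(0, 10, 1)$class, 3L)    # x = 10
  expect_equal(delta_solubility_class(0, 20, 1)$class, 4L)    # x = 20
  # negative gap: recommendation depends on impurity load
  lo <- delta_solubility_class(10, 5, 1)
  hi <- delta_solubility_class(10, 5, 3)
  expect_identical(lo$class, "NEGATIVE")
  expect_match(lo$recommended_wash_volumes, ">=3 equivalent cake volumes")
  expect_match(hi$recommended_wash_volumes, "revise crystallization")
  # no gaps/overlaps over a sweep
  xs <- c(-5, -1e-9, 0, 0.5, 1, 5, 10, 15, 20, 100)
  cls <- vapply(xs, function(x)
    as.character(delta_solubility_class(10, 10 + x)$class), character(1))
  expect_identical(cls, c("NEGATIVE", "NEGATIVE", "1", "1", "2", "2", "3",
                          "3", "4", "4"))
})

test_that("hard filters set the expected warning flags and never remove", {
  cryst <- solvent("alcohol", density = 0.789)
  mk <- function(name, ...) wash_candidate(solvent(name, ...),
                                           api_solubility = 1,
                                           impurity_solubilities = c(i = 5))
  cands <- list(
    mk("low-boiler", boiling_point = 28),          # |28 - 22| < 10
    mk("heavy", density = 1.33),                   # 1.33/0.789 = 1.69 > 1.3
    mk("class1", density = 0.9),
    mk("clean", density = 0.75, boiling_point = 98))
  cands[[3]]$solvent$ich_class <- 1L
  imm <- mk("oily", density = 0.75)
  imm$miscible_with_cryst <- FALSE
  cands <- c(cands, list(imm))
  out <- apply_hard_filters(cands, cryst, cryst_api_sol = 5.86)
  flags <- lapply(out, `[[`, "flags")
  expect_identical(flags[[1]], "BP_MP_NEAR_WASH_T")
  expect_identical(flags[[2]], "DENSITY_INVERSION")
  expect_identical(flags[[3]], "ICH_REJECT")
  expect_identical(flags[[4]], character(0))
  expect_identical(flags[[5]], "IMMISCIBLE")
  expect_length(out, 5L)
  # a wash solvent with lower API solubility than the liquor gets no flag;
  # a higher one does
  hi <- apply_hard_filters(list(mk("strong", density = 0.7)), cryst, 0.5)
  expect_identical(hi[[1]]$flags, "API_MORE_SOLUBLE_THAN_CRYST")
  lo <- apply_hard_filters(list(mk("weak", density = 0.7)), cryst, 5.86)
  expect_identical(lo[[1]]$flags, character(0))
})

test_that("threshold filters enforce the physicochemical and GSK bounds", {
  mk <- function(...) wash_candidate(solvent(...), 1, c(i = 2))
  # melting point at/above 0 C fails filter 3
  out <- apply_threshold_filters(list(mk("waxy", melting_point = 5,
                                         boiling_point = 100)))
  expect_true("THRESHOLD_FAIL" %in% out[[1]]$flags)
  # viscosity at the 0.09 Pa s bound fails; just under passes
  thick <- apply_threshold_filters(list(mk("thick", viscosity = 0.1)))[[1]]
  thin <- apply_threshold_filters(list(mk("thin", viscosity = 0.05)))[[1]]
  expect_true("THRESHOLD_FAIL" %in% thick$flags)
  expect_false("THRESHOLD_FAIL" %in% thin$flags)
  # all six GSK scores of 4 pass the "> 3" rule; one score of 3 fails
  ok <- mk("fine", ich_class = 3)
  ok$solvent$gsk_scores[] <- 4
  bad <- mk("waste-heavy", ich_class = 3)
  bad$solvent$gsk_scores[] <- c(3, 8, 8, 8, 8, 8)
  out <- apply_threshold_filters(list(ok, bad))
  expect_false("GSK_FAIL" %in% out[[1]]$flags)
  expect_true("GSK_FAIL" %in% out[[2]]$flags)
  # ICH class 2 fails the class-3 requirement; unknown passes unless strict
  cl2 <- apply_threshold_filters(list(mk("mid", ich_class = 2)))[[1]]
  expect_true("GSK_FAIL" %in% cl2$flags)
  unk <- apply_threshold_filters(list(mk("unrated")))[[1]]
  expect_false("GSK_FAIL" %in% unk$flags)
  strict <- apply_threshold_filters(
    list(mk("unrated")), wash_filter_config(strict_ich = TRUE))[[1]]
  expect_true("GSK_FAIL" %in% strict$flags)
})

test_that("staged filters 1-4 give a non-increasing unflagged count", {
  fx <- generate_fixture_table(3, 30, 2)
  cryst <- fx$solvents$solvents[[5]]
  api <- "fixture-solute-1"; imp <- "fixture-solute-2"
  cands <- lapply(setdiff(names(fx$solvents$solvents), tolower(cryst$name)),
                  function(nm) {
                    s <- fx$solvents$solvents[[nm]]
                    wash_candidate(
                      s,
                      lookup_solubility(fx$solubilities, api, s$name),
                      c(imp = lookup_solubility(fx$solubilities, imp,
                                                s$name)))
                  })
  capi <- lookup_solubility(fx$solubilities, api, cryst$name)
  unflagged <- vapply(1:4, function(lv) {
    out <- apply_filter_level(cands, lv, cryst, capi)
    sum(vapply(out, function(c) length(c$flags) == 0, logical(1)))
  }, numeric(1))
  expect_equal(unflagged[1], length(cands))
  expect_true(all(diff(unflagged) <= 0))
  expect_true(unflagged[4] < unflagged[1])  # generator plants violators
  # monotone flags: each level's flag set contains the previous level's
  for (lv in 2:4) {
    prev <- apply_filter_level(cands, lv - 1L, cryst, capi)
    cur <- apply_filter_level(cands, lv, cryst, capi)
    for (i in seq_along(cands))
      expect_true(all(prev[[i]]$flags %in% cur[[i]]$flags))
  }
})

test_that("pareto fronts match the brute-force dominance oracle", {
  # hand-checkable pairs first
  mk <- function(name, api, imp) wash_candidate(solvent(name), api, imp)
  rk <- pareto_rank(list(mk("A", 0.1, c(i = 5)), mk("B", 0.2, c(i = 4))))
  expect_equal(rk$ranking$front[rk$ranking$name == "A"], 1L)
  expect_equal(rk$ranking$front[rk$ranking$name == "B"], 2L)
  # heptane-like and isopropyl-acetate-like candidates are mutually
  # non-dominated (one wins on API, the other on the impurity)
  rk2 <- pareto_rank(list(mk("heptane", 0.005, c(acet = 0.04)),
                          mk("isopropyl acetate", 2.73, c(acet = 11.20))))
  expect_equal(unique(rk2$ranking$front), 1L)
  # randomized cross-check, 25 candidates x 20 seeds, 2 impurities
  for (seed in 1:20) {
    set.seed(seed)
    n <- 25
    api <- round(runif(n, 0, 5), 2)
    imp <- matrix(round(runif(2 * n, 0, 20), 2), n, 2)
    cands <- lapply(seq_len(n), function(i)
      mk(sprintf("c%02d", i), api[i], c(p = imp[i, 1], q = imp[i, 2])))
    rk <- pareto_rank(cands)
    want <- oracle_pareto_fronts(api, imp)
    got <- rk$ranking$front[match(sprintf("c%02d", seq_len(n)),
                                  rk$ranking$name)]
    expect_identical(got, want)
  }
})

test_that("flagged candidates are excluded before pareto sorting", {
  mk <- function(name, api, imp) wash_candidate(solvent(name), api, imp)
  good <- mk("good", 0.5, c(i = 3))
  bad <- mk("bad", 0.1, c(i = 9))
  bad$flags <- "DENSITY_INVERSION"
  rk <- pareto_rank(list(good, bad))
  expect_identical(rk$ranking$name, "good")
  expect_identical(rk$flagged$name, "bad")
  allbad <- lapply(list(bad), identity)
  expect_warning(empty <- pareto_rank(allbad), "no wash candidates")
  expect_equal(nrow(empty$ranking), 0L)
})

test_that("drying-friendliness score prefers volatile, low-boiling solvents", {
  mk <- function(name, ...) wash_candidate(solvent(name, ...), 1, c(i = 1))
  cands <- list(
    mk("volatile", boiling_point = 60, vapor_pressure = 5e4,
       enthalpy_vaporization = 30, viscosity = 4e-4),
    mk("sticky", boiling_point = 210, vapor_pressure = 20,
       enthalpy_vaporization = 65, viscosity = 1.3e-3))
  adv <- drying_friendliness(cands, solvent("alcohol", viscosity = 1.2e-3))
  expect_true(adv$drying_score[1] > adv$drying_score[2])
  expect_equal(adv$viscosity_ratio[1], 4e-4 / 1.2e-3)
})
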