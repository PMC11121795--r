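test_that("candidate pruning keeps flux-carrying internal reactions", {
  cand <- prune_candidates(toy)
  expect_false("DEADEND" %in% cand)            # authored zero-flux branch
  expect_false(any(startsWith(cand, "EX_")))   # exchanges excluded
  expect_false("BIOMASS" %in% cand)            # objective excluded
  expect_true(all(c("GLCt", "GLYC", "PRECSYN", "PIt") %in% cand))
})

test_that("FBA essentiality equals the exhaustive re-solve oracle", {
  scan <- essentiality_scan(toy)
  found <- sort(scan$id[scan$essential])
  oracle <- exhaustive_essentials(toy)
  ## pruning is exact for essentials: every oracle essential is a
  ## candidate and the verdicts agree on the full candidate set
  expect_identical(found, oracle)
  expect_identical(found, sort(c("GLCt", "GLYC", "PIt", "PRECSYN")))
  ## deleting a zero-flux dead end is harmless
  expect_gt(fba(delete_reactions(toy, "DEADEND"))$objective_value,
            0.95 * TOY_OPTIMUM)
})

test_that("synthetic lethal scan equals exhaustive double deletion", {
  sl <- synthetic_lethal_scan(toy)
  oracle <- exhaustive_sl(toy)
  got <- apply(as.matrix(sl), 1, paste, collapse = "|")
  want <- apply(oracle, 1, paste, collapse = "|")
  expect_setequal(got, want)
  ## authored redundant respiration/fermentation pair is reported
  expect_true("FERM|RESP" %in% got)
  ## no pair contains a singly essential reaction
  singles <- attr(sl, "singles")
  ess <- singles$id[singles$essential]
  expect_false(any(sl$rxn1 %in% ess | sl$rxn2 %in% ess))
  ## full enumeration agrees with the pruned scan on the toy model
  sl_full <- synthetic_lethal_scan(toy, full_enumeration = TRUE)
  expect_setequal(apply(as.matrix(sl_full), 1, paste, collapse = "|"), want)
})

test_that("ROOM reference flux minimizes out-of-band changes", {
  wt <- fba(toy)
  ## delete nothing: the wild type itself is optimal, nothing changes
  r0 <- room_reference_flux(toy, character(), wt)
  expect_equal(r0$n_changed, 0)
  expect_lt(r0$objective, 1e-6)
  ## delete a zero-flux reaction: still no significant change
  rd <- room_reference_flux(toy, "DEADEND", wt)
  expect_equal(rd$n_changed, 0)
  expect_equal(unname(rd$flux[["DEADEND"]]), 0)
  ## infeasible deletion reports biomass 0
  rme <- room_reference_flux(toy, c("GLCt"), wt)
  expect_lt(rme$biomass, 0.05 * TOY_OPTIMUM)
})

test_that("exact ROOM matches incremental subset-enumeration oracle", {
  ## 5-reaction reroute fixture: uptake -> X; X -> Y via parallel
  ## routes R2a / R2b; Y -> out. The wild-type reference flux uses R2a
  ## only, so deleting R2a must change exactly {R2a, R2b}.
  rx <- data.frame(id = c("IN", "R2a", "R2b", "OUT", "SPARE"),
                   name = c("IN", "R2a", "R2b", "OUT", "SPARE"),
                   lower_bound = c(0, 0, 0, 0, 0),
                   upper_bound = c(5, 10, 10, 10, 10),
                   gene_reaction_rule = "",
                   objective_coefficient = c(0, 0, 0, 1, 0),
                   stringsAsFactors = FALSE)
  mets <- data.frame(id = c("X", "Y"), name = c("X", "Y"),
                     compartment = "c", stringsAsFactors = FALSE)
  S <- matrix(0, 2, 5, dimnames = list(mets$id, rx$id))
  S["X", "IN"] <- 1
  S["X", c("R2a", "R2b")] <- -1; S["Y", c("R2a", "R2b")] <- 1
  S["Y", "OUT"] <- -1
  S["X", "SPARE"] <- -1             # alternative drain, unused at WT
  pm <- exogem:::new_metabolic_model("par", rx, mets, S)
  wt <- structure(list(values = c(IN = 5, R2a = 5, R2b = 0, OUT = 5,
                                  SPARE = 0),
                       objective_value = 5, status = "optimal"),
                  class = "flux_vector")
  res <- room_reference_flux(pm, "R2a", wt, exact = TRUE)
  ## oracle: smallest k such that freeing k reactions (others clamped
  ## to the wild-type band) keeps the deleted model feasible
  delta <- 0.03; eps <- 0.001
  w <- wt$values
  wu <- w + delta * abs(w) + eps
  wl <- w - delta * abs(w) - eps
  dm <- delete_reactions(pm, "R2a")
  n <- 5L
  feasible_with_free <- function(free) {
    lb <- ifelse(seq_len(n) %in% free, dm$reactions$lower_bound,
                 pmax(dm$reactions$lower_bound, wl))
    ub <- ifelse(seq_len(n) %in% free, dm$reactions$upper_bound,
                 pmin(dm$reactions$upper_bound, wu))
    if (any(lb > ub + 1e-12)) return(FALSE)
    s <- lp_solve(rep(0, n), dm$S, rep(0, nrow(dm$S)),
                  rep("=", nrow(dm$S)), lb, ub)
    s$status == "optimal"
  }
  k_min <- NA
  for (k in 0:n) {
    combos <- utils::combn(n, k)
    if (any(apply(combos, 2, feasible_with_free))) { k_min <- k; break }
  }
  expect_equal(k_min, 2)              # exactly {R2a, R2b} must move
  expect_equal(res$n_changed, k_min)
  expect_equal(unname(res$flux[["R2b"]]), 5, tolerance = 1e-6)
  expect_equal(res$biomass, 5, tolerance = 1e-6)
})

test_that("density-based and FBA predictors agree on strict infeasibility", {
  base <- sample_fluxes(toy, 400, seed = 17)
  rr <- resos(base)
  cfgR <- knockout_config(predictor = "resos", resos_params = rr$params,
                          resos_batch = 100L, resos_max_points = 400L)
  cfgF <- knockout_config()
  for (id in c("GLCt", "GLYC")) {     # deletions that void the model
    expect_lt(exogem:::predict_knockout_biomass(toy, id, cfgF),
              0.05 * TOY_OPTIMUM)
    expect_lt(exogem:::predict_knockout_biomass(toy, id, cfgR),
              0.05 * TOY_OPTIMUM)
  }
  ## resos predictor on a viable deletion returns a dense-region biomass
  bm <- exogem:::predict_knockout_biomass(toy, "FERM", cfgR)
  expect_gt(bm, 0.05 * TOY_OPTIMUM)
})

test_that("contingency arithmetic reproduces the prediction ratio", {
  expect_equal(prediction_ratio(contingency_table(1, 1, 1, 1)), 0.5)
  expect_equal(prediction_ratio(contingency_table(10, 5, 0, 0)), 1)
  expect_equal(prediction_ratio(contingency_table(2500, 0, 83, 0)),
               2500 / 2583, tolerance = 1e-12)
  expect_error(prediction_ratio(contingency_table(0, 0, 0, 0)), "empty")
  expect_error(contingency_table(-1, 0, 0, 0), "non-negative")
  ## counts partition the evaluated universe
  universe <- letters[1:10]
  ct <- compare_predictions(predicted = c("a", "b", "c"),
                            gold = c("b", "c", "d"), universe = universe)
  expect_equal(ct$TP + ct$TN + ct$FP + ct$FN, 10)
  expect_equal(ct$TP, 2); expect_equal(ct$FP, 1); expect_equal(ct$FN, 1)
  ## gold-standard reader normalizes pairs
  p <- tempfile()
  writeLines(c("# comment", "g2, g1", "", "g3"), p)
  expect_identical(read_gold_standard(p), c("g1,g2", "g3"))
})
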