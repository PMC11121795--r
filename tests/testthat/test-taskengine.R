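test_that("task definitions load from JSON and validate", {
  tasks <- toy_tasks()
  expect_length(tasks, 8)
  expect_identical(tasks[[1]]$id, "T_PRECURSOR")
  expect_error(task_definition("t", products = numeric()), "non-empty")
  expect_error(task_definition("t", products = c(a = -1)), "negative")
  ## NA substrate uptake falls back to the default 10
  t <- task_definition("t", substrates = c(glc_c = NA), products = c(x = 0))
  expect_equal(unname(t$substrates["glc_c"]), 10)
  ## TSV loader round trip
  p <- tempfile(fileext = ".tsv")
  writeLines(c("task\trole\tmetabolite\tflux",
               "T1\tsubstrate\tglc_c\t10",
               "T1\tproduct\tlac_c\t0"), p)
  tt <- load_tasks(p)
  expect_equal(unname(tt[[1]]$substrates["glc_c"]), 10)
})

test_that("task evaluation matches the hand-derived optimum", {
  ## glucose -> biomass precursor, closed exchanges. With all exchanges
  ## shut, lactate export and respiration are unavailable, so ATP and
  ## pyruvate both reduce to 2*GLYC and the network forces
  ## AASYN = PRECSYN; precursor output is then capped by the 4 units of
  ## glucose supplied by the task: optimum = 4 exactly.
  task <- task_definition("t", substrates = c(glc_c = 4, nh4_c = 4,
                                              pi_c = 4),
                          products = c(prec_c = 0))
  sc <- evaluate_task(toy, task, closed_exchanges = TRUE)
  expect_false(attr(sc, "infeasible"))
  expect_equal(as.numeric(sc), 4, tolerance = 1e-7)
  ## halving the glucose supply halves the optimum (same bottleneck)
  task2 <- task_definition("t", substrates = c(glc_c = 2, nh4_c = 4,
                                               pi_c = 4),
                           products = c(prec_c = 0))
  expect_equal(as.numeric(evaluate_task(toy, task2,
                                        closed_exchanges = TRUE)),
               2, tolerance = 1e-7)
})

test_that("task evaluation respects feasibility, monotonicity and purity", {
  ## unreachable demand -> score 0 with infeasible flag
  hi <- toy_tasks()[[which(vapply(toy_tasks(), `[[`, "", "id") ==
                             "T_HIGH_DEMAND")]]
  sc <- evaluate_task(toy, hi)
  expect_equal(as.numeric(sc), 0)
  expect_true(attr(sc, "infeasible"))
  ## product with no producing route (closed exchanges, synthesis cut)
  cut <- delete_reactions(toy, c("AASYN", "AAt"))
  t0 <- task_definition("t", products = c(aa_c = 0.1))
  sc0 <- evaluate_task(cut, t0, closed_exchanges = TRUE)
  expect_equal(as.numeric(sc0), 0)
  expect_true(attr(sc0, "infeasible"))
  ## doubling substrate uptake never decreases the score
  t1 <- task_definition("t", substrates = c(glc_c = 2),
                        products = c(lac_c = 0))
  t2 <- task_definition("t", substrates = c(glc_c = 4),
                        products = c(lac_c = 0))
  expect_gte(as.numeric(evaluate_task(toy, t2)) + 1e-9,
             as.numeric(evaluate_task(toy, t1)))
  ## substrate/product order does not matter
  ta <- task_definition("t", substrates = c(glc_c = 3, nh4_c = 2),
                        products = c(aa_c = 0, lac_c = 0))
  tb <- task_definition("t", substrates = c(nh4_c = 2, glc_c = 3),
                        products = c(lac_c = 0, aa_c = 0))
  expect_equal(as.numeric(evaluate_task(toy, ta)),
               as.numeric(evaluate_task(toy, tb)), tolerance = 1e-9)
  ## the input model is never mutated
  dg <- model_digest(toy)
  invisible(evaluate_task(toy, ta))
  expect_identical(model_digest(toy), dg)
  expect_error(evaluate_task(toy, task_definition("t",
                                                  products = c(nope = 1))),
               "unknown metabolite")
})

test_that("task matrices have deterministic shape and record errors", {
  tasks <- toy_tasks()[1:3]
  models <- list(p1 = toy, p2 = toy)
  tm <- evaluate_task_matrix(models, tasks)
  expect_equal(dim(tm$values), c(3, 2))
  expect_equal(tm$values[, 1], tm$values[, 2])   # identical models
  expect_true(all(tm$values >= 0))
  ## per-cell errors recorded, run continues
  badtask <- task_definition("bad", products = c(missing_met = 0))
  tm2 <- evaluate_task_matrix(models, c(tasks, list(badtask)))
  expect_equal(dim(tm2$values), c(4, 2))
  expect_length(tm2$errors, 2)
  expect_true(all(tm2$infeasible["bad", ]))
})

make_task_matrix <- function(vals, groups) {
  pid <- colnames(vals)
  structure(list(values = vals, task_ids = rownames(vals),
                 patient_ids = pid,
                 group_labels = stats::setNames(groups, pid)),
            class = "task_activity_matrix")
}

test_that("rank change filter applies the 10-position monotone rule", {
  ## After row standardization every task built as
  ## level + trend * s(group) collapses to the same +/- unit pattern,
  ## so group ranks are controlled exactly: 10 "up" tasks rank 1-10 in
  ## group A and 11-20 in group D (shift exactly 10), and vice versa.
  set.seed(33)
  groups <- rep(c("A", "B", "C", "D"), each = 4)
  pid <- sprintf("p%02d", seq_along(groups))
  s <- c(A = 1.5, B = 0.5, C = -0.5, D = -1.5)
  trend <- rep(c(1, -1), each = 10)
  level <- seq(2, 40, by = 2)
  vals <- outer(seq_len(20), seq_along(pid), function(t, p)
    level[t] + trend[t] * s[groups[p]])
  dimnames(vals) <- list(sprintf("task%02d", 1:20), pid)
  tm <- make_task_matrix(vals, groups)
  sel10 <- rank_change_filter(tm, c("A", "B", "C", "D"), min_shift = 10)
  rk <- attr(sel10, "ranks")
  expect_equal(unname(rk["task01", ]), c(1, 1, 11, 11))
  expect_equal(unname(rk["task11", ]), c(11, 11, 1, 1))
  ## shift exactly 10 and monotone: included (inclusive minimum)
  expect_setequal(sel10, rownames(vals))
  ## shift below a stricter threshold: excluded
  expect_length(rank_change_filter(tm, c("A", "B", "C", "D"),
                                   min_shift = 11), 0)
  ## a non-monotone (zigzag) task is never selected
  vals2 <- vals
  vals2[1, ] <- 2 + 3 * rep(c(1, -1, 1, -1), each = 4)
  sel2 <- rank_change_filter(make_task_matrix(vals2, groups),
                             c("A", "B", "C", "D"), min_shift = 0)
  expect_false("task01" %in% sel2)
  expect_error(rank_change_filter(tm, c("A", "E")), "no patients")
  ## singleton group draws a warning but still ranks
  g1 <- groups
  g1[16] <- "E"
  expect_warning(rank_change_filter(make_task_matrix(vals, g1),
                                    c("A", "E"), min_shift = 0),
                 "fewer than 2")
})

test_that("rank change filter recovers planted shifting tasks", {
  ## 20 tasks, 4 groups x 6 patients. Because rows are standardized,
  ## every task competes at unit pattern scale and ranks are zero-sum,
  ## so the construction controls the full rank geometry: 3 planted
  ## shifters (high in A/B, mid in C, far low in D), 12 structured
  ## non-monotone nulls whose large components sit in the middle
  ## groups (deterministically excluded by the direction rule), and 5
  ## pure-noise nulls confined to mid ranks.
  set.seed(44)
  planted_pat <- rbind(c(1.05, 1.00, -0.25), c(1.00, 1.10, -0.30),
                       c(1.10, 1.05, -0.35))
  planted_pat <- cbind(planted_pat, -rowSums(planted_pat))
  zig <- rbind(c(0.5,-0.5,1.6,-1.6), c(-0.5,0.5,-1.6,1.6),
               c(0.4,-0.6,1.7,-1.5), c(-0.4,0.3,1.5,-1.4),
               c(0.5,-0.4,-1.5,1.4), c(-0.3,0.5,-1.7,1.5),
               c(0.6,-0.3,1.4,-1.7), c(-0.6,0.4,-1.4,1.6),
               c(0.3,-0.5,1.5,-1.3), c(-0.5,0.6,-1.5,1.4),
               c(0.45,-0.35,1.55,-1.65), c(-0.45,0.25,1.65,-1.45))
  groups <- rep(c("A", "B", "C", "D"), each = 6)
  pid <- sprintf("p%02d", seq_along(groups))
  gi <- match(groups, c("A", "B", "C", "D"))
  vals <- matrix(0, 20, 24, dimnames = list(sprintf("task%02d", 1:20), pid))
  for (i in 1:3)
    vals[i, ] <- 5 * i + 2 * planted_pat[i, gi] + rnorm(24, sd = 0.4)
  for (j in 1:12)
    vals[3 + j, ] <- j + 1.5 * zig[j, gi] + rnorm(24, sd = 0.4)
  for (j in 16:20) vals[j, ] <- rnorm(24, sd = 1)
  tm <- make_task_matrix(vals, groups)
  planted <- sprintf("task%02d", 1:3)
  sel <- rank_change_filter(tm, c("A", "B", "C", "D"), min_shift = 10)
  expect_gte(length(intersect(sel, planted)), ceiling(0.9 * 3))
  expect_lte(length(setdiff(sel, planted)), ceiling(0.1 * 17))
})
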