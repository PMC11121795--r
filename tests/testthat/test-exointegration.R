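make_profile <- function(seed = 21, n = 400) {
  base <- set_biomass_floor(toy, 0.5)
  s <- sample_fluxes(base, n, seed = seed)
  list(base = base, samples = s, resos = resos(s))
}

test_that("control stats and ratios follow the min/mean/max convention", {
  ctrl <- rbind(a = c(m1 = 1, m2 = 2), b = c(3, 2), c = c(2, 2))
  pats <- rbind(P1 = c(m1 = 4, m2 = 2))
  co <- patient_cohort(pats, ctrl, metabolite_map = c(m1 = "EX_glc"))
  st <- control_stats(co)
  expect_equal(st$min, c(1, 2))
  expect_equal(st$mean, c(2, 2))
  expect_equal(st$max, c(3, 2))
  r <- compute_ratios(co, st, "P1")
  expect_equal(unname(r$min["m1"]), 4)
  expect_equal(unname(r$mean["m1"]), 2)
  expect_equal(unname(r$max["m1"]), 4 / 3)
  ## degenerate control spread: all three ratios identical
  expect_equal(unname(c(r$min["m2"], r$mean["m2"], r$max["m2"])),
               c(1, 1, 1))
  expect_error(compute_ratios(co, st, "NOPE"), "unknown patient")
  ## zero control stat replaced by eps with warning
  ctrl0 <- rbind(a = c(m1 = 0), b = c(m1 = 0))
  co0 <- patient_cohort(rbind(P1 = c(m1 = 2)), ctrl0, c(m1 = "EX_glc"))
  ws <- capture_warnings(r0 <- compute_ratios(co0, control_stats(co0), "P1"))
  expect_length(ws, 3)                 # one per control statistic
  expect_match(ws, "eps", all = TRUE)
  expect_equal(unname(r0$mean["m1"]), 2e6)
  expect_error(patient_cohort(rbind(P1 = c(m1 = -1)), ctrl0, NULL),
               "negative")
})

test_that("boundary rescaling satisfies the stated identities", {
  ## ratio 1 leaves any nonzero bound unchanged, exactly
  expect_identical(rescale_boundary(-5, 1), -5)
  expect_identical(rescale_boundary(7.25, 1), 7.25)
  expect_equal(rescale_boundary(-5, 2), -10)
  ## homogeneity in the ratio
  for (b in c(-5, 0.3, 12)) for (r in c(0, 0.25, 1.7))
    expect_equal(rescale_boundary(b, r), r * rescale_boundary(b, 1))
  ## audit mode: the literal printed form agrees for nonzero bounds
  expect_equal(rescale_boundary(c(-5, 3), 1.3, audit = TRUE),
               c(-6.5, 3.9))
  expect_error(rescale_boundary(1, -0.1), ">= 0")
  ## zero-flux baseline pair gets the conventional (-10, +10) window
  pr <- exogem:::rescale_bound_pair(0, 0, 1.5)
  expect_equal(c(pr$lower, pr$upper), c(-15, 15))
  ## inverted pair after rescaling is swapped and flagged
  pr2 <- exogem:::rescale_bound_pair(-2, 1, 1)
  expect_false(pr2$swapped)
})

test_that("baseline profile equals brute-force min/max over retained rows", {
  pf <- make_profile()
  prof <- baseline_profile(pf$base, pf$samples, pf$resos)
  kept <- pf$samples$matrix[pf$resos$retained_indices, , drop = FALSE]
  expect_equal(prof$bounds$lower, unname(apply(kept, 2, min)))
  expect_equal(prof$bounds$upper, unname(apply(kept, 2, max)))
  ## profile bounds never exceed model bounds (samples are feasible)
  expect_true(all(prof$bounds$lower >=
                    pf$base$reactions$lower_bound - 1e-6))
  expect_true(all(prof$bounds$upper <=
                    pf$base$reactions$upper_bound + 1e-6))
  ## digest mismatch is rejected
  other <- delete_reactions(pf$base, "FERM")
  expect_error(baseline_profile(other, pf$samples, pf$resos), "digest")
})

test_that("patient trio rescales mapped exchanges by each ratio", {
  pf <- make_profile()
  prof <- baseline_profile(pf$base, pf$samples, pf$resos)
  cohort <- simulate_cohort(cohort_spec(effects = "null", seed = 3))
  st <- control_stats(cohort)
  ## synthetic patient identical to the control mean: all mean-ratios 1
  pt <- cohort$patient_table
  pt["P01", ] <- st$mean[match(colnames(pt), st$metabolite)]
  co1 <- patient_cohort(pt, cohort$control_table, cohort$metabolite_map,
                        cohort$group_labels)
  trio <- build_patient_trio(pf$base, prof, co1, control_stats(co1), "P01")
  expect_named(trio, c("min", "mean", "max"))
  exch <- find_exchange_reactions(pf$base)
  bse <- apply_profile(pf$base, prof, exch)
  kmean <- match(exch, trio$mean$reactions$id)
  ## mean member: every mapped nonzero exchange bound keeps its
  ## baseline-envelope value (ratio 1), zero-pairs get the +/-10 window
  for (ex in unname(cohort$metabolite_map)) {
    k <- match(ex, bse$reactions$id)
    lo <- bse$reactions$lower_bound[k]; hi <- bse$reactions$upper_bound[k]
    pr <- exogem:::rescale_bound_pair(lo, hi, 1)
    expect_equal(trio$mean$reactions$lower_bound[k], pr$lower,
                 tolerance = 1e-9)
    expect_equal(trio$mean$reactions$upper_bound[k], pr$upper,
                 tolerance = 1e-9)
  }
  ## doubled metabolite doubles the mapped exchange bounds in each member
  pt2 <- pt
  pt2["P02", ] <- 2 * pt["P01", ]
  co2 <- patient_cohort(pt2, cohort$control_table, cohort$metabolite_map,
                        cohort$group_labels)
  trio2 <- build_patient_trio(pf$base, prof, co2, control_stats(co2), "P02")
  k <- match("EX_glc", bse$reactions$id)
  expect_equal(trio2$mean$reactions$lower_bound[k],
               2 * bse$reactions$lower_bound[k], tolerance = 1e-9)
  ## measured but unmapped metabolite leaves bounds untouched + warns
  map3 <- cohort$metabolite_map[-1]
  co3 <- patient_cohort(pt, cohort$control_table, map3,
                        cohort$group_labels)
  expect_warning(trio3 <- build_patient_trio(pf$base, prof, co3,
                                             control_stats(co3), "P01"),
                 "unmapped")
  kg <- match("EX_glc", bse$reactions$id)
  expect_equal(trio3$mean$reactions$lower_bound[kg],
               bse$reactions$lower_bound[kg])
})

test_that("consensus model fuses trio samples through density filtering", {
  pf <- make_profile(seed = 31, n = 300)
  prof <- baseline_profile(pf$base, pf$samples, pf$resos)
  ## three identical sample sets: consensus bounds equal the single-set
  ## profile bounds at the same percentile
  s <- pf$samples
  cons <- build_consensus_model(pf$base, list(s, s, s),
                                percentile = pf$resos$percentile)
  expect_equal(cons$model$reactions$lower_bound, prof$bounds$lower,
               tolerance = 1e-9)
  expect_equal(cons$model$reactions$upper_bound, prof$bounds$upper,
               tolerance = 1e-9)
  ## envelope equals brute-force min/max over retained fused rows
  s2 <- sample_fluxes(pf$base, 300, seed = 32)
  s3 <- sample_fluxes(pf$base, 300, seed = 33)
  cons2 <- build_consensus_model(pf$base, list(s, s2, s3))
  fusedM <- rbind(s$matrix, s2$matrix, s3$matrix)
  kept <- fusedM[cons2$resos$retained_indices, , drop = FALSE]
  expect_equal(cons2$model$reactions$lower_bound,
               unname(apply(kept, 2, min)), tolerance = 1e-12)
  expect_equal(cons2$model$reactions$upper_bound,
               unname(apply(kept, 2, max)), tolerance = 1e-12)
  ## central fused solution is feasible in the consensus model
  central <- fusedM[cons2$resos$central_index, ]
  expect_true(all(central >= cons2$model$reactions$lower_bound - 1e-9))
  expect_true(all(central <= cons2$model$reactions$upper_bound + 1e-9))
  ## reaction-order mismatch is rejected
  sswap <- s2
  sswap$reaction_ids <- rev(sswap$reaction_ids)
  expect_error(build_consensus_model(pf$base, list(s, sswap, s3)),
               "mismatch")
})

test_that("pooled trio samples separate in PCA when ratios differ", {
  ## Strongly different min/mean/max ratios (control spread 2.5x on
  ## every robust exchange, 1.3x on the growth-limiting ones) shift the
  ## trio sample clouds apart. On a 22-reaction toy the internal flux
  ## freedom dominates any feasible ratio-induced shift, so the clouds
  ## stay partially nested: the achievable silhouette plateaus around
  ## 0.2, an order of magnitude above the identical-ratio control but
  ## below what a tightly bounded genome-scale polytope would show.
  pf <- make_profile(seed = 21, n = 400)
  prof <- baseline_profile(pf$base, pf$samples, pf$resos)
  sb <- 2.5; ss <- 1.3
  ctrl <- cbind(glucose = c(1 / ss, 0.98, 1.02, ss),
                oxygen = c(1 / sb, 0.97, 1.03, sb),
                ammonium = c(1 / ss, 0.96, 1.04, ss),
                phosphate = c(1 / ss, 0.99, 1.01, ss),
                aminoacid = c(1 / sb, 0.95, 1.05, sb),
                lactate = c(1 / sb, 0.94, 1.06, sb),
                co2 = c(1 / sb, 0.93, 1.07, sb))
  rownames(ctrl) <- paste0("C", 1:4)
  pats <- rbind(P1 = rep(1, ncol(ctrl)))
  colnames(pats) <- colnames(ctrl)
  co <- patient_cohort(pats, ctrl,
                       metabolite_map = toy_metabolite_map()[colnames(ctrl)])
  trio <- build_patient_trio(pf$base, prof, co, control_stats(co), "P1")
  expect_true(all(vapply(trio, function(x) isTRUE(attr(x, "feasible")),
                         TRUE)))
  sams <- lapply(1:3, function(i)
    sample_fluxes(trio[[i]], 150, seed = 50 + i)$matrix)
  pc <- pca_check(do.call(rbind, sams), rep(names(trio), each = 150))
  ## identical ratios: three draws from the same model barely separate
  sams0 <- lapply(1:3, function(i)
    sample_fluxes(pf$base, 150, seed = 60 + i)$matrix)
  pc0 <- pca_check(do.call(rbind, sams0), rep(c("a", "b", "c"), each = 150))
  expect_gt(pc$silhouette, 0.15)
  expect_lt(pc0$silhouette, 0.05)
  expect_gt(pc$silhouette, 3 * max(pc0$silhouette, 0.01))
})

test_that("cohort tables round-trip through TSV", {
  cohort <- simulate_cohort(cohort_spec(seed = 9))
  d <- tempfile()
  write_cohort(cohort, d)
  back <- read_cohort(file.path(d, "patients.tsv"),
                      file.path(d, "controls.tsv"),
                      file.path(d, "metabolite_map.tsv"),
                      file.path(d, "groups.tsv"))
  expect_equal(back$patient_table, cohort$patient_table,
               tolerance = 1e-12)
  expect_equal(back$control_table, cohort$control_table,
               tolerance = 1e-12)
  expect_identical(unname(back$metabolite_map[names(cohort$metabolite_map)]),
                   unname(cohort$metabolite_map))
  expect_identical(unname(back$group_labels[names(cohort$group_labels)]),
                   unname(cohort$group_labels))
})
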