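resp_task <- task_definition("resp", products = c(co2_c = 0))

test_that("perturbation sweeps use an exact linspace grid and restore bounds", {
  dg <- model_digest(toy)
  sw <- perturbation_sweep(toy, "EX_glc", list(resp_task), n_steps = 100)
  expect_identical(model_digest(toy), dg)      # model untouched
  expect_length(sw$grid, 100)
  expect_equal(sw$grid[1], -10)
  expect_equal(sw$grid[100], 0)
  expect_equal(unique(round(diff(sw$grid), 12)), round(10 / 99, 12))
  ## fixed exchange -> single-point sweep with warning
  fixed <- toy
  k <- match("EX_o2", fixed$reactions$id)
  fixed$reactions$lower_bound[k] <- -3
  fixed$reactions$upper_bound[k] <- -3
  expect_warning(sw1 <- perturbation_sweep(fixed, "EX_o2",
                                           list(resp_task), 10),
                 "single-point")
  expect_length(sw1$grid, 1)
})

## toy model with the oxygen exchange trimmed to its attainable range
## (ATP balance caps respiration; beyond it the fixation is infeasible)
toy_o2 <- local({
  m <- toy
  m$reactions$lower_bound[match("EX_o2", m$reactions$id)] <- -2.5
  m
})

test_that("linearly coupled responses give rescaled slope magnitude 1", {
  ## CO2 output equals the fixed oxygen uptake exactly (1:1 coupling),
  ## so the rescaled response is linearly decreasing in the exchange
  ## flux: slope -1 up to LP tolerance
  sw <- perturbation_sweep(toy_o2, "EX_o2", list(resp_task), n_steps = 25)
  sl <- response_slope(sw, min_points = 5)
  expect_equal(unname(sl["resp"]), -1, tolerance = 1e-6)
  ## slope is invariant to affine rescaling of the raw task units
  sw2 <- sw
  sw2$values <- 7.3 * sw$values + 2.1
  expect_equal(unname(response_slope(sw2, min_points = 5)["resp"]),
               unname(sl["resp"]), tolerance = 1e-9)
  ## constant response and under-supported fits give 0 with a flag
  swc <- sw
  swc$values[] <- 5
  slc <- response_slope(swc, min_points = 5)
  expect_equal(unname(slc["resp"]), 0)
  expect_true(attr(slc, "flagged")["resp"])
  swna <- sw
  swna$values[4:25, ] <- NA
  sln <- response_slope(swna, min_points = 10)
  expect_equal(unname(sln["resp"]), 0)
  expect_true(attr(sln, "flagged")["resp"])
})

test_that("cube flattening is task-major with exact round trip", {
  a <- array(as.numeric(1:8), c(2, 2, 2),
             dimnames = list(c("t1", "t2"), c("m1", "m2"), c("p1", "p2")))
  flat <- flatten_cube(a)
  expect_equal(dim(flat), c(2, 4))
  expect_identical(colnames(flat), c("t1|m1", "t1|m2", "t2|m1", "t2|m2"))
  expect_equal(unname(flat["p1", "t2|m1"]), a["t2", "m1", "p1"])
  back <- unflatten_cube(flat, c("t1", "t2"), c("m1", "m2"))
  expect_identical(back, a)
  ## missing cells propagate
  a[1, 2, 1] <- NA
  expect_true(is.na(flatten_cube(a)["p1", "t1|m2"]))
  ## the cohort-scale shape: 16 tasks x 53 metabolites -> 848 columns
  big <- array(0, c(16, 53, 3),
               dimnames = list(paste0("t", 1:16), paste0("m", 1:53),
                               paste0("p", 1:3)))
  expect_equal(ncol(flatten_cube(big)), 848)
})

test_that("PLS-DA recovers a single discriminative feature", {
  set.seed(71)
  n <- 30; p <- 25
  X <- matrix(rnorm(n * p, sd = 0.3), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  labels <- rep(c("g1", "g2"), each = n / 2)
  X[labels == "g2", 7] <- X[labels == "g2", 7] + 4   # feature f7 drives
  fit <- plsda(X, labels, n_components = 3)
  rk <- plsda_feature_ranking(fit, 1)
  expect_identical(names(rk)[1], "f7")
  ## component-1 scores separate the groups with zero overlap
  s1 <- fit$scores[, 1]
  expect_true(max(s1[labels == "g1"]) < min(s1[labels == "g2"]) ||
                min(s1[labels == "g1"]) > max(s1[labels == "g2"]))
  ## successive score vectors are orthogonal
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  ## explained label variance lies in [0, 1] and decreases sensibly
  expect_true(all(fit$explained_y_variance >= 0 &
                    fit$explained_y_variance <= 1))
  expect_error(plsda(X, rep("g1", n)), "2 groups")
  ## zero-variance features are dropped with a warning
  X0 <- cbind(X, fz = 1)
  expect_warning(plsda(X0, labels, 2), "zero-variance")
})

test_that("permuted labels kill the explained label variance", {
  set.seed(72)
  n <- 24
  X <- matrix(rnorm(n * 10, sd = 0.3), n, 10)
  labels <- rep(c("g1", "g2"), each = n / 2)
  X[labels == "g2", 3] <- X[labels == "g2", 3] + 3
  real <- plsda(X, labels, 1)$explained_y_variance[1]
  null <- replicate(200, {
    plsda(X, sample(labels), 1)$explained_y_variance[1]
  })
  ## the true labeling must beat the 95th percentile of the null
  expect_gt(real, quantile(null, 0.95))
})

test_that("pca_check separates constructed clouds", {
  set.seed(73)
  a <- matrix(rnorm(50 * 3, mean = 0, sd = 0.2), 50)
  b <- sweep(matrix(rnorm(50 * 3, sd = 0.2), 50), 2, c(5, 0, 0), `+`)
  c3 <- sweep(matrix(rnorm(50 * 3, sd = 0.2), 50), 2, c(0, 5, 0), `+`)
  pc <- pca_check(rbind(a, b, c3), rep(c("a", "b", "c"), each = 50))
  expect_gt(pc$silhouette, 0.5)
  pc0 <- pca_check(rbind(a, a), rep(c("a", "b"), each = 50))
  expect_lt(abs(pc0$silhouette), 0.1)
  ## deterministic under identical input
  pc2 <- pca_check(rbind(a, b, c3), rep(c("a", "b", "c"), each = 50))
  expect_identical(pc$scores, pc2$scores)
  expect_error(pca_check(a, rep("a", 50)), "2 origin labels")
})

test_that("sensitivity cubes assemble per patient and serialize", {
  models <- list(p1 = toy_o2, p2 = set_biomass_floor(toy_o2, 0.3))
  map <- c(oxygen = "EX_o2", glucose = "EX_glc")
  cube <- build_cube(models, map, list(resp_task), n_steps = 8,
                     min_points = 4)
  expect_equal(dim(cube$values), c(1, 2, 2))
  expect_equal(unname(cube$values["resp", "oxygen", "p1"]), -1,
               tolerance = 1e-6)
  d <- tempfile()
  write_cube(cube, d)
  expect_true(file.exists(file.path(d, "p1.tsv")))
  expect_true(file.exists(file.path(d, "axes.json")))
})
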