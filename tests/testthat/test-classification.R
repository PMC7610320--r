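make_test_decs <- function(n_trials = 2, n_cycles = 5, seed = 1) {
  decs <- list()
  for (i in seq_len(n_trials)) {
    spec <- synth_spec(n_cycles = n_cycles, seed = seed + i)
    sim <- synthesize_normalized_emg(spec)
    decs[[sprintf("T%02d", i)]] <- synergait:::new_decomposition(
      sim$truth$W_true, sim$truth$H_true, R2 = 1, iterations = 0)
  }
  decs
}

test_that("the primitive pool stacks normalized mean cycles", {
  decs <- make_test_decs(2)
  pool <- build_primitive_pool(decs)
  expect_equal(dim(pool), c(8L, 200L))
  expect_true(all(abs(apply(pool, 1, max) - 1) < 1e-12))
  expect_true(all(abs(apply(pool, 1, min)) < 1e-12))
  meta <- attr(pool, "meta")
  expect_equal(meta$trial, rep(c("T01", "T02"), each = 4))
  expect_equal(meta$synergy, rep(1:4, 2))
  # constant primitives become zero rows and are flagged
  decs[[1]]$H[2, ] <- 0.4
  expect_warning(pool2 <- build_primitive_pool(decs), "constant")
  expect_true(all(pool2[2, ] == 0))
  expect_true(attr(pool2, "degenerate")[2])
  expect_error(build_primitive_pool(list()), "empty")
})

test_that("principal-shape clustering recovers planted bump shapes", {
  set.seed(42)
  centers <- c(25, 75, 125, 175)
  pool <- do.call(rbind, lapply(1:20, function(i) {
    b <- synergait:::.bump(centers[(i - 1) %% 4 + 1] + rnorm(1, 0, 2), 18)
    pmax(b + rnorm(200, 0, 0.02), 0)
  }))
  sh <- cluster_principal_shapes(pool, max_rank_observed = 4, base_seed = 3,
                                 n_restarts = 5)
  expect_equal(nrow(sh$shapes), 4L)
  expect_true(all(abs(apply(sh$shapes, 1, max) - 1) < 1e-12))
  # every planted bump is matched by some shape with high cosine similarity
  sims <- vapply(centers, function(cc) {
    b <- synergait:::.bump(cc, 18)
    max(apply(sh$shapes, 1, cosine_sim, b = b))
  }, numeric(1))
  expect_true(all(sims >= 0.95))
  expect_setequal(sh$functional_order,
                  setdiff(SYNERGY_LABELS, "combined"))
  # a pool of copies of one shape clusters at rank 1
  pool1 <- do.call(rbind, lapply(1:10, function(i)
    pmax(synergait:::.bump(75, 18) + rnorm(200, 0, 0.01), 0)))
  sh1 <- cluster_principal_shapes(pool1, max_rank_observed = 2,
                                  base_seed = 5, n_restarts = 3)
  expect_equal(nrow(sh1$shapes), 1L)
  # determinism under a fixed seed
  sh1b <- cluster_principal_shapes(pool1, max_rank_observed = 2,
                                   base_seed = 5, n_restarts = 3)
  expect_identical(sh1$shapes, sh1b$shapes)
})

test_that("functional ordering follows peak phase with prototype fallback", {
  mk <- function(peaks) do.call(rbind, lapply(peaks, synergait:::.bump,
                                              sigma = 10))
  expect_equal(label_by_function(mk(c(20, 75, 115, 180))),
               c("weight_acceptance", "propulsion", "early_swing",
                 "late_swing"))
  # permuted input keeps per-shape labels attached to the right shape
  expect_equal(label_by_function(mk(c(180, 20, 115, 75))),
               c("late_swing", "weight_acceptance", "early_swing",
                 "propulsion"))
  expect_equal(label_by_function(mk(c(20, 75, 180))),
               c("weight_acceptance", "propulsion", "late_swing"))
  # boundary peak at the stance/swing divide goes to the stance side
  expect_equal(label_by_function(mk(100)), "propulsion")
  # identical peak indices fall back to the center-of-mass tie-break
  two <- rbind(c(rep(0, 20), 1, rep(0, 179)),
               c(rep(0, 20), 1, rep(0.5, 100), rep(0, 79)))
  expect_message(labs <- label_by_function(two), "center of mass")
  expect_equal(labs[1], "weight_acceptance")
})

test_that("primitives are labelled fundamental or combined by the two-step rule", {
  set.seed(9)
  centers <- c(25, 75, 125, 175)
  rows <- lapply(1:16, function(i)
    pmax(synergait:::.bump(centers[(i - 1) %% 4 + 1], 18) +
           rnorm(200, 0, 0.02), 0))
  # plant 4 blended primitives: equal-weight sums of two distant bumps
  blends <- lapply(1:4, function(i) {
    b <- synergait:::.bump(centers[i], 18) +
      synergait:::.bump(centers[(i %% 4) + 1], 18)
    b / max(b)
  })
  pool <- do.call(rbind, c(rows, blends))
  pool <- t(apply(pool, 1, function(x) (x - min(x)) / (max(x) - min(x))))
  attr(pool, "meta") <- data.frame(trial = "T", synergy = 1:20)
  sh <- cluster_principal_shapes(pool, max_rank_observed = 4, base_seed = 11,
                                 n_restarts = 5)
  labs <- assign_labels(sh, pool)
  expect_length(labs$label, 20L)
  # a pure-bump primitive identical to a shape passes any threshold
  expect_true(all(labs$label[1:16] != "combined"))
  # the planted 20% blend fraction is recovered within 10 points
  frac <- mean(labs$label == "combined")
  expect_lt(abs(frac - 0.20), 0.10)
  # every primitive gets exactly one label
  expect_true(all(labs$label %in% SYNERGY_LABELS))
})

test_that("label assignment is invariant to the order primitives enter the pool", {
  set.seed(23)
  centers <- c(25, 75, 125, 175)
  rows <- lapply(1:12, function(i)
    pmax(synergait:::.bump(centers[(i - 1) %% 4 + 1], 18) +
           rnorm(200, 0, 0.02), 0))
  pool <- do.call(rbind, rows)
  pool <- t(apply(pool, 1, function(x) (x - min(x)) / (max(x) - min(x))))
  attr(pool, "meta") <- data.frame(trial = "T", synergy = 1:12)
  sh <- cluster_principal_shapes(pool, 4, base_seed = 2, n_restarts = 5)
  labs <- assign_labels(sh, pool)
  perm <- sample(12)
  pool_p <- pool[perm, ]
  attr(pool_p, "meta") <- data.frame(trial = "T", synergy = perm)
  sh_p <- cluster_principal_shapes(pool_p, 4, base_seed = 2, n_restarts = 5)
  labs_p <- assign_labels(sh_p, pool_p)
  expect_equal(labs_p$label, labs$label[perm])
})

test_that("occurrence tables count participants per condition and function", {
  df <- expand.grid(participant = sprintf("P%02d", 1:15),
                    group = "G2", locomotion = "R", speed = c(2.8, 4.2),
                    label = setdiff(SYNERGY_LABELS, "combined"),
                    stringsAsFactors = FALSE)
  tab <- occurrence_table(df)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab[setdiff(SYNERGY_LABELS, "combined")] == 15))
  # three participants whose propulsion synergy is combined drop out of
  # the propulsion count only
  df2 <- df[!(df$label == "propulsion" & df$speed == 2.8 &
                df$participant %in% c("P01", "P02", "P03")), ]
  tab2 <- occurrence_table(df2)
  expect_equal(tab2$propulsion[tab2$speed == 2.8], 12L)
  expect_equal(tab2$propulsion[tab2$speed == 4.2], 15L)
  expect_equal(tab2$late_swing[tab2$speed == 2.8], 15L)
  expect_error(occurrence_table(df[1:3]), "columns")
})
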