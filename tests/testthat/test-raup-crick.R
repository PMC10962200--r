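test_that("regional pool is the occurrence-weighted union across patients", {
  s1 <- series_from_sets(list(c("A", "B", "C"), c("B", "C")), c(0, 800), "P1")
  s2 <- series_from_sets(list(c("B", "C", "D"), c("C", "D")), c(0, 900), "P2")
  ds <- cohort_dataset(list(s1, s2))
  pool <- build_regional_pool(ds, "microbiota")
  expect_setequal(pool$taxa, c("A", "B", "C", "D"))
  expect_equal(pool$occurrence[match(c("A", "B", "C", "D"), pool$taxa)],
               c(1L, 3L, 4L, 2L))
  expect_equal(sum(pool$weights), 1)
  uni <- build_regional_pool(ds, "microbiota", "uniform")
  expect_equal(uni$weights, rep(0.25, 4))
  # group pools restrict to taxa holding that status somewhere
  chr <- build_regional_pool(ds, "chronic")
  expect_setequal(chr$taxa, c("B", "C", "D"))
})

test_that("exact oracle reproduces the closed-form worked values", {
  p6 <- species_pool(letters[1:6], weighting = "uniform")
  p10 <- species_pool(letters[1:10], weighting = "uniform")
  expect_equal(exact_null_srcs(p6, 2, 2, 2)$s_rc, 2 * (14.5 / 15) - 1,
               tolerance = 1e-12)
  expect_equal(exact_null_srcs(p10, 2, 2, 2)$s_rc, 2 * (44.5 / 45) - 1,
               tolerance = 1e-12)
  # and matches an independent binomial-coefficient oracle on random cases
  set.seed(12)
  for (i in 1:25) {
    N <- sample(4:12, 1)
    n_a <- sample(N, 1); n_b <- sample(N, 1)
    pool <- species_pool(paste0("t", 1:N), weighting = "uniform")
    feasible <- max(0, n_a + n_b - N):min(n_a, n_b)
    sh <- if (length(feasible) == 1) feasible else sample(feasible, 1)
    expect_equal(exact_null_srcs(pool, n_a, n_b, sh)$s_rc,
                 hyper_src_oracle(N, n_a, n_b, sh), tolerance = 1e-12)
  }
  # infeasible shared counts are a precondition error
  expect_error(exact_null_srcs(p6, 6, 6, 0), "impossible")
  wpool <- species_pool(paste0("t", 1:13), occurrence = 1:13)
  expect_error(exact_null_srcs(wpool, 2, 2, 1), "refused")
})

test_that("weighted enumeration agrees with brute-force Monte Carlo", {
  pool <- species_pool(c("w", "x", "y", "z"), occurrence = c(4, 3, 2, 1))
  ex <- exact_null_srcs(pool, 2, 2, 1)
  expect_equal(sum(ex$distribution), 1, tolerance = 1e-12)
  # independent oracle: base-R successive weighted sampling
  set.seed(31)
  iters <- 40000
  shared <- replicate(iters, {
    A <- sample(4, 2, prob = pool$weights)
    B <- sample(4, 2, prob = pool$weights)
    length(intersect(A, B))
  })
  p_mc <- mean(shared < 1) + 0.5 * mean(shared == 1)
  se <- sqrt(ex$p * (1 - ex$p) / iters)
  expect_lt(abs(p_mc - ex$p), 3 * se)
  # the packaged Monte-Carlo kernel agrees with the enumeration too
  rc <- raup_crick_pair(c("w", "x"), c("w", "y"), pool,
                        iterations = 40000, seed = 99)
  expect_lt(abs(rc$s_rc - ex$s_rc), 2 * 3 * se)
})

test_that("Monte-Carlo index matches the exact oracle across random cases", {
  set.seed(20)
  iters <- 20000
  ok <- 0
  n_cases <- 50
  for (i in seq_len(n_cases)) {
    N <- sample(4:12, 1)
    taxa <- paste0("t", 1:N)
    pool <- species_pool(taxa, weighting = "uniform")
    A <- sample(taxa, sample(N, 1))
    B <- sample(taxa, sample(N, 1))
    ex <- exact_null_srcs(pool, length(A), length(B),
                          length(intersect(A, B)))
    mc <- raup_crick_pair(A, B, pool, iterations = iters, seed = 1000 + i)
    tol <- 2 * 3 * sqrt(ex$p * (1 - ex$p) / iters)
    ok <- ok + (abs(mc$s_rc - ex$s_rc) <= tol)
  }
  expect_gte(ok / n_cases, 0.95)
})

test_that("index is bounded, symmetric, and deterministic under seeds", {
  pool <- species_pool(paste0("t", 1:30), occurrence = rep(c(3L, 1L), 15))
  A <- paste0("t", c(1, 3, 5, 7, 9))
  B <- paste0("t", c(1, 2, 3, 11, 13, 15))
  r1 <- raup_crick_pair(A, B, pool, 500, seed = 7)
  r2 <- raup_crick_pair(B, A, pool, 500, seed = 7)
  expect_identical(r1$s_rc, r2$s_rc)
  r3 <- raup_crick_pair(A, B, pool, 500, seed = 7)
  expect_identical(r1$s_rc, r3$s_rc)
  expect_gte(r1$s_rc, -1); expect_lte(r1$s_rc, 1)
  # p = 1 <-> s_rc = 1 rescaling identity on the counts scale
  expect_equal(r1$s_rc, 2 * r1$p - 1)

  # both communities equal to the whole pool: all null draws tie -> s_rc = 0
  all_t <- pool$taxa
  tie <- raup_crick_pair(all_t, all_t, pool, 300, seed = 3)
  expect_equal(tie$s_rc, 0)
  expect_equal(tie$process, "drift")

  expect_error(raup_crick_pair(c("t1", "nope"), A, pool), "outside the pool")
  expect_error(raup_crick_pair(character(0), A, pool), "nonempty")
})

test_that("within-patient matrix enumerates pairs reproducibly", {
  set.seed(8)
  sets <- lapply(1:6, function(i) paste0("t", sample(30, sample(5:10, 1))))
  s <- series_from_sets(sets, days = c(0, 100, 300, 500, 800, 1000), "P9")
  pool <- species_pool(paste0("t", 1:30), weighting = "uniform")
  m1 <- raup_crick_matrix(s, pool, iterations = 300, seed = 5)
  expect_equal(nrow(m1), 15)  # 6 choose 2
  m2 <- raup_crick_matrix(s, pool, iterations = 300, seed = 5)
  expect_identical(m1$s_rc, m2$s_rc)
  m3 <- raup_crick_matrix(s, pool, iterations = 300, seed = 6)
  expect_false(identical(m1$s_rc, m3$s_rc))
  expect_true(all(m1$s_rc >= -1 & m1$s_rc <= 1))
})

test_that("process classification thresholds are inclusive", {
  expect_equal(classify_process(0.95), "homogenizing_dispersal")
  expect_equal(classify_process(0.9499), "drift")
  expect_equal(classify_process(-0.97), "dispersal_limitation")
  expect_equal(classify_process(-0.95), "dispersal_limitation")
  expect_equal(classify_process(c(1, -1, 0)),
               c("homogenizing_dispersal", "dispersal_limitation", "drift"))
  expect_error(classify_process(1.2), "\\[-1, 1\\]")
})

test_that("process frequencies sum to 100", {
  pairs <- data.frame(patient_id = "P1", group = "microbiota",
                      process = rep("drift", 15))
  f <- process_frequencies(pairs)
  expect_equal(c(f$pct_homogenizing, f$pct_drift, f$pct_limitation),
               c(0, 100, 0))
  pairs2 <- data.frame(patient_id = "P1", group = "chronic",
                       process = c(rep("homogenizing_dispersal", 12),
                                   rep("drift", 3)))
  f2 <- process_frequencies(pairs2)
  expect_equal(c(f2$pct_homogenizing, f2$pct_drift, f2$pct_limitation),
               c(80, 20, 0))
  expect_equal(f2$pct_homogenizing + f2$pct_drift + f2$pct_limitation, 100,
               tolerance = 1e-9)
  expect_error(process_frequencies(pairs[0, ]), "no pairs")
})

test_that("random draws from the pool are classified drift (null consistency)", {
  set.seed(44)
  pool <- species_pool(paste0("t", 1:80), occurrence = sample(1:6, 80, TRUE))
  res <- replicate(100, {
    A <- pool$taxa[sample(80, sample(10:25, 1), prob = pool$weights)]
    B <- pool$taxa[sample(80, sample(10:25, 1), prob = pool$weights)]
    raup_crick_pair(A, B, pool, iterations = 500,
                    seed = sample.int(1e6, 1))$process
  })
  expect_gte(mean(res == "drift"), 0.9)
})
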