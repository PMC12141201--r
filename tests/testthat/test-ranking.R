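test_that("rank-sum weights follow the closed form, sum to one and decrease", {
  expect_equal(rank_sum_weights(1), 1)
  expect_equal(rank_sum_weights(2), c(2 / 3, 1 / 3))
  expect_equal(rank_sum_weights(4), c(0.4, 0.3, 0.2, 0.1))
  for (n in c(1:20, 50, 137, 1000)) {
    w <- rank_sum_weights(n)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    if (n > 1) expect_true(all(diff(w) < 0))
    expect_true(all(w > 0))
  }
  expect_error(rank_sum_weights(0), class = "vs_parameter_error")
})

test_that("the combined fitness reproduces a hand-evaluated instance", {
  ## f1 = (0.9, 0.5, 0.1), f2 = (-9, -5, -1):
  ## E(f1^2) = 107/300, E(f2^2) = 107/3,
  ## f(A) = (2/3)(0.9*300/107) + (1/3)(9*3/107) = 1.76636...
  tab <- data.frame(drug_id = c("A", "B", "C"),
                    similarity = c(0.9, 0.5, 0.1),
                    binding_energy = c(-9, -5, -1))
  sc <- fitness_scores(tab, mode = "ss_plus_be")
  expect_equal(sc$fitness[1], (2 / 3) * (0.9 * 300 / 107) + (1 / 3) * (9 * 3 / 107),
               tolerance = 1e-12)
  expect_equal(sc$fitness[1], 1.7664, tolerance = 1e-4)
  ranked <- rank_candidates(sc, tab)
  expect_identical(ranked$drug_id, c("A", "B", "C"))
})

test_that("fitness matches the independent oracle across modes on random instances", {
  set.seed(405)
  for (rep in 1:200) {
    n <- sample(2:100, 1)
    f1 <- stats::runif(n)
    f2 <- -stats::runif(n, 1, 12)
    tab <- data.frame(drug_id = sprintf("d%03d", sample(n)), similarity = f1,
                      binding_energy = f2)
    for (mode in c("ss", "be", "ss_plus_be")) {
      got <- fitness_scores(tab, mode = mode)
      expect_equal(got$fitness, oracle_fitness(f1, f2, mode), tolerance = 1e-9)
      ## ranking equals an independently coded stable sort
      ranked <- rank_candidates(got, tab)
      ord <- order(-got$fitness, -f1, tab$drug_id)
      expect_identical(ranked$drug_id, tab$drug_id[ord])
      expect_identical(ranked$rank, seq_len(n))
    }
  }
})

test_that("single-drug input evaluates the formula and ranks first", {
  tab <- data.frame(drug_id = "only", similarity = 0.4, binding_energy = -6)
  sc <- fitness_scores(tab, mode = "ss_plus_be")
  expect_equal(sc$fitness, (2 / 3) * 0.4 / 0.16 + (1 / 3) * 6 / 36)
  expect_identical(rank_candidates(sc, tab)$rank, 1L)
})

test_that("joint rescaling of both criteria preserves ordering and scales fitness by 1/c", {
  set.seed(406)
  for (rep in 1:250) {
    n <- sample(3:60, 1)
    f1 <- stats::runif(n); f2 <- -stats::runif(n, 1, 12)
    c0 <- stats::runif(1, 0.1, 10)
    tab <- data.frame(drug_id = sprintf("d%02d", seq_len(n)), similarity = f1,
                      binding_energy = f2)
    tab2 <- transform(tab, similarity = c0 * similarity,
                      binding_energy = c0 * binding_energy)
    s1 <- fitness_scores(tab, "ss_plus_be")
    s2 <- fitness_scores(tab2, "ss_plus_be")
    expect_equal(s2$fitness, s1$fitness / c0, tolerance = 1e-9)
    expect_identical(rank_candidates(s2, tab2)$drug_id,
                     rank_candidates(s1, tab)$drug_id)
  }
})

test_that("at fixed normalization constants fitness is monotone in each criterion", {
  set.seed(407)
  for (rep in 1:250) {
    n <- sample(3:40, 1)
    f1 <- stats::runif(n); f2 <- -stats::runif(n, 1, 12)
    e1 <- mean(f1^2); e2 <- mean(f2^2)
    w <- rank_sum_weights(2)
    fit <- function(a, b) w[1] * a / e1 - w[2] * b / e2
    k <- sample(n, 1)
    expect_gt(fit(f1[k] + 0.1, f2[k]), fit(f1[k], f2[k]))
    expect_gt(fit(f1[k], f2[k] - 0.5), fit(f1[k], f2[k]))
  }
})

test_that("degenerate modes collapse onto single objectives", {
  set.seed(408)
  n <- 30
  f1 <- stats::runif(n); f2 <- -stats::runif(n, 1, 12)
  ids <- sprintf("d%02d", seq_len(n))
  ## all f2 equal: ss_plus_be ordering == ss ordering
  tab <- data.frame(drug_id = ids, similarity = f1, binding_energy = rep(-5, n))
  expect_identical(rank_candidates(fitness_scores(tab, "ss_plus_be"), tab)$drug_id,
                   rank_candidates(fitness_scores(tab, "ss"), tab)$drug_id)
  ## all f1 equal: ss_plus_be ordering == be ordering
  tab <- data.frame(drug_id = ids, similarity = rep(0.5, n), binding_energy = f2)
  expect_identical(rank_candidates(fitness_scores(tab, "ss_plus_be"), tab)$drug_id,
                   rank_candidates(fitness_scores(tab, "be"), tab)$drug_id)
})

test_that("ties are broken by higher similarity, then drug id", {
  tab <- data.frame(drug_id = c("x", "y", "z"), similarity = c(0.6, 0.8, 0.8),
                    binding_energy = c(-5, -5, -5))
  sc <- data.frame(drug_id = tab$drug_id, fitness = c(1, 1, 1))
  expect_identical(rank_candidates(sc, tab)$drug_id, c("y", "z", "x"))
  expect_identical(rank_candidates(data.frame(drug_id = c("a", "b", "c"),
                                              fitness = c(0.2, 0.9, 0.5)))$drug_id,
                   c("b", "c", "a"))
})

test_that("degenerate all-zero criteria raise a named error", {
  tab <- data.frame(drug_id = c("a", "b"), similarity = c(0, 0),
                    binding_energy = c(-3, -4))
  expect_error(fitness_scores(tab, "ss_plus_be"), "similarity",
               class = "vs_rank_error")
  tab2 <- data.frame(drug_id = c("a", "b"), similarity = c(0.2, 0.4),
                     binding_energy = c(0, 0))
  expect_error(fitness_scores(tab2, "ss_plus_be"), "binding",
               class = "vs_rank_error")
})

test_that("the rms normalization variant evaluates per its definition", {
  set.seed(409)
  n <- 40
  tab <- data.frame(drug_id = sprintf("d%02d", 1:n),
                    similarity = stats::runif(n),
                    binding_energy = -stats::runif(n, 1, 12))
  s_ms <- fitness_scores(tab, "ss_plus_be", normalization = "mean_square")
  s_rms <- fitness_scores(tab, "ss_plus_be", normalization = "rms")
  expect_equal(s_rms$fitness, oracle_fitness(tab$similarity, tab$binding_energy,
                                             "ss_plus_be", "rms"), tolerance = 1e-9)
  expect_false(identical(s_ms$fitness, s_rms$fitness))
})
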