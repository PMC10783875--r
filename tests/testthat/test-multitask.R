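zeroed_head <- function(m, prefix) {
  for (suf in c("W1", "b1", "W2", "b2")) {
    nm <- paste0(prefix, ".", suf)
    m$params[[nm]] <- m$params[[nm]] * 0
  }
  m
}

test_that("regression heads route by label type only", {
  m <- mbp_model(gnn_config("gcn", 1, 4), seed = 2)
  o <- rnorm(2 * m$config$d_interaction)
  mz <- zeroed_head(m, "head.reg.K")
  expect_equal(predict_affinity(mz, o, "K"), 0)
  expect_false(predict_affinity(mz, o, "IC50") == 0)
  # shifting the K head moves K predictions only
  m2 <- m
  m2$params[["head.reg.K.b2"]] <- m$params[["head.reg.K.b2"]] + 5
  expect_equal(predict_affinity(m2, o, "K"),
               predict_affinity(m, o, "K") + 5)
  expect_equal(predict_affinity(m2, o, "IC50"),
               predict_affinity(m, o, "IC50"))
  expect_error(predict_affinity(m, o, "Kd"), "unknown task type")
})

test_that("ranking heads emit sigmoid probabilities, 0.5 at zero weights", {
  m <- mbp_model(gnn_config("gcn", 1, 4), seed = 2)
  dI <- m$config$d_interaction
  o1 <- rnorm(2 * dI)
  o2 <- rnorm(2 * dI)
  mz <- zeroed_head(m, "head.rank.IC50")
  expect_equal(predict_rank(mz, o1, o2, "IC50"), 0.5)
  p12 <- predict_rank(m, o1, o2, "K")
  p21 <- predict_rank(m, o2, o1, "K")
  expect_true(p12 > 0 && p12 < 1)
  # the head is not antisymmetric by construction
  expect_false(isTRUE(all.equal(p12, 1 - p21)))
  # direct MLP evaluation oracle
  z <- matrix(c(o1, o2), 1)
  h1 <- pmax(z %*% m$params[["head.rank.K.W1"]] +
               matrix(m$params[["head.rank.K.b1"]], 1), 0) +
    0.01 * pmin(z %*% m$params[["head.rank.K.W1"]] +
                  matrix(m$params[["head.rank.K.b1"]], 1), 0)
  logit <- as.numeric(h1 %*% m$params[["head.rank.K.W2"]]) +
    as.numeric(m$params[["head.rank.K.b2"]])
  expect_equal(p12, 1 / (1 + exp(-logit)), tolerance = 1e-6)
})

test_that("loss primitives match their closed forms", {
  expect_equal(regression_loss(6.0, 6.0), 0)
  expect_equal(regression_loss(6.0, to_paffinity(125)),
               (9 - log10(125) - 6)^2, tolerance = 1e-12)
  expect_equal(ranking_loss(0, 1), log(2))
  expect_equal(ranking_loss(0, 0), log(2))
  expect_equal(ranking_loss(1.5, 1), log1p(exp(-1.5)), tolerance = 1e-12)
  expect_equal(ranking_loss(40, 1), 0, tolerance = 1e-12)
  expect_lt(ranking_loss(5, 1), ranking_loss(1, 1)) # monotone in the logit
  expect_equal(mbp_loss(0.5, 0.25, 1.0), 0.75)
  expect_equal(mbp_loss(0.37, 99, 0), 0.37) # ranking-only ablation
  expect_error(mbp_loss(1, 1, -0.1), "non-negative")
})

test_that("the total pair loss is exactly L_rank + lambda * L_reg", {
  cs1 <- tiny_complex(41)
  cs2 <- tiny_complex(42)
  for (lam in c(0, 0.01, 0.1, 0.3, 1.0)) {
    m <- mbp_model(gnn_config("gcn", 2, 5), lambda = lam, seed = 3)
    b1 <- affpret:::.complex_bundle(complex_graphs(cs1))
    b2 <- affpret:::.complex_bundle(complex_graphs(cs2))
    tp <- affpret:::tape_new()
    pget <- affpret:::.param_getter(tp, m$params)
    pl <- affpret:::.pair_loss_tp(tp, pget, b1, b2, 7.2, 1, "IC50",
                                  m$config, FALSE)
    total <- affpret:::tp_value(tp, pl$total)[1, 1]
    expect_equal(total, pl$l_rank + lam * pl$l_reg, tolerance = 1e-6)
    expect_equal(total, mbp_loss(pl$l_rank, pl$l_reg, lam), tolerance = 1e-6)
  }
})

test_that("the regression term ignores the pair's second label", {
  cs1 <- tiny_complex(43)
  cs2 <- tiny_complex(44)
  m <- mbp_model(gnn_config("gcn", 1, 5), seed = 3)
  b1 <- affpret:::.complex_bundle(complex_graphs(cs1))
  b2 <- affpret:::.complex_bundle(complex_graphs(cs2))
  run <- function(label) {
    tp <- affpret:::tape_new()
    pget <- affpret:::.param_getter(tp, m$params)
    pl <- affpret:::.pair_loss_tp(tp, pget, b1, b2, 6.9, label, "K",
                                  m$config, FALSE)
    pl$l_reg
  }
  # the second sample enters only through the ranking label; with the label
  # fixed, swapping what y_ik would have been cannot move L_reg
  expect_identical(run(1), run(0))
})

test_that("disabled tasks drop their loss terms (task-ablation structure)", {
  cs1 <- tiny_complex(45)
  cs2 <- tiny_complex(46)
  b_of <- function(m) list(affpret:::.complex_bundle(complex_graphs(cs1)),
                           affpret:::.complex_bundle(complex_graphs(cs2)))
  loss_parts <- function(tasks, task_type) {
    m <- mbp_model(gnn_config("gcn", 1, 5), enabled_tasks = tasks, seed = 3)
    b <- b_of(m)
    tp <- affpret:::tape_new()
    pget <- affpret:::.param_getter(tp, m$params)
    pl <- affpret:::.pair_loss_tp(tp, pget, b[[1]], b[[2]], 6.9, 1, task_type,
                                  m$config, FALSE)
    list(total = if (is.null(pl$total)) NA_real_ else
      affpret:::tp_value(tp, pl$total)[1, 1],
      rank = pl$l_rank, reg = pl$l_reg)
  }
  only_rank <- loss_parts("k_rank", "K")
  expect_equal(only_rank$total, only_rank$rank, tolerance = 1e-10)
  expect_equal(only_rank$reg, 0)
  only_reg <- loss_parts("k_reg", "K")
  expect_equal(only_reg$total, 0.1 * only_reg$reg, tolerance = 1e-10)
  off_task <- loss_parts(c("ic50_reg", "ic50_rank"), "K")
  expect_true(is.na(off_task$total)) # K pair contributes nothing
  all4 <- loss_parts(c("ic50_reg", "ic50_rank", "k_reg", "k_rank"), "K")
  expect_equal(all4$total, all4$rank + 0.1 * all4$reg, tolerance = 1e-10)
})

test_that("gradients from a K batch leave both IC50 heads untouched", {
  cs1 <- tiny_complex(47)
  cs2 <- tiny_complex(48)
  m <- mbp_model(gnn_config("gcn", 1, 5), seed = 3)
  b1 <- affpret:::.complex_bundle(complex_graphs(cs1))
  b2 <- affpret:::.complex_bundle(complex_graphs(cs2))
  tp <- affpret:::tape_new()
  pget <- affpret:::.param_getter(tp, m$params)
  pl <- affpret:::.pair_loss_tp(tp, pget, b1, b2, 6.9, 1, "K", m$config, FALSE)
  gr <- affpret:::tape_backward(tp, pl$total)
  ic50_heads <- grep("^head\\.(reg|rank)\\.IC50", names(gr), value = TRUE)
  k_heads <- grep("^head\\.(reg|rank)\\.K", names(gr), value = TRUE)
  encoder <- grep("^(lig|prot|fus|att)", names(gr), value = TRUE)
  expect_true(all(vapply(gr[ic50_heads], function(g) all(g == 0), logical(1))))
  expect_true(any(vapply(gr[k_heads], function(g) any(g != 0), logical(1))))
  expect_true(any(vapply(gr[encoder], function(g) any(g != 0), logical(1))))
})
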