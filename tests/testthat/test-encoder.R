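test_that("final node embeddings equal the sum of per-layer outputs", {
  cs <- tiny_complex(2)
  for (v in c("gcn", "gin", "attentivefp")) {
    m <- mbp_model(gnn_config(v, 3, 6), seed = 4)
    g <- complex_graphs(cs)
    ne <- encode_graph(m, g$ligand)
    expect_equal(ne$embeddings, Reduce(`+`, ne$layers), tolerance = 1e-12)
    np <- encode_graph(m, g$protein)
    expect_equal(np$embeddings, Reduce(`+`, np$layers), tolerance = 1e-12)
  }
})

test_that("node embeddings are permutation-equivariant", {
  set.seed(9)
  coords <- matrix(runif(18, 0, 6), 6)
  elements <- c("C", "N", "O", "C", "S", "C")
  m <- mbp_model(gnn_config("gcn", 2, 8), seed = 1)
  g1 <- build_ligand_graph(make_atoms(coords, elements))
  perm <- sample(6)
  g2 <- build_ligand_graph(make_atoms(coords[perm, ], elements[perm]))
  e1 <- encode_graph(m, g1)$embeddings
  e2 <- encode_graph(m, g2)$embeddings
  expect_equal(e2, e1[perm, ], tolerance = 1e-10)
})

test_that("a single isolated node gets the zero message in every variant", {
  at <- make_atoms(cbind(1, 1, 1))
  for (v in c("gcn", "gin", "gat", "egnn", "attentivefp")) {
    m <- mbp_model(gnn_config(v, 2, 6), seed = 2)
    g <- build_ligand_graph(at)
    e <- encode_graph(m, g)
    expect_equal(dim(e$embeddings), c(1L, 6L))
    expect_true(all(is.finite(e$embeddings)))
    # oracle with an empty neighborhood: identical layer-by-layer result
    H0 <- g$node_features %*% m$params[["lig.embed.W"]] +
      matrix(m$params[["lig.embed.b"]], 1)
    p <- layer_params_of(m, "lig.l1")
    o1 <- switch(v,
      gcn = oracle_layer("gcn", H0, g$edges, g$edge_features, p, 6),
      gin = oracle_layer("gin", H0, g$edges, g$edge_features, p, 6),
      gat = oracle_layer("gat", H0, g$edges, g$edge_features, p, 6),
      egnn = oracle_layer_egnn(H0, g$edges, g$edge_features, g$distances, p, 6),
      attentivefp = oracle_layer_attentivefp(H0, g$edges, g$edge_features, p, 6))
    expect_equal(e$layers[[1]], o1, tolerance = 1e-8)
  }
})

test_that("each variant's layer matches its dense per-node oracle on small graphs", {
  set.seed(12)
  coords <- matrix(runif(18, 0, 5), 6) # 6 nodes, dense-ish graph
  atoms <- make_atoms(coords, c("C", "N", "O", "C", "C", "S"))
  g <- build_ligand_graph(atoms)
  expect_gt(nrow(g$edges), 3)
  d <- 5L
  for (v in c("gcn", "gin", "gat", "egnn", "attentivefp")) {
    m <- mbp_model(gnn_config(v, 2, d), seed = 7)
    ne <- encode_graph(m, g)
    H0 <- g$node_features %*% m$params[["lig.embed.W"]] +
      matrix(m$params[["lig.embed.b"]], 1)[rep(1, nrow(g$node_features)), , drop = FALSE]
    orc <- function(H, prefix) {
      p <- layer_params_of(m, prefix)
      switch(v,
        gcn = oracle_layer("gcn", H, g$edges, g$edge_features, p, d),
        gin = oracle_layer("gin", H, g$edges, g$edge_features, p, d),
        gat = oracle_layer("gat", H, g$edges, g$edge_features, p, d),
        egnn = oracle_layer_egnn(H, g$edges, g$edge_features, g$distances, p, d),
        attentivefp = oracle_layer_attentivefp(H, g$edges, g$edge_features, p, d))
    }
    L1 <- orc(H0, "lig.l1")
    L2 <- orc(L1, "lig.l2")
    expect_equal(ne$layers[[1]], L1, tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(ne$layers[[2]], L2, tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(ne$embeddings, L1 + L2, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("interaction fusion matches the direct per-edge formula", {
  set.seed(14)
  m <- mbp_model(gnn_config("gcn", 1, 4), seed = 3)
  res <- make_residues(matrix(runif(12, 0, 8), 4))
  at <- make_atoms(matrix(runif(9, 0, 8), 3))
  ig <- build_interaction_graph(res, at)
  HP <- matrix(rnorm(4 * 4), 4)
  HL <- matrix(rnorm(3 * 4), 3)
  got <- fuse_interactions(m, HP, HL, ig)
  expect_equal(nrow(got), nrow(ig$edges))
  expect_equal(got, oracle_fusion(m, HP, HL, ig), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("fusion with identity weights exposes the concatenation order", {
  # d = 2, d_interaction = 8, FC width 4: the fused width 2d + 4 = 8 lets
  # identity MLP weights pass the concatenation straight through
  m <- mbp_model(gnn_config("gcn", 1, 2), d_interaction = 8, seed = 5)
  m$params[["fus.W1"]] <- diag(8)
  m$params[["fus.b1"]] <- matrix(0, 1, 8)
  m$params[["fus.W2"]] <- diag(8)
  m$params[["fus.b2"]] <- matrix(0, 1, 8)
  m$params[["fus.fc.W"]] <- matrix(0.1, 16, 4)
  m$params[["fus.fc.b"]] <- matrix(0, 1, 4)
  res <- make_residues(cbind(0, 0, 0))
  at <- make_atoms(cbind(3, 0, 0))
  ig <- build_interaction_graph(res, at)
  HP <- matrix(c(1, 2), 1)
  HL <- matrix(c(5, 7), 1)
  out <- fuse_interactions(m, HP, HL, ig)
  expect_equal(out[1, 1:2], c(1, 2))            # protein block first
  expect_equal(out[1, 3:4], c(5, 7))            # ligand block second
  fc <- as.numeric(ig$edge_features[1, ] %*% m$params[["fus.fc.W"]])
  expect_equal(out[1, 5:8], fc)                 # transformed edge block last
})

test_that("empty interaction edge sets raise an explicit no-contact error", {
  m <- mbp_model(gnn_config("gcn", 1, 4), seed = 3)
  res <- make_residues(cbind(0, 0, 0))
  at <- make_atoms(cbind(100, 0, 0))
  ig <- build_interaction_graph(res, at)
  expect_equal(nrow(ig$edges), 0L)
  expect_error(fuse_interactions(m, matrix(0, 1, 4), matrix(0, 1, 4), ig),
               class = "affpret_no_contact")
})

test_that("read-out follows the attention formula and is permutation-invariant", {
  set.seed(15)
  m <- mbp_model(gnn_config("gcn", 1, 4), seed = 6)
  hI <- matrix(rnorm(5 * 4), 5)
  ce <- readout(m, hI)
  expect_equal(ce$o, oracle_readout(hI, as.numeric(m$params[["att.w"]])),
               tolerance = 1e-6)
  expect_equal(ce$o, c(ce$o_sum, ce$o_max))
  expect_true(all(ce$attention > -1 & ce$attention < 1))
  perm <- sample(5)
  ce2 <- readout(m, hI[perm, ])
  expect_equal(ce2$o, ce$o, tolerance = 1e-12)
  # zero attention vector nulls o_sum but not o_max
  m$params[["att.w"]] <- matrix(0, 4, 1)
  ce0 <- readout(m, hI)
  expect_equal(ce0$o_sum, numeric(4) + 0)
  expect_equal(ce0$o_max, apply(hI, 2, max))
  # single edge: o_sum = tanh(w . h) h, o_max = h
  m$params[["att.w"]] <- matrix(c(1, -1, 0.5, 0), 4, 1)
  h <- matrix(rnorm(4), 1)
  ce1 <- readout(m, h)
  expect_equal(ce1$o_sum, as.numeric(tanh(sum(h * c(1, -1, 0.5, 0))) * h))
  expect_equal(ce1$o_max, as.numeric(h))
})

test_that("complex encoding is deterministic and rigid-motion invariant", {
  cs <- tiny_complex(8)
  for (v in c("gcn", "egnn")) {
    m <- mbp_model(gnn_config(v, 2, 6), seed = 9)
    e1 <- encode_complex(m, cs)
    e2 <- encode_complex(m, cs)
    expect_identical(e1$o, e2$o)
    R <- random_rotation()
    shift <- c(3, -1, 7)
    rot <- function(df) {
      xyz <- sweep(as.matrix(df[, c("x", "y", "z")]) %*% R, 2, shift, "+")
      df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
      df
    }
    cs2 <- cs
    cs2$protein <- rot(cs$protein)
    cs2$ligand <- rot(cs$ligand)
    class(cs2$protein) <- class(cs$protein)
    class(cs2$ligand) <- class(cs$ligand)
    attr(cs2$ligand, "bonds") <- attr(cs$ligand, "bonds")
    e3 <- encode_complex(m, cs2)
    expect_equal(e3$o, e1$o, tolerance = 1e-6)
  }
})

test_that("tape gradients of the full pair loss match numerical differentiation", {
  cs1 <- tiny_complex(21)
  cs2 <- tiny_complex(22)
  m <- mbp_model(gnn_config("gcn", 2, 4), seed = 11)
  b1 <- affpret:::.complex_bundle(complex_graphs(cs1))
  b2 <- affpret:::.complex_bundle(complex_graphs(cs2))
  loss_at <- function(params) {
    tp <- affpret:::tape_new()
    pget <- affpret:::.param_getter(tp, params)
    pl <- affpret:::.pair_loss_tp(tp, pget, b1, b2, 6.5, 1, "K", m$config, FALSE)
    affpret:::tp_value(tp, pl$total)[1, 1]
  }
  tp <- affpret:::tape_new()
  pget <- affpret:::.param_getter(tp, m$params)
  pl <- affpret:::.pair_loss_tp(tp, pget, b1, b2, 6.5, 1, "K", m$config, FALSE)
  gr <- affpret:::tape_backward(tp, pl$total)
  set.seed(33)
  eps <- 1e-6
  for (nm in sample(names(gr), 8)) {
    i <- sample(length(m$params[[nm]]), 1)
    p_up <- m$params
    p_up[[nm]][i] <- p_up[[nm]][i] + eps
    p_dn <- m$params
    p_dn[[nm]][i] <- p_dn[[nm]][i] - eps
    num <- (loss_at(p_up) - loss_at(p_dn)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("every parameter group receives gradient from a mixed-task batch", {
  cs1 <- tiny_complex(31)
  cs2 <- tiny_complex(32)
  for (v in c("gcn", "gin", "gat", "egnn", "attentivefp")) {
    m <- mbp_model(gnn_config(v, 2, 5), seed = 13)
    b1 <- affpret:::.complex_bundle(complex_graphs(cs1))
    b2 <- affpret:::.complex_bundle(complex_graphs(cs2))
    tp <- affpret:::tape_new()
    pget <- affpret:::.param_getter(tp, m$params)
    l1 <- affpret:::.pair_loss_tp(tp, pget, b1, b2, 6.5, 1, "K", m$config, FALSE)
    l2 <- affpret:::.pair_loss_tp(tp, pget, b2, b1, 5.5, 0, "IC50", m$config, FALSE)
    tot <- affpret:::tp_add(tp, l1$total, l2$total)
    gr <- affpret:::tape_backward(tp, tot)
    nz <- vapply(gr, function(g) any(g != 0), logical(1))
    expect_true(all(nz), label = paste("gradient flow for", v))
  }
})
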