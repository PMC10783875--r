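# Shared-bottom encoder: message passing over the ligand and protein graphs
# (jumping-knowledge layer sum), fusion of the two towers along the
# interaction edges, and tanh-attention + max-pool read-out into a single
# complex embedding o = o_sum || o_max.
#
# All variants share the same skeleton: a linear input embedding to the
# hidden width d, then `n_layers` message-passing layers d -> d whose
# formulas follow each variant's defining paper (GCN normalized sum, GIN sum
# + MLP update, GAT attention, EGNN distance-aware messages, AttentiveFP
# gated attention with a GRU update). Edge features enter the message
# function; isolated nodes receive the zero message.

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

.GNN_VARIANTS <- c("gcn", "gin", "gat", "egnn", "attentivefp")

#' Encoder configuration
#'
#' @param variant GNN variant: one of `"gcn"`, `"gin"`, `"gat"`, `"egnn"`,
#'   `"attentivefp"`.
#' @param n_layers number of message-passing layers (>= 1).
#' @param hidden_dim hidden width d of node embeddings.
#' @param dropout dropout rate applied to layer outputs during training.
#' @return a `gnn_config` list.
#' @export
gnn_config <- function(variant = "gcn", n_layers = 2L, hidden_dim = 16L,
                       dropout = 0.1) {
  variant <- match.arg(tolower(variant), .GNN_VARIANTS)
  .assert(n_layers >= 1L, "n_layers must be >= 1")
  .assert(hidden_dim >= 1L, "hidden_dim must be >= 1")
  .assert(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(variant = variant, n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim), dropout = dropout),
            class = "gnn_config")
}

# ---- tape-side graph bundles ------------------------------------------------

# Directed expansion of an undirected graph plus the dense aggregation
# matrices the layer forwards need.
.tower_bundle <- function(node_features, edges, edge_features, distances) {
  n <- nrow(node_features)
  if (nrow(edges) > 0L) {
    src <- c(edges[, 1L], edges[, 2L])
    dst <- c(edges[, 2L], edges[, 1L])
    E <- rbind(edge_features, edge_features)
    d2 <- matrix(c(distances, distances)^2, ncol = 1L)
  } else {
    src <- integer(0)
    dst <- integer(0)
    E <- matrix(0, 0L, ncol(edge_features))
    d2 <- matrix(0, 0L, 1L)
  }
  m <- length(src)
  deg <- tabulate(dst, nbins = n)
  S_sum <- matrix(0, n, m)
  S_gcn <- matrix(0, n, m)
  if (m > 0L) {
    S_sum[cbind(dst, seq_len(m))] <- 1
    S_gcn[cbind(dst, seq_len(m))] <- 1 / sqrt((1 + deg[dst]) * (1 + deg[src]))
  }
  list(X = node_features, n = n, m = m, src = src, dst = dst, E = E, d2 = d2,
       deg = deg, S_sum = S_sum, S_gcn = S_gcn)
}

# Precompute everything the forward pass needs for one complex.
.complex_bundle <- function(graphs) {
  ig <- graphs$interaction
  if (nrow(ig$edges) == 0L) {
    stop(structure(class = c("affpret_no_contact", "error", "condition"),
                   list(message = "complex has no protein-ligand contacts within the interaction cutoff",
                        call = NULL)))
  }
  list(
    lig = .tower_bundle(graphs$ligand$node_features, graphs$ligand$edges,
                        graphs$ligand$edge_features, graphs$ligand$distances),
    prot = .tower_bundle(graphs$protein$node_features, graphs$protein$edges,
                         graphs$protein$edge_features, graphs$protein$distances),
    inter = list(src = graphs$interaction$edges[, 1L],
                 dst = graphs$interaction$edges[, 2L],
                 E = graphs$interaction$edge_features,
                 m = nrow(graphs$interaction$edges)),
    edges = graphs$interaction$edges
  )
}

.param_getter <- function(tp, params) {
  cache <- new.env(parent = emptyenv())
  function(name) {
    id <- cache[[name]]
    if (!is.null(id)) return(id)
    val <- params[[name]]
    .assert(!is.null(val), paste0("unknown parameter: ", name))
    id <- tp_param(tp, name, val)
    assign(name, id, envir = cache)
    id
  }
}

# ---- parameter initialisation ----------------------------------------------

.layer_params <- function(variant, d, fe) {
  p <- list()
  if (variant == "gcn") {
    p$W <- .glorot(d, d); p$We <- .glorot(fe, d)
    p$Wself <- .glorot(d, d); p$b <- matrix(0, 1L, d)
  } else if (variant == "gin") {
    p$We <- .glorot(fe, d)
    p$W1 <- .glorot(d, d); p$b1 <- matrix(0, 1L, d)
    p$W2 <- .glorot(d, d); p$b2 <- matrix(0, 1L, d)
  } else if (variant == "gat") {
    p$W <- .glorot(d, d); p$We <- .glorot(fe, d)
    p$a <- .glorot(3L * d, 1L)
    p$Wself <- .glorot(d, d); p$b <- matrix(0, 1L, d)
  } else if (variant == "egnn") {
    p$W1 <- .glorot(2L * d + 1L + fe, d); p$b1 <- matrix(0, 1L, d)
    p$W2 <- .glorot(d, d); p$b2 <- matrix(0, 1L, d)
    p$U1 <- .glorot(2L * d, d); p$c1 <- matrix(0, 1L, d)
    p$U2 <- .glorot(d, d); p$c2 <- matrix(0, 1L, d)
  } else if (variant == "attentivefp") {
    p$We <- .glorot(fe, d)
    p$a <- .glorot(3L * d, 1L)
    p$Wc <- .glorot(d, d)
    p$Wr <- .glorot(d, d); p$Ur <- .glorot(d, d); p$br <- matrix(0, 1L, d)
    p$Wu <- .glorot(d, d); p$Uu <- .glorot(d, d); p$bu <- matrix(0, 1L, d)
    p$Wn <- .glorot(d, d); p$Un <- .glorot(d, d); p$bn <- matrix(0, 1L, d)
  }
  p
}

.tower_param_list <- function(prefix, cfg, fin, fe) {
  d <- cfg$hidden_dim
  out <- list()
  out[[paste0(prefix, ".embed.W")]] <- .glorot(fin, d)
  out[[paste0(prefix, ".embed.b")]] <- matrix(0, 1L, d)
  for (l in seq_len(cfg$n_layers)) {
    lp <- .layer_params(cfg$variant, d, fe)
    for (nm in names(lp)) out[[paste0(prefix, ".l", l, ".", nm)]] <- lp[[nm]]
  }
  out
}

# ---- layer forward ----------------------------------------------------------

.broadcast_cols <- function(tp, col, d) {
  # m x 1 -> m x d by multiplying with a constant row of ones
  tp_mm(tp, col, tp_const(tp, matrix(1, 1L, d)))
}

.gnn_layer <- function(tp, pget, prefix, variant, H, gb, d) {
  P <- function(nm) pget(paste0(prefix, ".", nm))
  no_edges <- gb$m == 0L
  zeros_agg <- function() tp_const(tp, matrix(0, gb$n, d))
  if (variant == "gcn") {
    agg <- if (no_edges) zeros_agg() else {
      msg <- tp_add(tp, tp_mm(tp, tp_gather(tp, H, gb$src), P("W")),
                    tp_mm(tp, tp_const(tp, gb$E), P("We")))
      tp_agg(tp, gb$S_gcn, msg)
    }
    selfc <- matrix(rep(1 / (1 + gb$deg), d), gb$n, d)
    self <- tp_mul(tp, tp_mm(tp, H, P("Wself")), tp_const(tp, selfc))
    tp_leaky_relu(tp, tp_add_bias(tp, tp_add(tp, agg, self), P("b")))
  } else if (variant == "gin") {
    agg <- if (no_edges) zeros_agg() else {
      msg <- tp_add(tp, tp_gather(tp, H, gb$src),
                    tp_mm(tp, tp_const(tp, gb$E), P("We")))
      tp_agg(tp, gb$S_sum, msg)
    }
    pre <- tp_add(tp, H, agg) # GIN-0: epsilon fixed at zero
    h1 <- tp_leaky_relu(tp, tp_add_bias(tp, tp_mm(tp, pre, P("W1")), P("b1")))
    tp_add_bias(tp, tp_mm(tp, h1, P("W2")), P("b2"))
  } else if (variant == "gat") {
    Wh <- tp_mm(tp, H, P("W"))
    agg <- if (no_edges) zeros_agg() else {
      Ew <- tp_mm(tp, tp_const(tp, gb$E), P("We"))
      z <- tp_concat(tp, c(tp_gather(tp, Wh, gb$dst),
                           tp_gather(tp, Wh, gb$src), Ew))
      s <- tp_leaky_relu(tp, tp_mm(tp, z, P("a")), alpha = 0.2)
      ex <- tp_exp(tp, tp_scale(tp, s, 1)) # scores are bounded at this scale
      denom <- tp_gather(tp, tp_agg(tp, gb$S_sum, ex), gb$dst)
      alpha <- tp_div(tp, ex, denom)
      tp_agg(tp, gb$S_sum,
             tp_mul(tp, .broadcast_cols(tp, alpha, d), tp_gather(tp, Wh, gb$src)))
    }
    self <- tp_mm(tp, H, P("Wself"))
    tp_leaky_relu(tp, tp_add_bias(tp, tp_add(tp, agg, self), P("b")))
  } else if (variant == "egnn") {
    agg <- if (no_edges) zeros_agg() else {
      z <- tp_concat(tp, c(tp_gather(tp, H, gb$dst), tp_gather(tp, H, gb$src),
                           tp_const(tp, gb$d2 / 100), tp_const(tp, gb$E)))
      m1 <- tp_leaky_relu(tp, tp_add_bias(tp, tp_mm(tp, z, P("W1")), P("b1")))
      msg <- tp_add_bias(tp, tp_mm(tp, m1, P("W2")), P("b2"))
      tp_agg(tp, gb$S_sum, msg)
    }
    u <- tp_concat(tp, c(H, agg))
    u1 <- tp_leaky_relu(tp, tp_add_bias(tp, tp_mm(tp, u, P("U1")), P("c1")))
    tp_add(tp, H, tp_add_bias(tp, tp_mm(tp, u1, P("U2")), P("c2")))
  } else { # attentivefp
    ctx <- if (no_edges) zeros_agg() else {
      Ew <- tp_mm(tp, tp_const(tp, gb$E), P("We"))
      z <- tp_concat(tp, c(tp_gather(tp, H, gb$dst),
                           tp_gather(tp, H, gb$src), Ew))
      s <- tp_leaky_relu(tp, tp_mm(tp, z, P("a")), alpha = 0.2)
      ex <- tp_exp(tp, s)
      denom <- tp_gather(tp, tp_agg(tp, gb$S_sum, ex), gb$dst)
      alpha <- tp_div(tp, ex, denom)
      val <- tp_leaky_relu(tp, tp_mm(tp, tp_gather(tp, H, gb$src), P("Wc")))
      tp_agg(tp, gb$S_sum, tp_mul(tp, .broadcast_cols(tp, alpha, d), val))
    }
    r <- tp_sigmoid(tp, tp_add_bias(tp, tp_add(tp, tp_mm(tp, ctx, P("Wr")),
                                               tp_mm(tp, H, P("Ur"))), P("br")))
    u <- tp_sigmoid(tp, tp_add_bias(tp, tp_add(tp, tp_mm(tp, ctx, P("Wu")),
                                               tp_mm(tp, H, P("Uu"))), P("bu")))
    nn <- tp_tanh(tp, tp_add_bias(tp, tp_add(tp, tp_mm(tp, ctx, P("Wn")),
                                             tp_mm(tp, tp_mul(tp, r, H), P("Un"))),
                                  P("bn")))
    ones <- tp_const(tp, matrix(1, gb$n, d))
    tp_add(tp, tp_mul(tp, tp_sub(tp, ones, u), H), tp_mul(tp, u, nn))
  }
}

# Encode one tower; returns list(final = node id of JK sum, layers = ids)
.encode_tower <- function(tp, pget, prefix, cfg, gb, training = FALSE) {
  d <- cfg$hidden_dim
  X <- tp_const(tp, gb$X)
  H <- tp_add_bias(tp, tp_mm(tp, X, pget(paste0(prefix, ".embed.W"))),
                   pget(paste0(prefix, ".embed.b")))
  layers <- integer(cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    H <- .gnn_layer(tp, pget, paste0(prefix, ".l", l), cfg$variant, H, gb, d)
    H <- tp_dropout(tp, H, cfg$dropout, training)
    layers[l] <- H
  }
  final <- layers[1L]
  if (cfg$n_layers > 1L) {
    for (l in 2:cfg$n_layers) final <- tp_add(tp, final, layers[l])
  }
  list(final = final, layers = layers)
}

# Fusion + read-out; returns list(o = id of 1 x 2dI embedding,
# hI = id of m x dI interaction embeddings, att = id of m x 1 tanh scores)
.fuse_readout <- function(tp, pget, HP, HL, inter, training = FALSE,
                          dropout = 0) {
  fc <- tp_leaky_relu(tp, tp_add_bias(tp, tp_mm(tp, tp_const(tp, inter$E),
                                                pget("fus.fc.W")),
                                      pget("fus.fc.b")))
  z <- tp_concat(tp, c(tp_gather(tp, HP, inter$src),
                       tp_gather(tp, HL, inter$dst), fc))
  h1 <- tp_leaky_relu(tp, tp_add_bias(tp, tp_mm(tp, z, pget("fus.W1")),
                                      pget("fus.b1")))
  h1 <- tp_dropout(tp, h1, dropout, training)
  hI <- tp_add_bias(tp, tp_mm(tp, h1, pget("fus.W2")), pget("fus.b2"))
  att <- tp_tanh(tp, tp_mm(tp, hI, pget("att.w")))
  o_sum <- tp_mm(tp, tp_transpose(tp, att), hI)
  o_max <- tp_colmax(tp, hI)
  list(o = tp_concat(tp, c(o_sum, o_max)), hI = hI, att = att)
}

.forward_complex <- function(tp, pget, bundle, cfg, training = FALSE) {
  HP <- .encode_tower(tp, pget, "prot", cfg$encoder, bundle$prot, training)$final
  HL <- .encode_tower(tp, pget, "lig", cfg$encoder, bundle$lig, training)$final
  .fuse_readout(tp, pget, HP, HL, bundle$inter, training, cfg$encoder$dropout)
}
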