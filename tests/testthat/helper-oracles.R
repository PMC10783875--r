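# Independent oracles and fixture builders shared across test files.

# Brute-force all-pairs edge oracle: plain double loop, no vectorization,
# kept deliberately independent of the package's distance-matrix path.
brute_force_edges <- function(coords, cutoff) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), 0L, 2L) else out
}

brute_force_bipartite <- function(ca, atoms, cutoff) {
  out <- NULL
  for (i in seq_len(nrow(ca))) {
    for (j in seq_len(nrow(atoms))) {
      if (sqrt(sum((ca[i, ] - atoms[j, ])^2)) < cutoff) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0L, 2L) else out
}

# Minimal record builders from raw coordinate matrices.
make_atoms <- function(coords, element = "C") {
  df <- data.frame(index = seq_len(nrow(coords)),
                   element = rep_len(element, nrow(coords)),
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   degree = 0L, formal_charge = 0, aromatic = FALSE,
                   in_ring = FALSE, hybridization = "sp3",
                   stringsAsFactors = FALSE)
  attr(df, "bonds") <- data.frame(i = integer(0), j = integer(0),
                                  order = character(0))
  class(df) <- c("atom_records", "data.frame")
  df
}

make_residues <- function(coords, name = "ALA") {
  df <- data.frame(index = seq_len(nrow(coords)),
                   residue_name = rep_len(name, nrow(coords)),
                   chain = "A", resno = seq_len(nrow(coords)),
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   stringsAsFactors = FALSE)
  class(df) <- c("residue_records", "data.frame")
  df
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3)))
}

leaky <- function(x, alpha = 0.01) ifelse(x > 0, x, alpha * x)

# One message-passing layer re-evaluated with explicit per-node loops,
# independently of the tape/aggregation-matrix implementation. `H` is the
# embedded input (n x d), `edges` the undirected (i < j) edge matrix, `E`
# the per-undirected-edge feature matrix, `p` the layer's parameter list.
oracle_layer <- function(variant, H, edges, E, p, d) {
  n <- nrow(H)
  src <- c(edges[, 1], edges[, 2])
  dst <- c(edges[, 2], edges[, 1])
  EE <- rbind(E, E)
  deg <- tabulate(dst, nbins = n)
  out <- matrix(0, n, d)
  if (variant == "gcn") {
    for (i in seq_len(n)) {
      agg <- numeric(d)
      for (e in seq_along(src)) {
        if (dst[e] == i) {
          msg <- H[src[e], ] %*% p$W + EE[e, ] %*% p$We
          agg <- agg + as.numeric(msg) / sqrt((1 + deg[i]) * (1 + deg[src[e]]))
        }
      }
      self <- as.numeric(H[i, ] %*% p$Wself) / (1 + deg[i])
      out[i, ] <- leaky(agg + self + as.numeric(p$b))
    }
  } else if (variant == "gin") {
    for (i in seq_len(n)) {
      agg <- numeric(d)
      for (e in seq_along(src)) {
        if (dst[e] == i) agg <- agg + H[src[e], ] + as.numeric(EE[e, ] %*% p$We)
      }
      pre <- H[i, ] + agg
      h1 <- leaky(as.numeric(pre %*% p$W1) + as.numeric(p$b1))
      out[i, ] <- as.numeric(h1 %*% p$W2) + as.numeric(p$b2)
    }
  } else if (variant == "gat") {
    Wh <- H %*% p$W
    for (i in seq_len(n)) {
      ein <- which(dst == i)
      agg <- numeric(d)
      if (length(ein) > 0) {
        s <- vapply(ein, function(e) {
          z <- c(Wh[i, ], Wh[src[e], ], as.numeric(EE[e, ] %*% p$We))
          leaky(sum(z * as.numeric(p$a)), 0.2)
        }, numeric(1))
        alpha <- exp(s) / sum(exp(s))
        for (k in seq_along(ein)) agg <- agg + alpha[k] * Wh[src[ein[k]], ]
      }
      out[i, ] <- leaky(agg + as.numeric(H[i, ] %*% p$Wself) + as.numeric(p$b))
    }
  }
  out
}

oracle_layer_egnn <- function(H, edges, E, dist, p, d) {
  n <- nrow(H)
  src <- c(edges[, 1], edges[, 2])
  dst <- c(edges[, 2], edges[, 1])
  EE <- rbind(E, E)
  d2 <- c(dist, dist)^2 / 100
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    agg <- numeric(d)
    for (e in seq_along(src)) {
      if (dst[e] == i) {
        z <- c(H[i, ], H[src[e], ], d2[e], EE[e, ])
        m1 <- leaky(as.numeric(z %*% p$W1) + as.numeric(p$b1))
        agg <- agg + as.numeric(m1 %*% p$W2) + as.numeric(p$b2)
      }
    }
    u <- c(H[i, ], agg)
    u1 <- leaky(as.numeric(u %*% p$U1) + as.numeric(p$c1))
    out[i, ] <- H[i, ] + as.numeric(u1 %*% p$U2) + as.numeric(p$c2)
  }
  out
}

oracle_layer_attentivefp <- function(H, edges, E, p, d) {
  n <- nrow(H)
  src <- c(edges[, 1], edges[, 2])
  dst <- c(edges[, 2], edges[, 1])
  EE <- rbind(E, E)
  out <- matrix(0, n, d)
  sig <- function(x) 1 / (1 + exp(-x))
  for (i in seq_len(n)) {
    ein <- which(dst == i)
    ctx <- numeric(d)
    if (length(ein) > 0) {
      s <- vapply(ein, function(e) {
        z <- c(H[i, ], H[src[e], ], as.numeric(EE[e, ] %*% p$We))
        leaky(sum(z * as.numeric(p$a)), 0.2)
      }, numeric(1))
      alpha <- exp(s) / sum(exp(s))
      for (k in seq_along(ein)) {
        ctx <- ctx + alpha[k] * leaky(as.numeric(H[src[ein[k]], ] %*% p$Wc))
      }
    }
    r <- sig(as.numeric(ctx %*% p$Wr) + as.numeric(H[i, ] %*% p$Ur) + as.numeric(p$br))
    u <- sig(as.numeric(ctx %*% p$Wu) + as.numeric(H[i, ] %*% p$Uu) + as.numeric(p$bu))
    nn <- tanh(as.numeric(ctx %*% p$Wn) + as.numeric((r * H[i, ]) %*% p$Un) + as.numeric(p$bn))
    out[i, ] <- (1 - u) * H[i, ] + u * nn
  }
  out
}

# Extract a layer's parameter sub-list from a model.
layer_params_of <- function(model, prefix) {
  nms <- grep(paste0("^", prefix, "\\."), names(model$params), value = TRUE)
  p <- model$params[nms]
  names(p) <- sub(paste0("^", prefix, "\\."), "", nms)
  p
}

# Direct evaluation of the interaction fusion for one edge set.
oracle_fusion <- function(model, HP, HL, ig) {
  p <- model$params
  out <- NULL
  for (k in seq_len(nrow(ig$edges))) {
    i <- ig$edges[k, 1]
    j <- ig$edges[k, 2]
    fc <- leaky(as.numeric(ig$edge_features[k, ] %*% p[["fus.fc.W"]]) +
                  as.numeric(p[["fus.fc.b"]]))
    z <- c(HP[i, ], HL[j, ], fc)
    h1 <- leaky(as.numeric(z %*% p[["fus.W1"]]) + as.numeric(p[["fus.b1"]]))
    out <- rbind(out, as.numeric(h1 %*% p[["fus.W2"]]) + as.numeric(p[["fus.b2"]]))
  }
  out
}

# Direct evaluation of the attention read-out.
oracle_readout <- function(hI, w) {
  o_sum <- numeric(ncol(hI))
  for (k in seq_len(nrow(hI))) {
    o_sum <- o_sum + tanh(sum(w * hI[k, ])) * hI[k, ]
  }
  o_max <- apply(hI, 2, max)
  c(o_sum, o_max)
}

# A small random complex for encoder tests.
tiny_complex <- function(seed = 1, n_res = 5, n_at = 4) {
  set.seed(seed)
  res <- make_residues(matrix(runif(n_res * 3, 0, 10), n_res),
                       name = sample(c("ALA", "GLY", "LYS", "ASP", "TRP"),
                                     n_res, replace = TRUE))
  at <- make_atoms(matrix(runif(n_at * 3, 2, 8), n_at),
                   element = sample(c("C", "N", "O"), n_at, replace = TRUE))
  complex_structure(res, at, "Ptest", "Ltest")
}
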