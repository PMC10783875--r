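# The multi-task model: shared encoder, four task heads (IC50/K x
# regression/ranking), and the loss calculus
# L_total = L_rank + lambda * L_reg.

.ALL_TASKS <- c("ic50_reg", "ic50_rank", "k_reg", "k_rank")

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Construct a multi-task affinity model
#'
#' Builds the shared-bottom encoder (separate ligand and protein towers of
#' the configured GNN variant, interaction fusion and attention read-out)
#' plus four task heads: IC50 and K regression heads mapping the complex
#' embedding to a pAff scalar, and IC50 and K ranking heads mapping the
#' concatenated embeddings of a pair to a logit.
#'
#' @param encoder a [gnn_config()].
#' @param d_interaction width of interaction-edge embeddings (default: the
#'   encoder hidden width).
#' @param head_hidden hidden width of the task-head MLPs (default
#'   `d_interaction`).
#' @param lambda weight of the regression loss in the total pre-training
#'   loss, >= 0.
#' @param enabled_tasks subset of `c("ic50_reg", "ic50_rank", "k_reg",
#'   "k_rank")`; disabled tasks contribute nothing to the loss (the task
#'   ablation grid).
#' @param cutoffs graph distance cutoffs in Angstrom.
#' @param full_protein encode the full chain instead of the 12-Angstrom
#'   binding pocket.
#' @param schema a [feature_schema()].
#' @param seed integer seed for parameter initialization.
#' @return an object of class `mbp_model`.
#' @export
mbp_model <- function(encoder = gnn_config(), d_interaction = NULL,
                      head_hidden = NULL, lambda = 0.1,
                      enabled_tasks = .ALL_TASKS,
                      cutoffs = list(ligand = 5.0, protein = 8.0, interaction = 12.0),
                      full_protein = FALSE, schema = feature_schema(),
                      seed = 1L) {
  .assert(inherits(encoder, "gnn_config"), "encoder must be a gnn_config")
  .assert(is.numeric(lambda) && lambda >= 0, "lambda must be >= 0")
  .assert(all(enabled_tasks %in% .ALL_TASKS) && length(enabled_tasks) >= 1L,
          "enabled_tasks must be a non-empty subset of the four tasks")
  d <- encoder$hidden_dim
  dI <- as.integer(d_interaction %||% d)
  hh <- as.integer(head_hidden %||% dI)
  dI2 <- max(1L, dI %/% 2L)
  cfg <- list(encoder = encoder, d_interaction = dI, d_fc = dI2,
              head_hidden = hh, lambda = lambda,
              enabled_tasks = enabled_tasks, cutoffs = cutoffs,
              full_protein = isTRUE(full_protein), schema = schema)
  params <- .with_seed(seed, {
    p <- c(
      .tower_param_list("lig", encoder, schema$atom_dim, schema$ligand_edge_dim),
      .tower_param_list("prot", encoder, schema$residue_dim, schema$protein_edge_dim)
    )
    p[["fus.fc.W"]] <- .glorot(schema$interaction_edge_dim, dI2)
    p[["fus.fc.b"]] <- matrix(0, 1L, dI2)
    p[["fus.W1"]] <- .glorot(2L * d + dI2, dI)
    p[["fus.b1"]] <- matrix(0, 1L, dI)
    p[["fus.W2"]] <- .glorot(dI, dI)
    p[["fus.b2"]] <- matrix(0, 1L, dI)
    p[["att.w"]] <- .glorot(dI, 1L)
    for (tt in c("IC50", "K")) {
      p[[paste0("head.reg.", tt, ".W1")]] <- .glorot(2L * dI, hh)
      p[[paste0("head.reg.", tt, ".b1")]] <- matrix(0, 1L, hh)
      p[[paste0("head.reg.", tt, ".W2")]] <- .glorot(hh, 1L)
      p[[paste0("head.reg.", tt, ".b2")]] <- matrix(0, 1L, 1L)
      p[[paste0("head.rank.", tt, ".W1")]] <- .glorot(4L * dI, hh)
      p[[paste0("head.rank.", tt, ".b1")]] <- matrix(0, 1L, hh)
      p[[paste0("head.rank.", tt, ".W2")]] <- .glorot(hh, 1L)
      p[[paste0("head.rank.", tt, ".b2")]] <- matrix(0, 1L, 1L)
    }
    p
  })
  structure(list(config = cfg, params = params, epoch = 0L,
                 config_hash = .obj_hash(cfg)),
            class = "mbp_model")
}

#' @export
print.mbp_model <- function(x, ...) {
  e <- x$config$encoder
  cat("Multi-task bioassay pre-training model\n")
  cat("  encoder: ", toupper(e$variant), ", ", e$n_layers, " layers, d = ",
      e$hidden_dim, ", dropout ", e$dropout, "\n", sep = "")
  cat("  interaction dim:", x$config$d_interaction,
      "| complex embedding:", 2L * x$config$d_interaction, "\n")
  cat("  tasks enabled:", paste(x$config$enabled_tasks, collapse = ", "), "\n")
  cat("  lambda (regression weight):", x$config$lambda, "\n")
  cat("  parameters:", sum(vapply(x$params, length, integer(1))),
      "| trained epochs:", x$epoch, "\n")
  invisible(x)
}

#' @export
summary.mbp_model <- function(object, ...) {
  print(object)
  cat("  cutoffs (A): ligand", object$config$cutoffs$ligand,
      "| protein", object$config$cutoffs$protein,
      "| interaction", object$config$cutoffs$interaction, "\n")
  invisible(object)
}

#' @export
coef.mbp_model <- function(object, ...) object$params

# ---- public encoder surface -------------------------------------------------

#' Encode a single graph into node embeddings
#'
#' Runs the configured message-passing tower over one graph and returns the
#' jumping-knowledge node embeddings (the sum of every layer's output)
#' together with the per-layer matrices.
#'
#' @param model an [mbp_model()].
#' @param graph a `ligand_graph` or `protein_graph`.
#' @return a `node_embeddings` object: `embeddings` (n x d matrix) and
#'   `layers` (list of per-layer n x d matrices).
#' @export
encode_graph <- function(model, graph) {
  .assert(inherits(model, "mbp_model"), "model must be an mbp_model")
  prefix <- if (inherits(graph, "ligand_graph")) "lig"
  else if (inherits(graph, "protein_graph")) "prot"
  else stop("graph must be a ligand_graph or protein_graph", call. = FALSE)
  fin <- ncol(graph$node_features)
  expect <- nrow(model$params[[paste0(prefix, ".embed.W")]])
  .assert(fin == expect,
          paste0("node feature width ", fin, " does not match the model's ",
                 "configured input dimension ", expect))
  gb <- .tower_bundle(graph$node_features, graph$edges, graph$edge_features,
                      graph$distances)
  tp <- tape_new()
  pget <- .param_getter(tp, model$params)
  enc <- .encode_tower(tp, pget, prefix, model$config$encoder, gb, training = FALSE)
  structure(list(
    embeddings = tp_value(tp, enc$final),
    layers = lapply(enc$layers, function(id) tp_value(tp, id))
  ), class = "node_embeddings")
}

#' Fuse tower embeddings along interaction edges
#'
#' For each residue-atom interaction edge (i, j), concatenates the residue
#' embedding, the atom embedding and a fully connected transform of the edge
#' features, and passes the result through the fusion MLP.
#'
#' @param model an [mbp_model()].
#' @param h_protein,h_ligand node embedding matrices (or `node_embeddings`).
#' @param ig an `interaction_graph`.
#' @return matrix of interaction embeddings, one row per edge of `ig`.
#' @export
fuse_interactions <- function(model, h_protein, h_ligand, ig) {
  if (inherits(h_protein, "node_embeddings")) h_protein <- h_protein$embeddings
  if (inherits(h_ligand, "node_embeddings")) h_ligand <- h_ligand$embeddings
  .assert(inherits(ig, "interaction_graph"), "ig must be an interaction_graph")
  if (nrow(ig$edges) == 0L) {
    stop(structure(class = c("affpret_no_contact", "error", "condition"),
                   list(message = "no interaction edges to fuse", call = NULL)))
  }
  .assert(max(ig$edges[, 1L]) <= nrow(h_protein) &&
            max(ig$edges[, 2L]) <= nrow(h_ligand),
          "interaction edge indices exceed embedding matrices")
  tp <- tape_new()
  pget <- .param_getter(tp, model$params)
  inter <- list(src = ig$edges[, 1L], dst = ig$edges[, 2L],
                E = ig$edge_features, m = nrow(ig$edges))
  fr <- .fuse_readout(tp, pget, tp_const(tp, h_protein), tp_const(tp, h_ligand),
                      inter)
  tp_value(tp, fr$hI)
}

#' Attention read-out of interaction embeddings
#'
#' Computes the tanh-attention weighted sum o_sum over interaction-edge
#' embeddings and the element-wise maximum o_max, and concatenates them into
#' the complex embedding o. Per-edge attention scores (in (-1, 1)) are kept
#' for interpretation.
#'
#' @param model an [mbp_model()].
#' @param interaction_embeddings matrix with one row per interaction edge.
#' @return a `complex_embedding`: fields `o`, `o_sum`, `o_max`, `attention`.
#' @export
readout <- function(model, interaction_embeddings) {
  .assert(is.matrix(interaction_embeddings) && nrow(interaction_embeddings) >= 1L,
          "need at least one interaction embedding")
  hI <- interaction_embeddings
  w <- model$params[["att.w"]]
  att <- tanh(hI %*% w)
  o_sum <- as.vector(crossprod(hI, att)) # sum_e tanh(w'h_e) h_e
  o_max <- apply(hI, 2L, max)
  structure(list(o = c(o_sum, o_max), o_sum = o_sum, o_max = o_max,
                 attention = as.vector(att)),
            class = "complex_embedding")
}

#' Encode a protein-ligand complex end to end
#'
#' Builds the three graphs, runs both encoder towers, fuses along the
#' interaction edges and reads out the complex embedding. Deterministic in
#' evaluation mode (no dropout).
#'
#' @param model an [mbp_model()].
#' @param cs a [complex_structure()], or a precomputed list of graphs from
#'   [complex_graphs()].
#' @return a `complex_embedding` with fields `o` (length 2 * d_interaction),
#'   `o_sum`, `o_max`, `attention` (per interaction edge) and `edges` (the
#'   residue-atom pairs the attention refers to).
#' @export
encode_complex <- function(model, cs) {
  graphs <- if (inherits(cs, "complex_structure")) {
    complex_graphs(cs, model$config$cutoffs, model$config$full_protein,
                   model$config$schema)
  } else cs
  bundle <- .complex_bundle(graphs)
  tp <- tape_new()
  pget <- .param_getter(tp, model$params)
  fr <- .forward_complex(tp, pget, bundle, model$config, training = FALSE)
  o <- as.vector(tp_value(tp, fr$o))
  hI <- tp_value(tp, fr$hI)
  structure(list(o = o,
                 o_sum = o[seq_len(model$config$d_interaction)],
                 o_max = o[model$config$d_interaction + seq_len(model$config$d_interaction)],
                 attention = as.vector(tp_value(tp, fr$att)),
                 edges = bundle$edges),
            class = "complex_embedding")
}

#' @export
print.complex_embedding <- function(x, ...) {
  cat("complex_embedding: length", length(x$o), "over",
      length(x$attention), "interaction edges\n")
  invisible(x)
}

# ---- task heads -------------------------------------------------------------

.head_forward <- function(tp, pget, prefix, o, training = FALSE, dropout = 0) {
  h1 <- tp_leaky_relu(tp, tp_add_bias(tp, tp_mm(tp, o, pget(paste0(prefix, ".W1"))),
                                      pget(paste0(prefix, ".b1"))))
  h1 <- tp_dropout(tp, h1, dropout, training)
  tp_add_bias(tp, tp_mm(tp, h1, pget(paste0(prefix, ".W2"))),
              pget(paste0(prefix, ".b2")))
}

.task_key <- function(task_type) {
  .assert(task_type %in% c("IC50", "K"),
          paste0("unknown task type: ", task_type))
  task_type
}

.emb_vector <- function(o) {
  if (inherits(o, "complex_embedding")) o <- o$o
  .assert(is.numeric(o), "embedding must be numeric")
  matrix(o, nrow = 1L)
}

#' Predict binding affinity from a complex embedding
#'
#' Routes the embedding through the regression head matching `task_type`
#' (routing is by label type, never by data provenance).
#'
#' @param model an [mbp_model()].
#' @param o a `complex_embedding` or numeric embedding vector.
#' @param task_type `"IC50"` or `"K"`.
#' @return predicted affinity on the pAff scale.
#' @export
predict_affinity <- function(model, o, task_type) {
  key <- .task_key(task_type)
  tp <- tape_new()
  pget <- .param_getter(tp, model$params)
  out <- .head_forward(tp, pget, paste0("head.reg.", key),
                       tp_const(tp, .emb_vector(o)))
  tp_value(tp, out)[1L, 1L]
}

#' Predict the pairwise ranking probability
#'
#' Applies the ranking head of `task_type` to the ordered concatenation
#' `o1 || o2` and returns the sigmoid of its logit: the predicted probability
#' that the first complex's affinity value exceeds the second's. The head is
#' not antisymmetric by construction; training covers both orders through
#' random pair ordering.
#'
#' @param model an [mbp_model()].
#' @param o1,o2 complex embeddings (objects or numeric vectors) of equal
#'   length.
#' @param task_type `"IC50"` or `"K"`.
#' @return probability in (0, 1).
#' @export
predict_rank <- function(model, o1, o2, task_type) {
  key <- .task_key(task_type)
  v1 <- .emb_vector(o1)
  v2 <- .emb_vector(o2)
  .assert(ncol(v1) == ncol(v2), "embedding dimensions differ")
  tp <- tape_new()
  pget <- .param_getter(tp, model$params)
  logit <- .head_forward(tp, pget, paste0("head.rank.", key),
                         tp_const(tp, cbind(v1, v2)))
  stats::plogis(tp_value(tp, logit)[1L, 1L])
}

# ---- losses -----------------------------------------------------------------

#' Regression loss (mean squared error on pAff)
#'
#' For a bioassay pair only the first sample's label enters the regression
#' loss; with vectors the element-wise squared errors are averaged.
#'
#' @param y_hat predicted pAff value(s).
#' @param y true pAff value(s).
#' @return non-negative scalar.
#' @export
regression_loss <- function(y_hat, y) {
  .assert(length(y_hat) == length(y), "length mismatch")
  mean((y_hat - y)^2)
}

#' Ranking loss (binary cross-entropy with logit)
#'
#' Numerically stable BCE between the ranking-head logit and the 0/1 label
#' `I[value_a > value_b]`.
#'
#' @param logit finite ranking-head logit(s).
#' @param label 0/1 label(s).
#' @return non-negative scalar (mean over elements).
#' @export
ranking_loss <- function(logit, label) {
  .assert(all(is.finite(logit)), "logit must be finite")
  .assert(all(label %in% c(0, 1)), "label must be 0 or 1")
  mean(pmax(logit, 0) - logit * label + log1p(exp(-abs(logit))))
}

#' Total multi-task loss
#'
#' @param l_rank ranking loss.
#' @param l_reg regression loss.
#' @param lambda regression weight, >= 0 (`lambda = 0` is the ranking-only
#'   ablation).
#' @return `l_rank + lambda * l_reg`.
#' @export
mbp_loss <- function(l_rank, l_reg, lambda) {
  .assert(is.numeric(lambda) && length(lambda) == 1L && lambda >= 0,
          "lambda must be a non-negative scalar")
  l_rank + lambda * l_reg
}
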