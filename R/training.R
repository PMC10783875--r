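# Optimization: Adam with L2 regularization, the plateau learning-rate
# schedule, bioassay-pair pre-training and downstream fine-tuning.

#' Training configuration
#'
#' Defaults follow the framework's optimization protocol: Adam with initial
#' learning rate 1e-3 and L2 factor 1e-6; the learning rate is scaled by 0.6
#' whenever the training loss has not reached a new minimum for 10
#' consecutive epochs; dropout 0.1; batch size 256 for pre-training and 128
#' for fine-tuning; at most 100 pre-training epochs, and 1000 fine-tuning
#' epochs with early stopping after 70 epochs without validation
#' improvement.
#'
#' @param phase `"pretrain"` or `"finetune"`.
#' @param lr initial learning rate.
#' @param l2 L2 regularization factor.
#' @param lr_decay plateau decay factor.
#' @param plateau_patience epochs without a new training-loss minimum before
#'   the learning rate is decayed.
#' @param lr_floor lower bound guarding degenerate schedules.
#' @param batch_size minibatch size in pairs (pretrain) or complexes
#'   (finetune).
#' @param epochs maximum training epochs.
#' @param early_stop_patience fine-tuning early-stopping patience (epochs).
#' @param pairs_per_epoch pre-training pairs per epoch; default is the total
#'   record count of the assay collection.
#' @param seed RNG seed for sampling, dropout and shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(phase = c("pretrain", "finetune"), lr = 1e-3,
                         l2 = 1e-6, lr_decay = 0.6, plateau_patience = 10L,
                         lr_floor = 1e-6,
                         batch_size = if (phase[1L] == "pretrain") 256L else 128L,
                         epochs = if (phase[1L] == "pretrain") 100L else 1000L,
                         early_stop_patience = 70L, pairs_per_epoch = NULL,
                         seed = 1L) {
  phase <- match.arg(phase)
  .assert(lr > 0 && l2 >= 0 && lr_decay > 0 && lr_decay <= 1, "invalid optimizer settings")
  .assert(plateau_patience >= 1L && batch_size >= 1L && epochs >= 0L,
          "invalid schedule settings")
  structure(list(phase = phase, lr = lr, l2 = l2, lr_decay = lr_decay,
                 plateau_patience = as.integer(plateau_patience),
                 lr_floor = lr_floor, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 pairs_per_epoch = pairs_per_epoch, seed = as.integer(seed)),
            class = "train_config")
}

#' Plateau learning-rate schedule
#'
#' Pure form of the schedule used during training: starting from `lr0`, the
#' rate is multiplied by `factor` each time `patience` consecutive epochs
#' pass without a new strict minimum of the epoch training loss; the
#' counter resets on any new minimum and after each decay.
#'
#' @param loss_history numeric vector of per-epoch training losses.
#' @param lr0 initial learning rate.
#' @param factor decay factor.
#' @param patience consecutive non-improving epochs required.
#' @param floor lower bound on the rate.
#' @return numeric vector: the learning rate in force after each epoch.
#' @export
plateau_lr <- function(loss_history, lr0 = 1e-3, factor = 0.6,
                       patience = 10L, floor = 1e-6) {
  st <- .plateau_new(lr0, factor, patience, floor)
  out <- numeric(length(loss_history))
  for (i in seq_along(loss_history)) {
    st <- .plateau_step(st, loss_history[i])
    out[i] <- st$lr
  }
  out
}

# Incremental plateau-schedule state shared by plateau_lr(), pretrain() and
# finetune(): decay on `patience` consecutive epochs without a new strict
# minimum; the counter resets on a new minimum and after each decay.
.plateau_new <- function(lr0, factor, patience, floor) {
  list(lr = lr0, factor = factor, patience = patience, floor = floor,
       best = Inf, counter = 0L)
}

.plateau_step <- function(st, loss) {
  if (loss < st$best) {
    st$best <- loss
    st$counter <- 0L
  } else {
    st$counter <- st$counter + 1L
    if (st$counter >= st$patience) {
      st$lr <- max(st$lr * st$factor, st$floor)
      st$counter <- 0L
    }
  }
  st
}

# ---- Adam -------------------------------------------------------------------

.adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, l2 = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (l2 > 0) g <- g + l2 * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- data preparation -------------------------------------------------------

# Accepts complex_structure / graph list / prepared bundle; returns bundle.
.as_bundle <- function(x, cfg) {
  if (is.list(x) && !is.null(x$inter)) return(x)
  if (inherits(x, "complex_structure")) {
    x <- complex_graphs(x, cfg$cutoffs, cfg$full_protein, cfg$schema)
  }
  .assert(is.list(x) && inherits(x$interaction, "interaction_graph"),
          "cannot interpret complex input")
  .complex_bundle(x)
}

#' Precompute encoder-ready bundles for a set of complexes
#'
#' Complexes with no protein-ligand contact within the interaction cutoff
#' are dropped with a message (their count is reported as an attribute).
#'
#' @param model an [mbp_model()].
#' @param complexes named list of [complex_structure()] objects (or graph
#'   lists from [complex_graphs()]).
#' @return named list of prepared bundles; `attr(, "n_skipped")` counts
#'   contact-free complexes that were excluded.
#' @export
prepare_complexes <- function(model, complexes) {
  .assert(!is.null(names(complexes)), "complexes must be a named list")
  out <- list()
  skipped <- 0L
  for (nm in names(complexes)) {
    b <- tryCatch(.as_bundle(complexes[[nm]], model$config),
                  affpret_no_contact = function(e) NULL)
    if (is.null(b)) {
      skipped <- skipped + 1L
    } else {
      out[[nm]] <- b
    }
  }
  if (skipped > 0L) {
    message(skipped, " complex(es) without protein-ligand contacts excluded")
  }
  attr(out, "n_skipped") <- skipped
  out
}

# Loss of one bioassay pair on an open tape. Returns NULL total when all
# relevant tasks are disabled.
.pair_loss_tp <- function(tp, pget, b1, b2, y1_paff, label, task_type, cfg,
                          training) {
  fr1 <- .forward_complex(tp, pget, b1, cfg, training)
  fr2 <- .forward_complex(tp, pget, b2, cfg, training)
  key <- .task_key(task_type)
  low <- tolower(key)
  dropout <- cfg$encoder$dropout
  rank_on <- paste0(low, "_rank") %in% cfg$enabled_tasks
  reg_on <- paste0(low, "_reg") %in% cfg$enabled_tasks
  l_rank <- NULL
  l_reg <- NULL
  if (rank_on) {
    logit <- .head_forward(tp, pget, paste0("head.rank.", key),
                           tp_concat(tp, c(fr1$o, fr2$o)), training, dropout)
    l_rank <- tp_sub(tp, tp_softplus(tp, logit), tp_scale(tp, logit, label))
  }
  if (reg_on) {
    yhat <- .head_forward(tp, pget, paste0("head.reg.", key), fr1$o,
                          training, dropout)
    l_reg <- tp_square(tp, tp_sub(tp, yhat, tp_const(tp, y1_paff)))
  }
  total <- NULL
  if (!is.null(l_rank)) total <- l_rank
  if (!is.null(l_reg)) {
    reg_term <- tp_scale(tp, l_reg, cfg$lambda)
    total <- if (is.null(total)) reg_term else tp_add(tp, total, reg_term)
  }
  list(total = total,
       l_rank = if (is.null(l_rank)) 0 else tp_value(tp, l_rank)[1L, 1L],
       l_reg = if (is.null(l_reg)) 0 else tp_value(tp, l_reg)[1L, 1L])
}

# ---- pre-training -----------------------------------------------------------

#' Pre-train on bioassay-specific data pairs
#'
#' Repeatedly samples an assay with probability proportional to its size and
#' an untied ligand pair within it, encodes both complexes with the shared
#' encoder and optimizes the enabled task heads under
#' `L = L_rank + lambda * L_reg` (the regression term uses only the pair's
#' first label). One epoch is `pairs_per_epoch` sampled pairs (default: the
#' total record count). The learning rate follows the plateau schedule.
#'
#' @param model an [mbp_model()].
#' @param assays list of `bioassay` objects ([group_into_assays()]).
#' @param complexes named list keyed by ligand id: complex structures,
#'   graph lists or prepared bundles covering every assay ligand.
#' @param config a [train_config()] with `phase = "pretrain"`.
#' @return an object of class `mbp_fit`: `model` (parameters after the last
#'   epoch), `best_model` (parameters at the best training loss), `history`
#'   (per-epoch total/rank/reg losses and learning rate).
#' @export
pretrain <- function(model, assays, complexes, config = train_config("pretrain")) {
  .assert(inherits(model, "mbp_model"), "model must be an mbp_model")
  .assert(config$phase == "pretrain", "config phase must be 'pretrain'")
  .assert(length(assays) >= 1L, "need at least one assay")
  set.seed(config$seed)
  bundles <- if (all(vapply(complexes, function(x) is.list(x) && !is.null(x$inter), logical(1)))) {
    complexes
  } else {
    prepare_complexes(model, complexes)
  }
  need <- unique(unlist(lapply(assays, `[[`, "ligand_id")))
  missing <- setdiff(need, names(bundles))
  .assert(length(missing) == 0L,
          paste0("no complex provided for ligand(s): ",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  n_pairs <- config$pairs_per_epoch %||% sum(vapply(assays, `[[`, numeric(1), "size"))
  params <- model$params
  opt <- .adam_new(params)
  sched <- .plateau_new(config$lr, config$lr_decay, config$plateau_patience,
                        config$lr_floor)
  best <- Inf
  best_params <- params
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     loss_rank = numeric(0), loss_reg = numeric(0),
                     lr = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    done <- 0L
    ep_tot <- 0
    ep_rank <- 0
    ep_reg <- 0
    while (done < n_pairs) {
      bs <- min(config$batch_size, n_pairs - done)
      tp <- tape_new()
      pget <- .param_getter(tp, params)
      batch_total <- NULL
      for (k in seq_len(bs)) {
        assay <- sample_assay(assays)
        pair <- sample_pair(assay)
        pl <- .pair_loss_tp(tp, pget,
                            bundles[[pair$ligand_a]], bundles[[pair$ligand_b]],
                            to_paffinity(pair$value_a),
                            ranking_label(pair), pair$task_type,
                            model$config, training = TRUE)
        ep_rank <- ep_rank + pl$l_rank
        ep_reg <- ep_reg + pl$l_reg
        if (!is.null(pl$total)) {
          batch_total <- if (is.null(batch_total)) pl$total else
            tp_add(tp, batch_total, pl$total)
        }
      }
      if (!is.null(batch_total)) {
        batch_mean <- tp_scale(tp, batch_total, 1 / bs)
        lv <- tp_value(tp, batch_mean)[1L, 1L]
        if (!is.finite(lv)) {
          stop("non-finite pre-training loss at epoch ", epoch,
               " (lr = ", sched$lr, "); aborting", call. = FALSE)
        }
        ep_tot <- ep_tot + lv * bs
        grads <- tape_backward(tp, batch_mean)
        upd <- .adam_step(params, grads, opt, sched$lr, config$l2)
        params <- upd$params
        opt <- upd$state
      }
      done <- done + bs
    }
    ep_tot <- ep_tot / n_pairs
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_tot,
                                   loss_rank = ep_rank / n_pairs,
                                   loss_reg = ep_reg / n_pairs, lr = sched$lr))
    if (ep_tot < best) {
      best <- ep_tot
      best_params <- params
    }
    sched <- .plateau_step(sched, ep_tot)
  }
  out_model <- model
  out_model$params <- params
  out_model$epoch <- model$epoch + config$epochs
  best_model <- model
  best_model$params <- best_params
  structure(list(model = out_model, best_model = best_model, history = hist,
                 phase = "pretrain"),
            class = "mbp_fit")
}

#' @export
print.mbp_fit <- function(x, ...) {
  cat("mbp_fit (", x$phase, "): ", nrow(x$history), " epochs\n", sep = "")
  if (nrow(x$history) > 0L) {
    last <- x$history[nrow(x$history), ]
    cat("  final loss:", signif(last$loss, 5),
        "| lr:", signif(last$lr, 3), "\n")
    if (!is.null(x$history$val_rmse)) {
      cat("  best validation RMSE:", signif(min(x$history$val_rmse), 5), "\n")
    }
  }
  invisible(x)
}

# ---- fine-tuning ------------------------------------------------------------

.finetune_batch_loss <- function(tp, pget, items, bundles, cfg) {
  total <- NULL
  for (it in items) {
    fr <- .forward_complex(tp, pget, bundles[[it$complex_id]], cfg, training = TRUE)
    yhat <- .head_forward(tp, pget, paste0("head.reg.", .task_key(it$task_type)),
                          fr$o, training = TRUE, dropout = cfg$encoder$dropout)
    sq <- tp_square(tp, tp_sub(tp, yhat, tp_const(tp, it$y_paff)))
    total <- if (is.null(total)) sq else tp_add(tp, total, sq)
  }
  tp_scale(tp, total, 1 / length(items))
}

#' Fine-tune on labelled complexes
#'
#' Transfers the shared encoder and the two regression heads (ranking heads
#' are not used downstream) and minimizes mean squared error on the pAff
#' labels, routing each sample to the regression head of its own label
#' type. Training stops early when the validation RMSE has not improved for
#' `early_stop_patience` epochs; the parameters of the best validation epoch
#' are restored.
#'
#' @param model an [mbp_model()] (typically `$best_model` of a pre-training
#'   [pretrain()] fit, or a freshly initialized model for from-scratch
#'   baselines).
#' @param train,val data frames with columns `complex_id`, `y_paff`,
#'   `task_type` ("IC50" or "K").
#' @param complexes named list keyed by `complex_id` (structures, graph
#'   lists or prepared bundles).
#' @param config a [train_config()] with `phase = "finetune"`.
#' @return an `mbp_fit` with the restored best `model` and a history of
#'   train loss and validation RMSE.
#' @export
finetune <- function(model, train, val, complexes,
                     config = train_config("finetune")) {
  .assert(inherits(model, "mbp_model"), "model must be an mbp_model")
  .assert(config$phase == "finetune", "config phase must be 'finetune'")
  .assert(all(c("complex_id", "y_paff", "task_type") %in% names(train)),
          "train must have complex_id, y_paff, task_type")
  set.seed(config$seed)
  bundles <- if (all(vapply(complexes, function(x) is.list(x) && !is.null(x$inter), logical(1)))) {
    complexes
  } else {
    prepare_complexes(model, complexes)
  }
  items <- lapply(seq_len(nrow(train)), function(i) {
    list(complex_id = train$complex_id[i], y_paff = train$y_paff[i],
         task_type = train$task_type[i])
  })
  params <- model$params
  opt <- .adam_new(params)
  sched <- .plateau_new(config$lr, config$lr_decay, config$plateau_patience,
                        config$lr_floor)
  best_val <- Inf
  best_params <- params
  since_improve <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_rmse = numeric(0), lr = numeric(0))
  eval_model <- model
  for (epoch in seq_len(config$epochs)) {
    idx <- sample(length(items))
    ep_loss <- 0
    for (start in seq(1L, length(items), by = config$batch_size)) {
      bidx <- idx[start:min(start + config$batch_size - 1L, length(items))]
      tp <- tape_new()
      pget <- .param_getter(tp, params)
      bl <- .finetune_batch_loss(tp, pget, items[bidx], bundles, model$config)
      lv <- tp_value(tp, bl)[1L, 1L]
      if (!is.finite(lv)) {
        stop("non-finite fine-tuning loss at epoch ", epoch, "; aborting",
             call. = FALSE)
      }
      ep_loss <- ep_loss + lv * length(bidx)
      grads <- tape_backward(tp, bl)
      upd <- .adam_step(params, grads, opt, sched$lr, config$l2)
      params <- upd$params
      opt <- upd$state
    }
    ep_loss <- ep_loss / length(items)
    eval_model$params <- params
    val_pred <- vapply(seq_len(nrow(val)), function(i) {
      .predict_bundle(eval_model, bundles[[val$complex_id[i]]], val$task_type[i])
    }, numeric(1))
    val_rmse <- sqrt(mean((val_pred - val$y_paff)^2))
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss,
                                   val_rmse = val_rmse, lr = sched$lr))
    sched <- .plateau_step(sched, ep_loss)
    if (val_rmse < best_val) {
      best_val <- val_rmse
      best_params <- params
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$early_stop_patience) break
    }
  }
  out_model <- model
  out_model$params <- best_params
  out_model$epoch <- model$epoch + nrow(hist)
  structure(list(model = out_model, best_model = out_model, history = hist,
                 phase = "finetune"),
            class = "mbp_fit")
}

# ---- prediction -------------------------------------------------------------

.predict_bundle <- function(model, bundle, task_type) {
  tp <- tape_new()
  pget <- .param_getter(tp, model$params)
  fr <- .forward_complex(tp, pget, bundle, model$config, training = FALSE)
  out <- .head_forward(tp, pget, paste0("head.reg.", .task_key(task_type)), fr$o)
  tp_value(tp, out)[1L, 1L]
}

#' Predict binding affinity for complexes
#'
#' Deterministic evaluation-mode prediction (dropout off) on the pAff scale.
#'
#' @param object an [mbp_model()].
#' @param newdata a [complex_structure()], a graph list, a prepared bundle,
#'   or a (named) list of any of these.
#' @param task_type `"IC50"` or `"K"` (recycled over complexes).
#' @param ... unused.
#' @return numeric vector of predicted pAff values.
#' @export
predict.mbp_model <- function(object, newdata, task_type = "K", ...) {
  single <- inherits(newdata, "complex_structure") ||
    (is.list(newdata) && (!is.null(newdata$inter) || inherits(newdata$interaction, "interaction_graph")))
  if (single) newdata <- list(newdata)
  task_type <- rep_len(task_type, length(newdata))
  out <- vapply(seq_along(newdata), function(i) {
    .predict_bundle(object, .as_bundle(newdata[[i]], object$config), task_type[i])
  }, numeric(1))
  names(out) <- names(newdata)
  out
}

#' Within-assay pair-ranking accuracy
#'
#' Samples untied ligand pairs from held-out assays and scores how often the
#' ranking head orders them correctly (`predict_rank > 0.5` matching the
#' label).
#'
#' @param model an [mbp_model()].
#' @param assays list of `bioassay` objects.
#' @param complexes named list keyed by ligand id (bundles or structures).
#' @param n_pairs number of evaluation pairs to sample.
#' @return accuracy in [0, 1], with attribute `n` giving the pair count.
#' @export
rank_accuracy <- function(model, assays, complexes, n_pairs = 200L) {
  bundles <- if (all(vapply(complexes, function(x) is.list(x) && !is.null(x$inter), logical(1)))) {
    complexes
  } else {
    prepare_complexes(model, complexes)
  }
  emb_cache <- new.env(parent = emptyenv())
  emb_of <- function(id) {
    e <- emb_cache[[id]]
    if (is.null(e)) {
      tp <- tape_new()
      pget <- .param_getter(tp, model$params)
      fr <- .forward_complex(tp, pget, bundles[[id]], model$config, FALSE)
      e <- as.vector(tp_value(tp, fr$o))
      assign(id, e, envir = emb_cache)
    }
    e
  }
  correct <- 0L
  for (k in seq_len(n_pairs)) {
    pair <- sample_pair(sample_assay(assays))
    p <- predict_rank(model, emb_of(pair$ligand_a), emb_of(pair$ligand_b),
                      pair$task_type)
    correct <- correct + as.integer((p > 0.5) == (ranking_label(pair) == 1L))
  }
  structure(correct / n_pairs, n = n_pairs)
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints round-trip bit-exactly: parameters, configuration, epoch
#' counter, the caller's RNG state and a configuration fingerprint that is
#' verified on load.
#'
#' @param model an [mbp_model()].
#' @param path file path for the checkpoint.
#' @export
save_checkpoint <- function(model, path) {
  .assert(inherits(model, "mbp_model"), "model must be an mbp_model")
  rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  saveRDS(list(params = model$params, config = model$config,
               epoch = model$epoch, config_hash = model$config_hash,
               rng_state = rng, format = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  .assert(file.exists(path), paste0("checkpoint not found: ", path))
  ck <- readRDS(path)
  .assert(identical(ck$format, 1L), "unrecognized checkpoint format")
  if (!identical(.obj_hash(ck$config), ck$config_hash)) {
    stop("checkpoint configuration hash mismatch; refusing to load", call. = FALSE)
  }
  structure(list(config = ck$config, params = ck$params, epoch = ck$epoch,
                 config_hash = ck$config_hash, rng_state = ck$rng_state),
            class = "mbp_model")
}
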