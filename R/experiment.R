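# Experiment driver: pretrain -> adapt -> distill runs with repeats,
# the ablation lattice over {pretrain, gibda, distill}, the beta sweep and
# embedding export.

#' Configuration of a full experiment
#'
#' @param data either a [shift_spec()] (the benchmark is generated) or a
#'   list with `source` and `target` [domain_dataset()]s.
#' @param train a [gda_config()].
#' @param aug an [augmentation_config()] for the pre-training stage.
#' @param pretrain_on,gibda_on,distill_on stage toggles; all off is a
#'   source-only GCN.
#' @param repeats number of repeated runs; `seeds` optionally lists one
#'   seed per repeat (defaults to `seed + 0:(repeats-1)`).
#' @param seed base seed.
#' @export
run_config <- function(data, train = gda_config(), aug = augmentation_config(),
                       pretrain_on = TRUE, gibda_on = TRUE, distill_on = TRUE,
                       repeats = 3L, seed = 1L, seeds = NULL) {
  if (is.null(seeds)) seeds <- seed + seq_len(repeats) - 1L
  stopifnot(length(seeds) == repeats)
  train$gibda_on <- isTRUE(gibda_on)
  train$distill_on <- isTRUE(distill_on)
  list(data = data, train = train, aug = aug,
       pretrain_on = isTRUE(pretrain_on), gibda_on = isTRUE(gibda_on),
       distill_on = isTRUE(distill_on), repeats = as.integer(repeats),
       seed = as.integer(seed), seeds = as.integer(seeds))
}

.resolve_data <- function(data) {
  if (!is.null(data$source) && !is.null(data$target)) return(data)
  if (data$task == "graph") make_graph_shift_pair(data) else make_node_shift_pair(data)
}

# One pipeline execution at one seed; returns the trained states + metrics.
.run_once <- function(pair, config, seed) {
  tr <- config$train
  enc_params <- NULL
  if (config$pretrain_on) {
    union <- c(pair$source$graphs, pair$target$graphs)
    b0 <- batch_graphs(pair$source$graphs[1L])
    enc_cfg <- encoder_config(ncol(b0$X), tr$hidden_dim, tr$n_layers,
                              tr$relax_temperature, task = tr$task,
                              alpha_mode = if (tr$gibda_on) "scorer" else "off")
    pt <- pretrain_encoder(union, enc_cfg, config$aug,
                           seed = derive_seed(seed, 501L))
    enc_params <- pt$params
  }
  if (!tr$gibda_on && !tr$distill_on && !config$pretrain_on) {
    train_source_gcn(pair$source, pair$target, tr, seed = seed)
  } else {
    gda_train(pair$source, pair$target, tr, seed = seed,
              enc_params = enc_params)
  }
}

# Final target accuracy of a finished run (student if present, else teacher).
.final_acc <- function(fit) {
  if (!is.na(fit$final_acc_student)) fit$final_acc_student else fit$final_acc_teacher
}

#' Run an experiment over repeats
#'
#' Executes the enabled stages for each repeat seed and aggregates final
#' target accuracy. Target labels are consumed only by the reported
#' accuracies, never by training.
#'
#' @param config a [run_config()].
#' @return list of class `metrics_record`: per-repeat `runs` (fits with
#'   per-epoch metrics), `final_acc` per repeat, `acc_mean`, `acc_sd`.
#' @export
run_experiment <- function(config) {
  pair <- .resolve_data(config$data)
  runs <- lapply(config$seeds, function(s) .run_once(pair, config, s))
  accs <- vapply(runs, .final_acc, numeric(1L))
  structure(list(runs = runs, final_acc = accs,
                 acc_mean = mean(accs), acc_sd = stats::sd(accs),
                 seeds = config$seeds),
            class = "metrics_record")
}

#' Ablation suite over the component lattice
#'
#' Runs the full model plus the six variants obtained by removing
#' non-empty proper subsets of {pretrain, gibda, distill}, all with the
#' same seeds (paired comparison). The remove-everything configuration is
#' the source-only baseline, available through [run_experiment()] with all
#' toggles off.
#'
#' @param config a [run_config()] describing the full model.
#' @return data.frame with one row per variant: the removed components,
#'   per-seed final accuracies, mean and sd.
#' @export
ablation_suite <- function(config) {
  toggles <- c("pretrain", "gibda", "distill")
  removals <- list(character(0))
  for (k in 1:2) removals <- c(removals, utils::combn(toggles, k, simplify = FALSE))
  rows <- lapply(removals, function(rm) {
    cf <- run_config(config$data, config$train, config$aug,
                     pretrain_on = !("pretrain" %in% rm),
                     gibda_on = !("gibda" %in% rm),
                     distill_on = !("distill" %in% rm),
                     repeats = config$repeats, seed = config$seed,
                     seeds = config$seeds)
    res <- run_experiment(cf)
    data.frame(variant = if (length(rm) == 0L) "full" else paste0("-", paste(rm, collapse = ",-")),
               removed = paste(rm, collapse = ","),
               acc_mean = res$acc_mean, acc_sd = res$acc_sd,
               acc_median = stats::median(res$final_acc),
               accs = I(list(res$final_acc)))
  })
  do.call(rbind, rows)
}

#' Accuracy as a function of the bottleneck weight
#'
#' One [run_experiment()] per beta on shared seeds.
#'
#' @param config a [run_config()].
#' @param betas increasing grid, by default six points spanning 0 to 0.05.
#' @return data.frame with columns `beta`, `acc_mean`, `acc_sd`, `accs`.
#' @export
beta_sweep <- function(config, betas = seq(0, 0.05, length.out = 6L)) {
  stopifnot(!is.unsorted(betas))
  rows <- lapply(betas, function(b) {
    cf <- config
    cf$train$beta <- b
    res <- run_experiment(cf)
    data.frame(beta = b, acc_mean = res$acc_mean, acc_sd = res$acc_sd,
               acc_median = stats::median(res$final_acc),
               accs = I(list(res$final_acc)))
  })
  do.call(rbind, rows)
}

#' Export representations with domain and class metadata
#'
#' @param state a trained teacher or student state.
#' @param dataset a [domain_dataset()].
#' @param seed evaluation seed (hard structure draws).
#' @return data.frame: one row per graph (or node), `hidden_dim`
#'   representation columns `Z1..Zk` plus `domain` and `class`.
#' @export
export_embeddings <- function(state, dataset, seed = 1L) {
  batch <- batch_graphs(dataset$graphs)
  eo <- encode_graphs(batch, state$enc, state$config, seed = seed, mode = "hard")
  Z <- eo$representations
  cls <- if (state$config$task == "graph") {
    if (dataset$labels_visible) batch$labels else dataset$hidden_labels
  } else .hidden_labels(dataset, "node")
  if (is.null(cls)) cls <- rep(NA_integer_, nrow(Z))
  out <- as.data.frame(Z)
  names(out) <- paste0("Z", seq_len(ncol(Z)))
  out$domain <- dataset$domain
  out$class <- cls
  out
}

#' Rank-based attribution of learned keep probabilities
#'
#' Scores every stored edge of every graph by its learned keep probability
#' in the deepest layer (whose edge scores see structure-aware embeddings;
#' first-layer scores are computed from raw node features and are blind to
#' structure) and returns the area under the ROC curve for separating
#' planted-motif edges from background edges (chance = 0.5).
#'
#' @param state trained teacher or student state.
#' @param dataset a dataset from [make_graph_shift_pair()].
#' @param seed evaluation seed.
#' @export
alpha_motif_auc <- function(state, dataset, seed = 1L) {
  truth <- motif_edge_ground_truth(dataset)
  scores <- numeric(0); labels <- logical(0)
  for (i in seq_along(dataset$graphs)) {
    g <- dataset$graphs[[i]]
    if (nrow(g$edges) == 0L) next
    b <- batch_graphs(list(g))
    eo <- encode_graphs(b, state$enc, state$config,
                        seed = derive_seed(seed, i), mode = "hard")
    a <- eo$edge_alpha[[length(eo$edge_alpha)]]
    lab <- seq_len(nrow(g$edges)) %in% truth[[i]]
    scores <- c(scores, a); labels <- c(labels, lab)
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
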