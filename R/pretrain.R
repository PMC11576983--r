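# Joint self-supervised initialization: two stochastic views per batch
# (edge dropping + feature masking) pulled together with the NT-Xent loss.

#' Augmentation / pre-training configuration
#'
#' @param edge_drop_rate probability of dropping each edge, in `[0, 1)`.
#' @param feature_mask_rate probability of zeroing each feature entry per
#'   node, in `[0, 1)`.
#' @param tau NT-Xent temperature (> 0, default 0.5).
#' @param epochs,batch_size optimization schedule.
#' @param lr Adam learning rate for the encoder.
#' @export
augmentation_config <- function(edge_drop_rate = 0.2, feature_mask_rate = 0.1,
                                tau = 0.5, epochs = 30L, batch_size = 64L,
                                lr = 0.001) {
  stopifnot(edge_drop_rate >= 0, edge_drop_rate < 1,
            feature_mask_rate >= 0, feature_mask_rate < 1, tau > 0)
  list(edge_drop_rate = edge_drop_rate, feature_mask_rate = feature_mask_rate,
       tau = tau, epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr)
}

# One stochastic view of a batch: drop edges, zero feature entries.
.augment_view <- function(batch, config, seed) {
  set.seed(seed)
  E <- length(batch$eu)
  keep <- if (config$edge_drop_rate > 0 && E > 0L) {
    stats::runif(E) >= config$edge_drop_rate
  } else rep(TRUE, E)
  X <- batch$X
  if (config$feature_mask_rate > 0) {
    M <- matrix(stats::runif(length(X)) >= config$feature_mask_rate,
                nrow(X), ncol(X))
    X <- X * M
  }
  out <- batch
  out$X <- X
  out$eu <- batch$eu[keep]
  out$ev <- batch$ev[keep]
  out
}

#' Two correlated stochastic views of a graph batch
#'
#' Each view independently drops every edge with probability
#' `edge_drop_rate` and zeroes each feature entry with probability
#' `feature_mask_rate`; node counts and graph membership are untouched.
#'
#' @param batch a `graph_batch`.
#' @param config an [augmentation_config()].
#' @param seed integer seed; the same seed reproduces the same view pair.
#' @return list with elements `a` and `b`, both `graph_batch` objects.
#' @export
augment_batch <- function(batch, config, seed = 1L) {
  list(a = .augment_view(batch, config, derive_seed(seed, 1L)),
       b = .augment_view(batch, config, derive_seed(seed, 2L)))
}

#' Normalized-temperature cross-entropy (NT-Xent) contrastive loss
#'
#' For each anchor row `i` of `z_a` the positive is row `i` of `z_b` and the
#' negatives are all other rows of `z_b`; similarities are cosine scaled by
#' `1 / tau`. Both anchor directions are averaged.
#'
#' @param z_a,z_b embedding matrices with matching row counts (>= 2).
#' @param tau temperature (> 0).
#' @export
nt_xent_loss <- function(z_a, z_b, tau = 0.5) {
  stopifnot(nrow(z_a) == nrow(z_b), nrow(z_a) >= 2L, tau > 0)
  n <- nrow(z_a)
  na <- z_a / sqrt(rowSums(z_a^2) + 1e-12)
  nb <- z_b / sqrt(rowSums(z_b^2) + 1e-12)
  S <- (na %*% t(nb)) / tau
  ce <- function(M) {
    P <- .softmax_rows(M)
    -mean(log(pmax(P[cbind(seq_len(n), seq_len(n))], 1e-12)))
  }
  0.5 * (ce(S) + ce(t(S)))
}

# Tape version used inside pretraining.
.nt_xent_fwd <- function(tape, za, zb, tau) {
  na <- ad_row_l2_normalize(tape, za)
  nb <- ad_row_l2_normalize(tape, zb)
  S <- ad_scale(tape, ad_mm(tape, na, ad_t(tape, nb)), 1 / tau)
  n <- nrow(S$value)
  l1 <- ad_softmax_ce(tape, S, seq_len(n))
  l2 <- ad_softmax_ce(tape, ad_t(tape, S), seq_len(n))
  ad_scale(tape, ad_add(tape, l1, l2), 0.5)
}

#' Contrastive pre-training of the encoder
#'
#' Optimizes the encoder alone (structure sampling active, so the edge
#' scorer is warmed up too) with NT-Xent over paired stochastic views of
#' the pooled source + target graphs. Labels are never read.
#'
#' @param union_dataset a [domain_dataset()] or plain list of graphs
#'   pooling both domains.
#' @param enc_config an [encoder_config()].
#' @param aug_config an [augmentation_config()].
#' @param seed integer seed controlling initialization, batching,
#'   augmentation and structure sampling.
#' @param params optional starting encoder parameters.
#' @return list with `params` (trained encoder parameters) and `loss`
#'   (per-epoch mean NT-Xent trajectory).
#' @export
pretrain_encoder <- function(union_dataset, enc_config, aug_config, seed = 1L,
                             params = NULL) {
  graphs <- if (inherits(union_dataset, "domain_dataset")) union_dataset$graphs else union_dataset
  if (length(graphs) == 0L) stop("pretrain_encoder: empty dataset")
  if (is.null(params)) params <- init_encoder_params(enc_config, derive_seed(seed, 11L))
  opt <- opt_init("adam", aug_config$lr)
  ng <- length(graphs)
  bs <- min(aug_config$batch_size, ng)
  losses <- numeric(aug_config$epochs)
  for (ep in seq_len(aug_config$epochs)) {
    set.seed(derive_seed(seed, 13L, ep))
    perm <- sample.int(ng)
    nb <- max(1L, floor(ng / bs))
    eploss <- 0
    for (bi in seq_len(nb)) {
      idx <- perm[((bi - 1L) * bs + 1L):(bi * bs)]
      batch <- batch_graphs(graphs[idx])
      views <- augment_batch(batch, aug_config, derive_seed(seed, 17L, ep, bi))
      tape <- ad_tape()
      pn <- ad_wrap_params(tape, params)
      ea <- .encode_fwd(tape, views$a, pn, enc_config,
                        .maybe_noise(enc_config, derive_seed(seed, 19L, ep, bi),
                                     length(views$a$eu)))
      eb <- .encode_fwd(tape, views$b, pn, enc_config,
                        .maybe_noise(enc_config, derive_seed(seed, 23L, ep, bi),
                                     length(views$b$eu)))
      loss <- .nt_xent_fwd(tape, ea$pooled, eb$pooled, aug_config$tau)
      ad_backward(tape, loss)
      st <- opt_step(opt, params, ad_collect_grads(pn))
      params <- st$params; opt <- st$opt
      eploss <- eploss + loss$value[1L]
    }
    losses[ep] <- eploss / nb
  }
  list(params = params, loss = losses)
}
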