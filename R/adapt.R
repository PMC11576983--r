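# GIB-constrained adversarial adaptation: single-layer classifier, a
# Donsker-Varadhan mutual-information critic over (source, target)
# representation pairs, the combined loss
#   L_cla - L_adv + beta * (I_up_source + I_up_target)
# and the alternating minimax update (critic ascends the DV bound, the
# encoder + classifier descend the total with the critic frozen, so the
# encoder *maximizes* estimated cross-domain mutual information).

#' Initialize the single-layer classifier
#' @param hidden_dim representation width.
#' @param n_classes number of classes.
#' @param seed integer seed.
#' @export
init_classifier_params <- function(hidden_dim, n_classes, seed = 1L) {
  set.seed(seed)
  list(Wc = .glorot(hidden_dim, n_classes), bc = matrix(0, 1L, n_classes))
}

#' Initialize the DV critic
#'
#' A two-layer feed-forward map from a concatenated (source, target)
#' representation pair to a real score.
#'
#' @param rep_dim representation width (the critic input is `2 * rep_dim`).
#' @param hidden critic hidden width.
#' @param seed integer seed.
#' @export
init_critic_params <- function(rep_dim, hidden = 32L, seed = 1L) {
  set.seed(seed)
  list(Wd1 = .glorot(2L * rep_dim, hidden), bd1 = matrix(0, 1L, hidden),
       Wd2 = .glorot(hidden, 1L), bd2 = matrix(0, 1L, 1L))
}

#' Class probabilities from representations
#' @param representations matrix, one row per graph or node.
#' @param classifier_params from [init_classifier_params()].
#' @return softmax probability matrix; rows sum to one.
#' @export
classify <- function(representations, classifier_params) {
  logits <- representations %*% classifier_params$Wc
  logits <- logits + classifier_params$bc[rep.int(1L, nrow(logits)), , drop = FALSE]
  .softmax_rows(logits)
}

#' Mean cross-entropy classification loss
#' @param probabilities softmax rows from [classify()].
#' @param labels integer class labels, 0-based.
#' @export
classification_loss <- function(probabilities, labels) {
  labels <- as.integer(labels) + 1L
  stopifnot(all(labels >= 1L), all(labels <= ncol(probabilities)))
  -mean(log(pmax(probabilities[cbind(seq_along(labels), labels)], 1e-12)))
}

# Numeric critic scores on paired rows.
.critic_score <- function(zs, zt, cp) {
  x <- cbind(zs, zt) %*% cp$Wd1
  h <- pmax(x + cp$bd1[rep.int(1L, nrow(x)), , drop = FALSE], 0)
  as.numeric(h %*% cp$Wd2 + cp$bd2[1L])
}

# Seeded derangement (permutation without fixed points) of 1..n.
.derangement <- function(n, seed) {
  stopifnot(n >= 2L)
  if (n == 2L) return(c(2L, 1L))
  set.seed(seed)
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Donsker-Varadhan lower bound on cross-domain mutual information
#'
#' Joint pairs are the index-aligned rows (after truncating to the shorter
#' batch); marginal pairs re-pair the target rows by a seeded derangement.
#' The value is `mean(T_joint) - log mean(exp(T_marginal))` with
#' max-shifted log-mean-exp; larger means more estimated dependence.
#'
#' @param z_s,z_t representation matrices.
#' @param critic_params from [init_critic_params()].
#' @param pairing_seed seed of the marginal derangement.
#' @export
dv_mi_lower_bound <- function(z_s, z_t, critic_params, pairing_seed = 1L) {
  n <- min(nrow(z_s), nrow(z_t))
  if (n < 2L) stop("dv_mi_lower_bound: batch size must be >= 2")
  zs <- z_s[seq_len(n), , drop = FALSE]
  zt <- z_t[seq_len(n), , drop = FALSE]
  tj <- .critic_score(zs, zt, critic_params)
  pi_ <- .derangement(n, pairing_seed)
  tm <- .critic_score(zs, zt[pi_, , drop = FALSE], critic_params)
  m <- max(tm)
  mean(tj) - (log(mean(exp(tm - m))) + m)
}

# Tape DV given representation nodes; cn = critic parameter nodes.
.dv_fwd <- function(tape, zs, zt, cn, pairing_seed) {
  n <- min(nrow(zs$value), nrow(zt$value))
  zs <- ad_rows(tape, zs, seq_len(n))
  zt_j <- ad_rows(tape, zt, seq_len(n))
  pi_ <- .derangement(n, pairing_seed)
  zt_m <- ad_rows(tape, zt, pi_)
  score <- function(a, b) {
    h <- ad_relu(tape, ad_add(tape, ad_mm(tape, ad_cbind(tape, a, b), cn$Wd1), cn$bd1))
    ad_add(tape, ad_mm(tape, h, cn$Wd2), cn$bd2)
  }
  tj <- score(zs, zt_j)
  tm <- score(zs, zt_m)
  ad_sub(tape, ad_mean_all(tape, tj), ad_logmeanexp(tape, tm))
}

#' Train a DV critic to estimate mutual information from samples
#'
#' Full-batch Adam ascent of the DV bound over paired samples; used both
#' inside the adversarial loop and standalone as a mutual-information
#' estimator on (for example) bivariate Gaussian draws.
#'
#' @param z_s,z_t paired sample matrices (rows aligned).
#' @param steps ascent steps.
#' @param lr Adam learning rate.
#' @param hidden critic width.
#' @param seed controls initialization and the per-step derangements.
#' @param critic_params optional warm start.
#' @return list with `critic_params` and `dv` (the final bound value).
#' @export
dv_critic_train <- function(z_s, z_t, steps = 300L, lr = 0.005, hidden = 32L,
                            seed = 1L, critic_params = NULL) {
  if (is.null(critic_params)) {
    critic_params <- init_critic_params(ncol(z_s), hidden, derive_seed(seed, 31L))
  }
  opt <- opt_init("adam", lr)
  for (st in seq_len(steps)) {
    tape <- ad_tape()
    cn <- ad_wrap_params(tape, critic_params)
    dv <- .dv_fwd(tape, ad_const(tape, z_s), ad_const(tape, z_t), cn,
                  derive_seed(seed, 37L, st))
    neg <- ad_scale(tape, dv, -1)
    ad_backward(tape, neg)
    up <- opt_step(opt, critic_params, ad_collect_grads(cn))
    critic_params <- up$params; opt <- up$opt
  }
  list(critic_params = critic_params,
       dv = dv_mi_lower_bound(z_s, z_t, critic_params, derive_seed(seed, 41L)))
}

#' Decompose the adaptation loss of one source/target batch pair
#'
#' @param source_batch,target_batch `graph_batch` objects (source labels
#'   must be visible).
#' @param encoder_out_s,encoder_out_t outputs of [encode_graphs()].
#' @param params list with `cls` (classifier) and `critic` parameter lists.
#' @param beta non-negative weight of the two information-bottleneck terms.
#' @param pairing_seed derangement seed for the DV marginal term.
#' @return list of class `adapt_loss_terms`: `l_cla`, `l_adv`,
#'   `i_up_source`, `i_up_target`, `beta` and
#'   `total = l_cla - l_adv + beta * (i_up_source + i_up_target)`.
#' @export
adapt_loss <- function(source_batch, target_batch, encoder_out_s, encoder_out_t,
                       params, beta, pairing_seed = 1L) {
  labs <- if (!is.null(source_batch$labels) && !all(is.na(source_batch$labels))) {
    source_batch$labels
  } else source_batch$node_labels
  if (any(is.na(labs))) stop("adapt_loss: source labels must be visible")
  probs <- classify(encoder_out_s$representations, params$cls)
  l_cla <- classification_loss(probs, labs)
  l_adv <- dv_mi_lower_bound(encoder_out_s$representations,
                             encoder_out_t$representations,
                             params$critic, pairing_seed)
  i_s <- encoder_out_s$i_up
  i_t <- encoder_out_t$i_up
  structure(list(l_cla = l_cla, l_adv = l_adv, i_up_source = i_s,
                 i_up_target = i_t, beta = beta,
                 total = l_cla - l_adv + beta * (i_s + i_t)),
            class = "adapt_loss_terms")
}
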