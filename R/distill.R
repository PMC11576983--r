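# Teacher-student meta pseudo-label distillation.
#
# Per batch: the teacher generates pseudo-labels for the target batch, the
# student takes one optimizer step on them, the student's improvement on
# truly labeled source data becomes the scalar feedback h, and the teacher
# then descends  L_adapt(y_s) + h * L_adapt(soft pseudo-labels)  with h
# treated as a detached constant (first-order bi-level approximation).
#
# All stochastic draws key off hash-derived seeds (seed, epoch, batch,
# role), never the global RNG position, so removing a pipeline stage never
# perturbs another stage's randomness.

# role tags for derive_seed
.R_INIT_ENC <- 101L; .R_INIT_CLS <- 102L; .R_INIT_CRITIC <- 103L
.R_PERM_S <- 104L; .R_PERM_T <- 105L
.R_NOISE_S <- 106L; .R_NOISE_T <- 107L; .R_PAIRING <- 108L
.R_PSEUDO <- 109L; .R_STUDENT_S <- 110L; .R_STUDENT_T <- 111L
.R_DISTILL_EVAL <- 112L; .R_EVAL <- 113L; .R_KMEANS <- 114L

#' Initialize a teacher state
#'
#' The teacher bundles encoder, classifier and DV critic parameters with
#' their optimizers (SGD for encoder + classifier, Adam for the critic).
#'
#' @param enc_config an [encoder_config()].
#' @param n_classes number of classes.
#' @param seed integer seed.
#' @param enc_params optional (pre-trained) encoder parameters.
#' @param lr learning rate of the encoder + classifier.
#' @param opt optimizer kind for encoder + classifier, `"adam"` or `"sgd"`.
#' @param lr_critic Adam learning rate of the critic.
#' @param critic_hidden critic width.
#' @export
init_teacher <- function(enc_config, n_classes, seed = 1L, enc_params = NULL,
                         lr = 0.01, opt = "adam", lr_critic = 0.001,
                         critic_hidden = 32L) {
  if (is.null(enc_params)) {
    enc_params <- init_encoder_params(enc_config, derive_seed(seed, .R_INIT_ENC))
  }
  list(enc = enc_params,
       cls = init_classifier_params(enc_config$hidden_dim, n_classes,
                                    derive_seed(seed, .R_INIT_CLS)),
       critic = init_critic_params(enc_config$hidden_dim, critic_hidden,
                                   derive_seed(seed, .R_INIT_CRITIC)),
       config = enc_config, n_classes = as.integer(n_classes),
       opt_main = opt_init(opt, lr),
       opt_critic = opt_init("adam", lr_critic),
       step = 0L)
}

#' Initialize a student from a pre-trained encoder and target clustering
#'
#' The encoder is copied from the supplied (typically pre-trained) weights;
#' the classifier weight column of each class is the direction of a k-means
#' centroid of the target representations (unsupervised semantic
#' clustering), so the student starts from a target-structured decision
#' boundary.
#'
#' @param pretrained_encoder encoder parameter list.
#' @param target_representations matrix of target representations under
#'   that encoder.
#' @param n_classes number of classes (= k of k-means).
#' @param enc_config the [encoder_config()] shared with the teacher.
#' @param seed integer seed.
#' @param lr Adam learning rate of the student.
#' @export
init_student <- function(pretrained_encoder, target_representations, n_classes,
                         enc_config, seed = 1L, lr = 0.001) {
  if (nrow(target_representations) < n_classes) {
    stop("init_student: fewer target samples than classes")
  }
  set.seed(derive_seed(seed, .R_KMEANS))
  km <- tryCatch(
    stats::kmeans(target_representations, centers = n_classes, nstart = 5L),
    error = function(e) NULL)
  h <- enc_config$hidden_dim
  Wc <- if (is.null(km)) {
    set.seed(derive_seed(seed, .R_KMEANS, 2L)); .glorot(h, n_classes)
  } else {
    t(km$centers / pmax(sqrt(rowSums(km$centers^2)), 1e-8))
  }
  list(enc = pretrained_encoder,
       cls = list(Wc = Wc, bc = matrix(0, 1L, n_classes)),
       config = enc_config, n_classes = as.integer(n_classes),
       opt_main = opt_init("adam", lr),
       step = 0L,
       cluster = if (is.null(km)) NULL else km$cluster)
}

#' Teacher pseudo-labels for a target batch
#'
#' Evaluation-mode encoding (hard structure sampling at a fixed seed)
#' followed by the classifier.
#'
#' @param teacher a teacher state.
#' @param target_batch a `graph_batch`.
#' @param seed integer seed for the hard structure draws.
#' @return list with `soft` (probability rows), `hard` (0-based argmax
#'   labels) and `step` (the teacher step that generated them).
#' @export
generate_pseudo_labels <- function(teacher, target_batch, seed = 1L) {
  eo <- encode_graphs(target_batch, teacher$enc, teacher$config,
                      seed = seed, mode = "hard")
  soft <- classify(eo$representations, teacher$cls)
  list(soft = soft, hard = max.col(soft) - 1L, step = teacher$step)
}

# Forward the teacher (or student) classifier on a tape-encoded batch.
.logits_fwd <- function(tape, rep_node, cls_nodes) {
  ad_add(tape, ad_mm(tape, rep_node, cls_nodes$Wc), cls_nodes$bc)
}

#' One teacher update step (Eq.-13-style combined objective)
#'
#' With the GIB adversarial stage enabled this performs one critic ascent
#' step on the DV bound and then one SGD descent step of encoder +
#' classifier on
#' `[L_cla(y_s) - L_adv + beta (I_up_s + I_up_t)] + h * [L_cla_soft(yhat_t)
#'  - L_adv + beta (I_up_s + I_up_t)]`,
#' with the critic frozen and `h` a detached scalar. With `h = 0` and no
#' pseudo batch this is exactly the plain adversarial adaptation step.
#'
#' @param teacher a teacher state.
#' @param h distill coefficient (scalar; see [distill_coefficient()]).
#' @param source_batch labeled source `graph_batch`.
#' @param target_batch target `graph_batch`.
#' @param pseudo output of [generate_pseudo_labels()] or NULL.
#' @param beta information-bottleneck weight.
#' @param seed integer seed for this step's structure noise and pairing.
#' @param gibda_on FALSE degrades the encoder to a plain GCN and drops the
#'   adversarial and bottleneck terms.
#' @return list with the updated `teacher` and the `terms`
#'   (`adapt_loss_terms`).
#' @export
teacher_step <- function(teacher, h, source_batch, target_batch, pseudo = NULL,
                         beta = 0.01, seed = 1L, gibda_on = TRUE) {
  labs <- .batch_labels(source_batch, teacher$config$task)
  need_target <- gibda_on || !is.null(pseudo)
  noise_seed_s <- derive_seed(seed, .R_NOISE_S)
  noise_seed_t <- derive_seed(seed, .R_NOISE_T)
  pair_seed <- derive_seed(seed, .R_PAIRING)

  if (gibda_on) {
    # critic ascent on detached representations (same structure noise)
    eo_s <- encode_graphs(source_batch, teacher$enc, teacher$config,
                          seed = noise_seed_s, mode = "relaxed")
    eo_t <- encode_graphs(target_batch, teacher$enc, teacher$config,
                          seed = noise_seed_t, mode = "relaxed")
    tape_c <- ad_tape()
    cn <- ad_wrap_params(tape_c, teacher$critic)
    dv_c <- .dv_fwd(tape_c, ad_const(tape_c, eo_s$representations),
                    ad_const(tape_c, eo_t$representations), cn, pair_seed)
    ad_backward(tape_c, ad_scale(tape_c, dv_c, -1))
    up <- opt_step(teacher$opt_critic, teacher$critic, ad_collect_grads(cn))
    teacher$critic <- up$params; teacher$opt_critic <- up$opt
  }

  # encoder + classifier descent, critic frozen
  obj <- .teacher_objective(c(teacher$enc, teacher$cls), teacher$critic,
                            teacher$config, source_batch, target_batch,
                            pseudo, h, beta, seed, gibda_on)
  if (!is.finite(obj$value)) stop("teacher_step: non-finite loss")
  up <- opt_step(teacher$opt_main, c(teacher$enc, teacher$cls), obj$grads)
  teacher$enc <- up$params[names(teacher$enc)]
  teacher$cls <- up$params[names(teacher$cls)]
  teacher$opt_main <- up$opt
  teacher$step <- teacher$step + 1L
  list(teacher = teacher, terms = obj$terms)
}

# The teacher-side descent objective of one step (critic held fixed):
#   [L_cla(y_s) - L_adv + beta (KL_s + KL_t)]
#   + h * [L_cla_soft(yhat_t) - L_adv + beta (KL_s + KL_t)]
# Returns the value, the gradients with respect to `main` (encoder +
# classifier parameters, flat named list) and the decomposed terms. All
# stochastic draws derive from `seed`, so repeated evaluation at different
# parameter values is a deterministic function — which is what makes a
# central-finite-difference check of the returned gradient meaningful.
.teacher_objective <- function(main, critic, config, source_batch, target_batch,
                               pseudo, h, beta, seed, gibda_on = TRUE) {
  labs <- .batch_labels(source_batch, config$task)
  noise_seed_s <- derive_seed(seed, .R_NOISE_S)
  noise_seed_t <- derive_seed(seed, .R_NOISE_T)
  pair_seed <- derive_seed(seed, .R_PAIRING)
  need_target <- gibda_on || !is.null(pseudo)
  tape <- ad_tape()
  pn <- ad_wrap_params(tape, main)
  cfg <- config
  if (!gibda_on) cfg$alpha_mode <- "off"
  fs <- .encode_fwd(tape, source_batch, pn, cfg,
                    .maybe_noise(cfg, noise_seed_s, length(source_batch$eu)),
                    reparam_seed = derive_seed(noise_seed_s, 7L))
  logits_s <- .logits_fwd(tape, fs$rep, pn)
  l_cla <- ad_softmax_ce(tape, logits_s, labs + 1L)
  if (gibda_on) {
    ft <- .encode_fwd(tape, target_batch, pn, cfg,
                      .maybe_noise(cfg, noise_seed_t, length(target_batch$eu)),
                      reparam_seed = derive_seed(noise_seed_t, 7L))
    cn_f <- ad_wrap_params(tape, critic)  # frozen: grads unread
    dv <- .dv_fwd(tape, fs$rep, ft$rep, cn_f, pair_seed)
    pen <- ad_scale(tape, ad_add(tape, fs$kl, ft$kl), beta)
    adapt_part <- ad_add(tape, ad_sub(tape, l_cla, dv), pen)
  } else {
    if (need_target) {
      ft <- .encode_fwd(tape, target_batch, pn, cfg, NULL)
    }
    adapt_part <- l_cla
  }
  total <- adapt_part
  if (!is.null(pseudo)) {
    logits_t <- .logits_fwd(tape, ft$rep, pn)
    l_soft <- ad_softmax_ce_soft(tape, logits_t, pseudo$soft)
    distill_part <- if (gibda_on) {
      ad_add(tape, ad_sub(tape, l_soft, dv),
             ad_scale(tape, ad_add(tape, fs$kl, ft$kl), beta))
    } else l_soft
    total <- ad_add(tape, adapt_part, ad_scale(tape, distill_part, h))
  }
  ad_backward(tape, total)
  terms <- structure(list(
    l_cla = l_cla$value[1L],
    l_adv = if (gibda_on) dv$value[1L] else 0,
    i_up_source = if (gibda_on) fs$kl$value[1L] else 0,
    i_up_target = if (gibda_on) ft$kl$value[1L] else 0,
    beta = beta, total = total$value[1L]), class = "adapt_loss_terms")
  list(value = total$value[1L], grads = ad_collect_grads(pn), terms = terms)
}

#' One plain adversarial adaptation step
#'
#' Critic ascent on the DV bound, then encoder + classifier descent on
#' `L_cla - L_adv + beta (I_up_s + I_up_t)` with the critic frozen.
#' Identical to [teacher_step()] with `h = 0` and no pseudo batch.
#'
#' @inheritParams teacher_step
#' @export
adapt_step <- function(teacher, source_batch, target_batch, beta = 0.01,
                       seed = 1L, gibda_on = TRUE) {
  teacher_step(teacher, h = 0, source_batch = source_batch,
               target_batch = target_batch, pseudo = NULL, beta = beta,
               seed = seed, gibda_on = gibda_on)
}

#' One student update on teacher pseudo-labels
#'
#' The student descends soft cross-entropy against the teacher's class
#' probabilities on the target batch plus (when the GIB stage is active)
#' the `beta`-weighted bottleneck penalties of both domains; source labels
#' are never read. Soft targets let the student weight the teacher's
#' confidence, which keeps it markedly closer to the teacher than hard
#' argmax labels when the teacher itself is noisy.
#'
#' @param student a student state.
#' @param source_batch,target_batch `graph_batch` objects.
#' @param pseudo output of [generate_pseudo_labels()].
#' @param beta bottleneck weight.
#' @param seed integer seed.
#' @param gibda_on whether the stochastic encoder + penalties are active.
#' @return updated student state.
#' @export
student_step <- function(student, source_batch, target_batch, pseudo,
                         beta = 0.01, seed = 1L, gibda_on = TRUE) {
  tape <- ad_tape()
  main <- c(student$enc, student$cls)
  pn <- ad_wrap_params(tape, main)
  cfg <- student$config
  if (!gibda_on) cfg$alpha_mode <- "off"
  ft <- .encode_fwd(tape, target_batch, pn, cfg,
                    .maybe_noise(cfg, derive_seed(seed, .R_STUDENT_T),
                                 length(target_batch$eu)),
                    reparam_seed = derive_seed(seed, .R_STUDENT_T, 7L))
  logits_t <- .logits_fwd(tape, ft$rep, pn)
  loss <- ad_softmax_ce_soft(tape, logits_t, pseudo$soft)
  if (gibda_on) {
    fs <- .encode_fwd(tape, source_batch, pn, cfg,
                      .maybe_noise(cfg, derive_seed(seed, .R_STUDENT_S),
                                   length(source_batch$eu)),
                      reparam_seed = derive_seed(seed, .R_STUDENT_S, 7L))
    loss <- ad_add(tape, loss,
                   ad_scale(tape, ad_add(tape, fs$kl, ft$kl), beta))
  }
  if (!is.finite(loss$value[1L])) stop("student_step: non-finite loss")
  ad_backward(tape, loss)
  up <- opt_step(student$opt_main, main, ad_collect_grads(pn))
  student$enc <- up$params[names(student$enc)]
  student$cls <- up$params[names(student$cls)]
  student$opt_main <- up$opt
  student$step <- student$step + 1L
  student
}

# Student classification loss on labeled source data, evaluation mode.
.student_source_loss <- function(student, source_batch, seed) {
  eo <- encode_graphs(source_batch, student$enc, student$config,
                      seed = seed, mode = "hard")
  labs <- .batch_labels(source_batch, student$config$task)
  classification_loss(classify(eo$representations, student$cls), labs)
}

#' Distill feedback coefficient
#'
#' `h = L_cla(student_before on source, y_s) - L_cla(student_after on
#' source, y_s)`: positive exactly when the pseudo-label update improved
#' the student on held-out truly labeled data.
#'
#' @param student_before,student_after student states around one
#'   [student_step()].
#' @param labeled_source_batch source `graph_batch` with labels.
#' @param seed evaluation seed (shared by both evaluations).
#' @return list with `h`, `before_loss`, `after_loss`.
#' @export
distill_coefficient <- function(student_before, student_after,
                                labeled_source_batch, seed = 1L) {
  before <- .student_source_loss(student_before, labeled_source_batch, seed)
  after <- .student_source_loss(student_after, labeled_source_batch, seed)
  list(h = before - after, before_loss = before, after_loss = after)
}

# Indices resampled so every class label appears equally often (with
# replacement for minority classes); degenerate single-class input is
# returned unchanged.
.balance_by_class <- function(labels, seed) {
  classes <- sort(unique(labels))
  if (length(classes) < 2L) return(seq_along(labels))
  per <- ceiling(length(labels) / length(classes))
  set.seed(seed)
  out <- integer(0)
  for (cl in classes) {
    members <- which(labels == cl)
    out <- c(out, members[sample.int(length(members), per, replace = TRUE)])
  }
  set.seed(derive_seed(seed, 3L))
  out[sample.int(length(out))]
}

# labels of a batch for the task at hand (graph labels or node labels)
.batch_labels <- function(batch, task) {
  labs <- if (task == "graph") batch$labels else batch$node_labels
  if (is.null(labs) || any(is.na(labs))) {
    stop("labels required but not visible on this batch")
  }
  labs
}

# 0-based predictions of a state's classifier on a dataset. Evaluation
# averages class probabilities over `draws` hard structure samples, which
# estimates the expected prediction under the learned Bernoulli structure
# model (one draw when the encoder is deterministic).
.predict_labels <- function(state, batch, seed, draws = 5L) {
  if (state$config$alpha_mode == "off") draws <- 1L
  acc <- NULL
  for (d in seq_len(draws)) {
    eo <- encode_graphs(batch, state$enc, state$config,
                        seed = derive_seed(seed, d), mode = "hard")
    p <- classify(eo$representations, state$cls)
    acc <- if (is.null(acc)) p else acc + p
  }
  max.col(acc) - 1L
}

# Match student k-means classes to teacher classes by majority vote.
.align_classifier_columns <- function(student, teacher_hard, student_hard) {
  k <- student$n_classes
  conf <- matrix(0L, k, k)
  for (i in seq_along(teacher_hard)) {
    conf[student_hard[i] + 1L, teacher_hard[i] + 1L] <-
      conf[student_hard[i] + 1L, teacher_hard[i] + 1L] + 1L
  }
  mapping <- rep(NA_integer_, k)
  cf <- conf
  for (step in seq_len(k)) {
    ij <- which(cf == max(cf), arr.ind = TRUE)[1L, ]
    mapping[ij[1L]] <- ij[2L]
    cf[ij[1L], ] <- -1L; cf[, ij[2L]] <- -1L
  }
  Wc <- student$cls$Wc
  newW <- Wc
  for (cl in seq_len(k)) newW[, mapping[cl]] <- Wc[, cl]
  student$cls$Wc <- newW
  student
}

#' Training configuration for the adaptation loop
#'
#' @param task `"graph"` or `"node"`.
#' @param hidden_dim,n_layers,relax_temperature encoder shape.
#' @param beta information-bottleneck weight (default 0.01).
#' @param epochs training epochs.
#' @param batch_size graphs per domain per batch (graph task).
#' @param lr_teacher teacher-side learning rate (default 0.01).
#' @param opt_teacher teacher-side optimizer kind, `"adam"` or `"sgd"`.
#' @param lr_student Adam rate of the student (default 0.01).
#' @param student_steps student updates per pseudo-label batch (default 2;
#'   the student learns from noisier labels than the teacher and needs the
#'   extra updates to track it within the same epoch budget).
#' @param lr_critic Adam rate of the critic.
#' @param critic_hidden critic width.
#' @param gibda_on,distill_on stage toggles; both off is a source-only GCN.
#' @export
gda_config <- function(task = "graph", hidden_dim = 64L, n_layers = 2L,
                       relax_temperature = 1, beta = 0.01, epochs = 60L,
                       batch_size = 64L, lr_teacher = 0.01, opt_teacher = "adam",
                       lr_student = 0.01, student_steps = 2L, lr_critic = 0.001,
                       critic_hidden = 32L, gibda_on = TRUE, distill_on = TRUE) {
  list(task = task, hidden_dim = as.integer(hidden_dim),
       n_layers = as.integer(n_layers), relax_temperature = relax_temperature,
       beta = beta, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), lr_teacher = lr_teacher,
       opt_teacher = opt_teacher, lr_student = lr_student,
       student_steps = as.integer(student_steps),
       lr_critic = lr_critic, critic_hidden = as.integer(critic_hidden),
       gibda_on = isTRUE(gibda_on), distill_on = isTRUE(distill_on))
}

#' Train the full adaptation pipeline
#'
#' Runs the per-batch loop (pseudo-label generation, student step, distill
#' coefficient, teacher step) for `config$epochs` epochs. Target labels are
#' never consumed by any loss; when the target dataset carries
#' `hidden_labels` they are used only to report per-epoch target accuracy.
#'
#' @param source labeled [domain_dataset()].
#' @param target unlabeled [domain_dataset()] (labels hidden).
#' @param config a [gda_config()].
#' @param seed integer master seed.
#' @param enc_params optional pre-trained encoder parameters for the
#'   teacher (the student always starts from them too when present).
#' @param h_clamp_zero force the distill coefficient to zero every step
#'   (diagnostic; reduces the loop to adversarial adaptation alone).
#' @return list with `teacher`, `student` (NULL when distilling is off) and
#'   `metrics` (one row per epoch).
#' @export
gda_train <- function(source, target, config, seed = 1L, enc_params = NULL,
                      h_clamp_zero = FALSE) {
  stopifnot(inherits(source, "domain_dataset"), source$labels_visible)
  stopifnot(inherits(target, "domain_dataset"), !target$labels_visible)
  task <- config$task
  src_all <- batch_graphs(source$graphs)
  tgt_all <- batch_graphs(target$graphs)
  labs_all <- .batch_labels(src_all, task)
  n_classes <- max(labs_all) + 1L
  enc_cfg <- encoder_config(ncol(src_all$X), config$hidden_dim, config$n_layers,
                            config$relax_temperature, task = task,
                            alpha_mode = if (config$gibda_on) "scorer" else "off")
  teacher <- init_teacher(enc_cfg, n_classes, seed = seed,
                          enc_params = enc_params, lr = config$lr_teacher,
                          opt = config$opt_teacher,
                          lr_critic = config$lr_critic,
                          critic_hidden = config$critic_hidden)
  student <- NULL
  if (config$distill_on) {
    eo_t <- encode_graphs(tgt_all, teacher$enc, enc_cfg,
                          seed = derive_seed(seed, .R_EVAL, 0L), mode = "hard")
    student <- init_student(teacher$enc, eo_t$representations, n_classes,
                            enc_cfg, seed = seed, lr = config$lr_student)
    ps0 <- generate_pseudo_labels(teacher, tgt_all,
                                  derive_seed(seed, .R_PSEUDO, 0L))
    sh0 <- .predict_labels(student, tgt_all, derive_seed(seed, .R_EVAL, 0L))
    student <- .align_classifier_columns(student, ps0$hard, sh0)
  }

  ns <- length(source$graphs); nt <- length(target$graphs)
  # per-epoch accuracy is tracked on a fixed subsample of the target for
  # speed; the final reported accuracy uses the full set
  hidden_all <- .hidden_labels(target, task)
  if (task == "graph" && nt > 150L && !is.null(hidden_all)) {
    set.seed(derive_seed(seed, .R_EVAL, 999L))
    ev_idx <- sort(sample.int(nt, 150L))
    tgt_eval <- .subset_batch(tgt_all, ev_idx)
    hidden_eval <- hidden_all[ev_idx]
  } else {
    tgt_eval <- tgt_all
    hidden_eval <- hidden_all
  }
  metrics <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    if (task == "graph") {
      set.seed(derive_seed(seed, .R_PERM_S, ep)); perm_s <- sample.int(ns)
      set.seed(derive_seed(seed, .R_PERM_T, ep)); perm_t <- sample.int(nt)
      bs <- min(config$batch_size, ns, nt)
      nb <- max(1L, floor(min(ns, nt) / bs))
    } else nb <- 1L
    acc_terms <- NULL; hs <- numeric(0)
    for (bi in seq_len(nb)) {
      if (task == "graph") {
        is_ <- perm_s[((bi - 1L) * bs + 1L):(bi * bs)]
        it_ <- perm_t[((bi - 1L) * bs + 1L):(bi * bs)]
        sb <- batch_graphs(source$graphs[is_])
        tb <- batch_graphs(target$graphs[it_])
      } else {
        sb <- src_all; tb <- tgt_all
      }
      step_seed <- derive_seed(seed, ep, bi)
      if (config$distill_on) {
        pseudo <- generate_pseudo_labels(teacher, tb,
                                         derive_seed(step_seed, .R_PSEUDO))
        # class-balanced batch composition for the student: resample the
        # target batch so each pseudo-class is equally represented, which
        # removes the pressure to collapse onto the majority pseudo-class
        # (labels themselves stay argmax of the teacher's probabilities)
        bal <- .balance_by_class(pseudo$hard, derive_seed(step_seed, 71L))
        tb_s <- if (task == "graph") .subset_batch(tb, bal) else tb
        ps_s <- if (task == "graph") {
          list(soft = pseudo$soft[bal, , drop = FALSE],
               hard = pseudo$hard[bal], step = pseudo$step)
        } else pseudo
        s_before <- student
        for (ss in seq_len(max(1L, config$student_steps))) {
          student <- student_step(student, sb, tb_s, ps_s, beta = config$beta,
                                  seed = derive_seed(step_seed, ss),
                                  gibda_on = config$gibda_on)
        }
        dc <- distill_coefficient(s_before, student, sb,
                                  derive_seed(step_seed, .R_DISTILL_EVAL))
        h <- if (h_clamp_zero) 0 else dc$h
        st <- teacher_step(teacher, h, sb, tb, pseudo, beta = config$beta,
                           seed = step_seed, gibda_on = config$gibda_on)
        hs <- c(hs, h)
      } else {
        st <- teacher_step(teacher, 0, sb, tb, pseudo = NULL,
                           beta = config$beta, seed = step_seed,
                           gibda_on = config$gibda_on)
      }
      teacher <- st$teacher
      tt <- unlist(st$terms[c("l_cla", "l_adv", "i_up_source", "i_up_target", "total")])
      acc_terms <- if (is.null(acc_terms)) tt else acc_terms + tt
    }
    mt <- as.list(acc_terms / nb)
    ev_seed <- derive_seed(seed, .R_EVAL, ep)
    mt$target_acc_teacher <- if (is.null(hidden_eval)) NA_real_ else {
      mean(.predict_labels(teacher, tgt_eval, ev_seed, draws = 1L) == hidden_eval)
    }
    mt$target_acc_student <- if (is.null(hidden_eval) || is.null(student)) NA_real_ else {
      mean(.predict_labels(student, tgt_eval, ev_seed, draws = 1L) == hidden_eval)
    }
    mt$h_mean <- if (length(hs)) mean(hs) else NA_real_
    mt$h_pos_frac <- if (length(hs)) mean(hs > 0) else NA_real_
    mt$epoch <- ep
    metrics[[ep]] <- as.data.frame(mt)
  }
  hidden <- hidden_all
  fin_seed <- derive_seed(seed, .R_EVAL, config$epochs + 1L)
  final_teacher <- if (is.null(hidden)) NA_real_ else {
    mean(.predict_labels(teacher, tgt_all, fin_seed) == hidden)
  }
  final_student <- if (is.null(hidden) || is.null(student)) NA_real_ else {
    mean(.predict_labels(student, tgt_all, fin_seed) == hidden)
  }
  list(teacher = teacher, student = student,
       metrics = do.call(rbind, metrics),
       final_acc_teacher = final_teacher, final_acc_student = final_student)
}

# hidden evaluation labels of a target dataset (graph or node level)
.hidden_labels <- function(target, task) {
  if (task == "graph") return(target$hidden_labels)
  nl <- target$graphs[[1L]]$node_labels
  if (!is.null(nl) && !any(is.na(nl))) nl else target$hidden_labels
}

#' Train a source-only GCN baseline
#'
#' A plain 2-layer GCN (every edge kept) plus single-layer classifier,
#' trained by SGD on source cross-entropy alone; the target is never
#' touched during training. Shares the batching and seed-derivation scheme
#' of [gda_train()], so it is also the exact trajectory reference for the
#' all-stages-off configuration.
#'
#' @inheritParams gda_train
#' @return list with `teacher` (the trained model) and `metrics`.
#' @export
train_source_gcn <- function(source, target, config, seed = 1L) {
  cfg <- config
  cfg$gibda_on <- FALSE; cfg$distill_on <- FALSE
  src_all <- batch_graphs(source$graphs)
  labs_all <- .batch_labels(src_all, cfg$task)
  n_classes <- max(labs_all) + 1L
  enc_cfg <- encoder_config(ncol(src_all$X), cfg$hidden_dim, cfg$n_layers,
                            cfg$relax_temperature, task = cfg$task,
                            alpha_mode = "off")
  model <- init_teacher(enc_cfg, n_classes, seed = seed, lr = cfg$lr_teacher,
                        opt = cfg$opt_teacher, lr_critic = cfg$lr_critic,
                        critic_hidden = cfg$critic_hidden)
  tgt_all <- batch_graphs(target$graphs)
  ns <- length(source$graphs); nt <- length(target$graphs)
  hidden_all <- .hidden_labels(target, cfg$task)
  if (cfg$task == "graph" && nt > 150L && !is.null(hidden_all)) {
    set.seed(derive_seed(seed, .R_EVAL, 999L))
    ev_idx <- sort(sample.int(nt, 150L))
    tgt_eval <- .subset_batch(tgt_all, ev_idx)
    hidden_eval <- hidden_all[ev_idx]
  } else {
    tgt_eval <- tgt_all
    hidden_eval <- hidden_all
  }
  metrics <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    if (cfg$task == "graph") {
      set.seed(derive_seed(seed, .R_PERM_S, ep)); perm_s <- sample.int(ns)
      set.seed(derive_seed(seed, .R_PERM_T, ep))  # consumed as in gda_train
      bs <- min(cfg$batch_size, ns, nt)
      nb <- max(1L, floor(min(ns, nt) / bs))
    } else nb <- 1L
    tot <- 0
    for (bi in seq_len(nb)) {
      sb <- if (cfg$task == "graph") {
        batch_graphs(source$graphs[perm_s[((bi - 1L) * bs + 1L):(bi * bs)]])
      } else src_all
      tape <- ad_tape()
      main <- c(model$enc, model$cls)
      pn <- ad_wrap_params(tape, main)
      fs <- .encode_fwd(tape, sb, pn, model$config, NULL)
      loss <- ad_softmax_ce(tape, .logits_fwd(tape, fs$rep, pn),
                            .batch_labels(sb, cfg$task) + 1L)
      ad_backward(tape, loss)
      up <- opt_step(model$opt_main, main, ad_collect_grads(pn))
      model$enc <- up$params[names(model$enc)]
      model$cls <- up$params[names(model$cls)]
      model$opt_main <- up$opt
      model$step <- model$step + 1L
      tot <- tot + loss$value[1L]
    }
    metrics[[ep]] <- data.frame(
      l_cla = tot / nb, l_adv = 0, i_up_source = 0, i_up_target = 0,
      total = tot / nb,
      target_acc_teacher = if (is.null(hidden_eval)) NA_real_ else {
        mean(.predict_labels(model, tgt_eval, derive_seed(seed, .R_EVAL, ep),
                             draws = 1L) == hidden_eval)
      },
      target_acc_student = NA_real_, h_mean = NA_real_, h_pos_frac = NA_real_,
      epoch = ep)
  }
  final_teacher <- if (is.null(hidden_all)) NA_real_ else {
    mean(.predict_labels(model, tgt_all,
                         derive_seed(seed, .R_EVAL, cfg$epochs + 1L)) == hidden_all)
  }
  list(teacher = model, student = NULL, metrics = do.call(rbind, metrics),
       final_acc_teacher = final_teacher, final_acc_student = NA_real_)
}
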