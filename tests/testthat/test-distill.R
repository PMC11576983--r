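# Teacher-student meta pseudo-label machinery.

make_states <- function(n = 20L, seed = 2L, hidden = 6L) {
  pair <- tiny_pair(n = n, seed = seed)
  sb <- batch_graphs(pair$source$graphs)
  tb <- batch_graphs(pair$target$graphs)
  cfg <- encoder_config(ncol(sb$X), hidden_dim = hidden)
  teacher <- init_teacher(cfg, 2L, seed = 3L, lr = 0.01)
  eo <- encode_graphs(tb, teacher$enc, cfg, seed = 1, mode = "hard")
  student <- init_student(teacher$enc, eo$representations, 2L, cfg,
                          seed = 4L, lr = 0.01)
  list(pair = pair, sb = sb, tb = tb, cfg = cfg, teacher = teacher,
       student = student)
}

test_that("student initialization is deterministic with the right shape", {
  set.seed(77)
  reps <- matrix(rnorm(60), 20, 3)
  cfg <- encoder_config(3L, hidden_dim = 3L)
  enc <- init_encoder_params(cfg, 1L)
  s1 <- init_student(enc, reps, 4L, cfg, seed = 9L)
  s2 <- init_student(enc, reps, 4L, cfg, seed = 9L)
  expect_identical(s1$cls, s2$cls)
  expect_equal(ncol(s1$cls$Wc), 4L)
  expect_identical(s1$enc, enc)
  expect_error(init_student(enc, reps[1:2, ], 4L, cfg), "fewer")
})

test_that("k-means initialization recovers well-separated clusters", {
  set.seed(41)
  centers <- rbind(c(6, 0), c(0, 6))
  y <- rep(0:1, each = 100)
  reps <- centers[y + 1, ] + matrix(rnorm(400), 200, 2)  # 6-sigma separation
  cfg <- encoder_config(2L, hidden_dim = 2L)
  st <- init_student(init_encoder_params(cfg, 1L), reps, 2L, cfg, seed = 5L)
  purity <- max(mean((st$cluster - 1L) == y), mean((2L - st$cluster) == y))
  expect_gte(purity, 0.95)
})

test_that("pseudo-labels are deterministic soft/hard pairs; oracle weights recover truth", {
  ms <- make_states()
  p1 <- generate_pseudo_labels(ms$teacher, ms$tb, seed = 8)
  p2 <- generate_pseudo_labels(ms$teacher, ms$tb, seed = 8)
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1$soft)), rep(1, nrow(p1$soft)),
               tolerance = 1e-6)
  expect_identical(p1$hard, max.col(p1$soft) - 1L)

  # a linearly separable toy with a hand-built oracle classifier
  set.seed(42)
  X <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  y <- rep(0:1, each = 20)
  ds <- domain_dataset(points_as_graphs(X, y), "source", TRUE)
  b <- batch_graphs(ds$graphs)
  cfg <- encoder_config(2L, hidden_dim = 2L, n_layers = 1L, readout_scale = 1,
                        alpha_mode = "off")
  teach <- init_teacher(cfg, 2L, seed = 1L)
  # identity featurizer (bias keeps ReLU live, adding 5 to each coordinate)
  # + classifier whose boundary is x1 + x2 = 0 after that offset
  teach$enc$W1 <- diag(2); teach$enc$b1 <- matrix(c(5, 5), 1)
  teach$cls$Wc <- matrix(c(-1, -1, 1, 1), 2, 2)
  teach$cls$bc <- matrix(c(10, -10), 1, 2)
  pl <- generate_pseudo_labels(teach, b, seed = 3)
  expect_equal(pl$hard, y)
})

test_that("student steps descend, freeze at zero lr, and are deterministic", {
  ms <- make_states()
  pseudo <- generate_pseudo_labels(ms$teacher, ms$tb, seed = 8)
  s0 <- ms$student; s0$opt_main <- gdadapt:::opt_init("adam", 0)
  r0 <- student_step(s0, ms$sb, ms$tb, pseudo, seed = 2)
  expect_identical(r0$enc, s0$enc); expect_identical(r0$cls, s0$cls)

  ra <- student_step(ms$student, ms$sb, ms$tb, pseudo, seed = 2)
  rb <- student_step(ms$student, ms$sb, ms$tb, pseudo, seed = 2)
  expect_identical(ra$enc, rb$enc)

  # repeated small steps on the same batch reduce the pseudo-label loss
  loss_of <- function(st, seed) {
    eo <- encode_graphs(ms$tb, st$enc, st$config, seed = seed, mode = "hard")
    classification_loss(classify(eo$representations, st$cls), pseudo$hard)
  }
  st <- ms$student; st$opt_main <- gdadapt:::opt_init("adam", 0.005)
  before <- loss_of(st, 91)
  for (k in 1:25) st <- student_step(st, ms$sb, ms$tb, pseudo, seed = k)
  expect_lt(loss_of(st, 91), before)
})

test_that("the distill coefficient is the source-loss improvement", {
  ms <- make_states()
  d0 <- distill_coefficient(ms$student, ms$student, ms$sb, seed = 5)
  expect_identical(d0$h, 0)
  expect_identical(d0$h, d0$before_loss - d0$after_loss)

  # when pseudo-labels equal the truth, a pseudo-label update helps on source
  set.seed(43)
  X <- rbind(matrix(rnorm(60, -2, 0.5), 30, 2), matrix(rnorm(60, 2, 0.5), 30, 2))
  y <- rep(0:1, each = 30)
  src <- domain_dataset(points_as_graphs(X, y), "source", TRUE)
  tgt <- domain_dataset(points_as_graphs(X + 0.1), "target", FALSE,
                        hidden_labels = y)
  sb <- batch_graphs(src$graphs); tb <- batch_graphs(tgt$graphs)
  cfg <- encoder_config(2L, hidden_dim = 4L, n_layers = 1L, readout_scale = 1)
  student <- init_student(init_encoder_params(cfg, 2L),
                          encode_graphs(tb, init_encoder_params(cfg, 2L), cfg,
                                        seed = 1, mode = "hard")$representations,
                          2L, cfg, seed = 3L, lr = 0.05)
  pseudo <- list(soft = diag(2)[y + 1, ], hard = y, step = 0L)
  upd <- student_step(student, sb, tb, pseudo, seed = 7)
  dc <- distill_coefficient(student, upd, sb, seed = 11)
  expect_gt(dc$h, 0)
})

test_that("teacher_step with h = 0 and no pseudo batch is a plain adapt_step", {
  ms <- make_states()
  pseudo <- generate_pseudo_labels(ms$teacher, ms$tb, seed = 8)
  ra <- adapt_step(ms$teacher, ms$sb, ms$tb, beta = 0.01, seed = 4)
  rb <- teacher_step(ms$teacher, h = 0, ms$sb, ms$tb, pseudo = pseudo,
                     beta = 0.01, seed = 4)
  expect_identical(ra$teacher$enc, rb$teacher$enc)
  expect_identical(ra$teacher$cls, rb$teacher$cls)
  expect_identical(ra$teacher$critic, rb$teacher$critic)
  # h scales the reinforcement: a different h gives a different update
  rc <- teacher_step(ms$teacher, h = 0.5, ms$sb, ms$tb, pseudo = pseudo,
                     beta = 0.01, seed = 4)
  expect_false(identical(rb$teacher$enc, rc$teacher$enc))
  # determinism
  rd <- teacher_step(ms$teacher, h = 0.5, ms$sb, ms$tb, pseudo = pseudo,
                     beta = 0.01, seed = 4)
  expect_identical(rc$teacher$enc, rd$teacher$enc)
})

test_that("training runs per-epoch metrics; clamping h reproduces adversarial-only teachers", {
  pair <- tiny_pair(n = 16, seed = 14)
  cfg <- gda_config(epochs = 4L, batch_size = 16L, hidden_dim = 6L)
  fit <- gda_train(pair$source, pair$target, cfg, seed = 2)
  expect_equal(nrow(fit$metrics), 4L)
  expect_true(all(c("l_cla", "l_adv", "i_up_source", "i_up_target",
                    "target_acc_teacher", "target_acc_student",
                    "h_mean", "h_pos_frac") %in% names(fit$metrics)))
  expect_true(all(fit$metrics$target_acc_teacher >= 0 &
                    fit$metrics$target_acc_teacher <= 1))

  clamped <- gda_train(pair$source, pair$target, cfg, seed = 2,
                       h_clamp_zero = TRUE)
  cfg_nod <- cfg; cfg_nod$distill_on <- FALSE
  advonly <- gda_train(pair$source, pair$target, cfg_nod, seed = 2)
  expect_identical(clamped$teacher$enc, advonly$teacher$enc)
  expect_identical(clamped$teacher$cls, advonly$teacher$cls)
  expect_identical(clamped$teacher$critic, advonly$teacher$critic)
})

test_that("target labels are never visible to the training path", {
  pair <- tiny_pair(n = 10, seed = 15)
  expect_false(pair$target$labels_visible)
  expect_true(all(vapply(pair$target$graphs,
                         function(g) is.null(g$label), logical(1L))))
  expect_error(
    gda_train(pair$target, pair$source, gda_config(epochs = 1L), seed = 1),
    "labels_visible")
})

test_that("the full loop also adapts node-level tasks on block-model networks", {
  pair <- make_node_shift_pair(shift_spec(task = "node", n_per_domain = 100,
                                          shift_kind = "feature_shift",
                                          shift_magnitude = 1,
                                          feature_dim = 6, seed = 2))
  cfg <- gda_config(task = "node", epochs = 60L, hidden_dim = 16L)
  fit <- gda_train(pair$source, pair$target, cfg, seed = 1)
  expect_equal(nrow(fit$metrics), 60L)
  # both networks share block structure, so the classes stay recoverable
  expect_gte(fit$final_acc_teacher, 0.85)
  expect_gte(fit$final_acc_student, 0.85)
})
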