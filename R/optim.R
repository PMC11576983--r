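# Plain SGD and Adam on flat named lists of parameter matrices.

opt_init <- function(kind = c("sgd", "adam"), lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  kind <- match.arg(kind)
  list(kind = kind, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L, m = NULL, v = NULL)
}

opt_step <- function(opt, params, grads) {
  if (opt$lr == 0) return(list(params = params, opt = opt))
  if (opt$kind == "sgd") {
    for (nm in names(params)) params[[nm]] <- params[[nm]] - opt$lr * grads[[nm]]
    return(list(params = params, opt = opt))
  }
  if (is.null(opt$m)) {
    opt$m <- lapply(params, function(p) p * 0)
    opt$v <- lapply(params, function(p) p * 0)
  }
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    mh <- opt$m[[nm]] / c1
    vh <- opt$v[[nm]] / c2
    params[[nm]] <- params[[nm]] - opt$lr * mh / (sqrt(vh) + opt$eps)
  }
  list(params = params, opt = opt)
}

# Deterministic seed derivation: mixes small integers into a 31-bit seed
# without touching the global RNG stream. Multiplier kept < 2^22 so the
# product stays exact in doubles.
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483629
  for (b in list(...)) {
    h <- (h * 2654435 + as.numeric(b) + 1013904223) %% 2147483629
  }
  as.integer(h)
}
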