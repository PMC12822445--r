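#' Normalize a raw MammaPrint-style risk score
#'
#' Maps the raw index in \[-1, 1\] onto \[0, 1\] via `(x + 1) / 2`, the scale
#' used for model training and prediction. The raw high/low cutoff at 0 maps
#' to 0.5.
#'
#' @param x numeric vector with values in \[-1, 1\].
#' @return `(x + 1) / 2`.
#' @export
normalize_mp_score <- function(x) {
  x <- as.numeric(x)
  if (any(is.na(x)) || any(x < -1) || any(x > 1))
    stop_invalid("raw scores must lie in [-1, 1]")
  (x + 1) / 2
}

#' Assign risk groups from a score
#'
#' On the raw scale, scores <= 0 are high-risk and scores > 0 low-risk; on
#' the normalized scale the boundary is 0.5 (<= 0.5 high, > 0.5 low). The
#' two scales agree through [normalize_mp_score()].
#'
#' @param score numeric vector.
#' @param scale `"raw"` or `"normalized"`.
#' @return character vector of `"high"` / `"low"`.
#' @export
assign_risk_group <- function(score, scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  score <- as.numeric(score)
  cut <- if (scale == "raw") 0 else 0.5
  rng <- if (scale == "raw") c(-1, 1) else c(0, 1)
  if (any(is.na(score)) || any(score < rng[1]) || any(score > rng[2]))
    stop_invalid("scores out of range for the ", scale, " scale")
  ifelse(score <= cut, "high", "low")
}

#' Dual mean-squared-error objective
#'
#' `(1/B) sum_i [lambda1 (Y_i - Yhat_i)^2 +
#'               lambda2 1(Y_i > 0.5) (Y_i - Yhat_i)^2]`:
#' ordinary MSE plus an extra penalty on the cases whose label exceeds the
#' 0.5 risk boundary, balancing the contribution of the two groups.
#'
#' @param y true normalized labels in \[0, 1\].
#' @param yhat predictions in \[0, 1\].
#' @param lambda1,lambda2 non-negative scale factors (defaults 1, 1).
#' @return non-negative scalar loss.
#' @export
dual_mse_loss <- function(y, yhat, lambda1 = 1, lambda2 = 1) {
  if (length(y) != length(yhat))
    stop_invalid("y and yhat must have equal length")
  ind <- as.numeric(y > 0.5)
  mean((lambda1 + lambda2 * ind) * (y - yhat)^2)
}

#' Learning rate schedule
#'
#' Linear decay from `lr_init` at epoch 0 to `lr_floor` at epoch
#' `decay_epochs`, constant at the floor afterwards.
#'
#' @param epoch zero-based epoch index.
#' @param lr_init,lr_floor initial and floor rates.
#' @param decay_epochs epochs over which to decay.
#' @return learning rate at `epoch`.
#' @export
lr_at_epoch <- function(epoch, lr_init = 1e-4, lr_floor = 1e-5,
                        decay_epochs = 500L) {
  frac <- pmin(epoch / decay_epochs, 1)
  lr_init + frac * (lr_floor - lr_init)
}

#' Training configuration
#'
#' Optimization protocol defaults: Adam (`beta1 = 0.9`), learning rate
#' 1e-4 decaying linearly to 1e-5 at epoch 500, at most 1000 epochs,
#' early stopping after 50 epochs without validation improvement, gradient
#' accumulation over 32 bags.
#'
#' @param lr_init,lr_floor,lr_decay_epochs learning-rate schedule.
#' @param max_epochs,patience stopping rule.
#' @param accum_size bags per accumulated optimizer step.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param seed RNG seed for shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr_init = 1e-4, lr_floor = 1e-5,
                         lr_decay_epochs = 500L, max_epochs = 1000L,
                         patience = 50L, accum_size = 32L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = 1L) {
  if (lr_floor > lr_init) stop_invalid("lr_floor must not exceed lr_init")
  if (patience > max_epochs) stop_invalid("patience must not exceed max_epochs")
  structure(list(lr_init = lr_init, lr_floor = lr_floor,
                 lr_decay_epochs = as.integer(lr_decay_epochs),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 accum_size = as.integer(accum_size),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Patient-level repeated cross-validation plan
#'
#' For each of `times` experiments: a random 20% of patients is held out
#' for testing and the remainder is split into `folds` disjoint folds of
#' near-equal size (sizes differ by at most one). All slides of a patient
#' follow the patient, so no patient appears in more than one set. When
#' `risk_group` is supplied the test split is stratified by group.
#'
#' @param patient_ids character vector of unique patient identifiers.
#' @param times number of repetitions (default 5).
#' @param folds folds per repetition (default 5).
#' @param test_frac held-out test fraction (default 0.2).
#' @param seed RNG seed; the plan is a pure function of its arguments.
#' @param risk_group optional per-patient `"high"`/`"low"` labels used to
#'   stratify the test split.
#' @return list of class `cv_plan`; element `t` has `$test` and `$folds`
#'   (list of `folds` patient-id vectors).
#' @export
make_cv_plan <- function(patient_ids, times = 5L, folds = 5L,
                         test_frac = 0.2, seed = 1L, risk_group = NULL) {
  patient_ids <- as.character(patient_ids)
  if (anyDuplicated(patient_ids)) stop_invalid("patient_ids must be unique")
  n <- length(patient_ids)
  n_test <- round(n * test_frac)
  if (n - n_test < folds)
    stop_invalid("too few patients for ", folds, " folds after the test split")
  set.seed(seed)
  plan <- vector("list", times)
  for (t in seq_len(times)) {
    if (is.null(risk_group)) {
      test <- sample(patient_ids, n_test)
    } else {
      # proportional allocation per group, remainder to the larger group
      test <- character(0)
      for (grp in unique(risk_group)) {
        ids <- patient_ids[risk_group == grp]
        take <- round(length(ids) * test_frac)
        test <- c(test, sample(ids, min(take, length(ids))))
      }
      if (length(test) > n_test) test <- test[seq_len(n_test)]
    }
    rest <- sample(setdiff(patient_ids, test))
    fold_id <- rep(seq_len(folds), length.out = length(rest))
    plan[[t]] <- list(test = sort(test),
                      folds = lapply(seq_len(folds),
                                     function(f) sort(rest[fold_id == f])))
  }
  structure(plan, class = "cv_plan",
            times = times, folds = folds, seed = seed)
}

# Flat Adam update over a list of tensors.
adam_step <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# Accumulated gradient over a set of bags (mean of per-bag gradients).
accumulate_gradients <- function(bags, params, config) {
  acc <- zero_like(params)
  loss <- 0
  for (bag in bags) {
    res <- forward_bag_impl(bag, params, config, keep_cache = TRUE)
    g <- backward_bag(res, params, config, bag$label_normalized)
    for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]]
    loss <- loss + bag_loss(res$risk_probability, bag$label_normalized, config)
  }
  nb <- length(bags)
  list(grads = lapply(acc, function(a) a / nb), loss = loss / nb)
}

validation_loss <- function(bags, params, config) {
  mean(vapply(bags, function(bag) {
    bag_loss(forward_bag_impl(bag, params, config)$risk_probability,
             bag$label_normalized, config)
  }, numeric(1)))
}

#' Train the slide-level model
#'
#' Bags are processed one at a time (batch-of-one forward), accumulating
#' gradients over `accum_size` bags before each Adam step; the accumulated
#' gradient is divided by the number of bags in the window, so a partial
#' window at the end of an epoch takes an equivalent step. The learning rate
#' follows [lr_at_epoch()]. Training stops when the validation loss has not
#' strictly decreased for `patience` consecutive epochs, or at
#' `max_epochs`; the parameters achieving the minimum validation loss are
#' returned.
#'
#' @param train_bags,val_bags lists of labeled [tile_bag()]s.
#' @param config a [model_config()].
#' @param tconf a [train_config()].
#' @param init_seed seed for parameter initialization (default
#'   `tconf$seed`).
#' @param verbose print per-epoch losses.
#' @return list with `params` (best), `config`, `history` (data frame with
#'   per-epoch train/validation loss and learning rate), `best_epoch`.
#' @export
train_model <- function(train_bags, val_bags, config, tconf = train_config(),
                        init_seed = tconf$seed, verbose = FALSE) {
  labs <- vapply(c(train_bags, val_bags),
                 function(b) is.null(b$label_normalized), logical(1))
  if (any(labs)) stop_invalid("all training/validation bags must be labeled")
  params <- init_params(config, seed = init_seed)
  state <- list(t = 0L, m = zero_like(params), v = zero_like(params))
  set.seed(tconf$seed)
  best <- list(loss = Inf, params = params, epoch = 0L)
  since_improved <- 0L
  hist <- list()

  for (epoch in seq_len(tconf$max_epochs) - 1L) {
    lr <- lr_at_epoch(epoch, tconf$lr_init, tconf$lr_floor,
                      tconf$lr_decay_epochs)
    order_idx <- sample(length(train_bags))
    ep_loss <- 0; nwin <- 0L
    i <- 1L
    while (i <= length(order_idx)) {
      j <- min(i + tconf$accum_size - 1L, length(order_idx))
      win <- train_bags[order_idx[i:j]]
      acc <- accumulate_gradients(win, params, config)
      if (!is.finite(acc$loss))
        stop_invalid("non-finite loss at epoch ", epoch)
      upd <- adam_step(params, acc$grads, state, lr,
                       tconf$beta1, tconf$beta2, tconf$eps)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + acc$loss * length(win)
      nwin <- nwin + length(win)
      i <- j + 1L
    }
    vl <- validation_loss(val_bags, params, config)
    hist[[epoch + 1L]] <- c(epoch = epoch, train_loss = ep_loss / nwin,
                            val_loss = vl, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                      epoch, ep_loss / nwin, vl, lr))
    if (vl < best$loss) {
      best <- list(loss = vl, params = params, epoch = epoch)
      since_improved <- 0L
    } else {
      since_improved <- since_improved + 1L
      if (since_improved >= tconf$patience) break
    }
  }
  history <- as.data.frame(do.call(rbind, hist))
  list(params = best$params, config = config, history = history,
       best_epoch = best$epoch, best_val_loss = best$loss)
}
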