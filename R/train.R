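#' Training configuration
#'
#' @param epochs number of passes over the training split.
#' @param batch_size movies per optimizer step.
#' @param learning_rate Adam step size.
#' @param n_runs number of independent training runs for repeated-run
#'   experiments (default 5).
#' @param validation_fraction held-out fraction (informational; the split is
#'   recorded in the dataset).
#' @param seed RNG seed (initialization draw and shuffling).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 16L,
                         learning_rate = 1e-3, n_runs = 5L,
                         validation_fraction = 0.2, seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, n_runs = as.integer(n_runs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

movie_input <- function(movie) {
  array(as.double(movie$frames), dim = dim(movie$frames))
}

flatten_params <- function(p) {
  unlist(lapply(p, function(x) if (is.list(x)) unlist(x) else x))
}

# in-place style Adam over the nested parameter list
adam_init <- function(params) {
  n <- length(flatten_params(params))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, mu_floor = 0.2) {
  g <- flatten_params(grads)
  p <- flatten_params(model$params)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  p <- p - lr * mhat / (sqrt(vhat) + eps)
  # unflatten back into the model
  pos <- 1L
  for (nm in names(model$params)) {
    cur <- model$params[[nm]]
    if (is.list(cur)) {
      for (i in seq_along(cur)) {
        len <- length(cur[[i]])
        model$params[[nm]][[i]][] <- p[pos:(pos + len - 1L)]
        pos <- pos + len
      }
    } else {
      len <- length(cur)
      model$params[[nm]][] <- p[pos:(pos + len - 1L)]
      pos <- pos + len
    }
  }
  # keep the time constants in a physically meaningful range
  model$params$mu1 <- pmax(model$params$mu1, mu_floor)
  model$params$mu2 <- pmax(model$params$mu2, mu_floor)
  list(model = model, state = state)
}

accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(total)) {
    if (is.list(total[[nm]])) {
      for (i in seq_along(total[[nm]])) {
        total[[nm]][[i]] <- total[[nm]][[i]] + g[[nm]][[i]]
      }
    } else {
      total[[nm]] <- total[[nm]] + g[[nm]]
    }
  }
  total
}

scale_grads <- function(g, f) {
  for (nm in names(g)) {
    if (is.list(g[[nm]])) {
      for (i in seq_along(g[[nm]])) g[[nm]][[i]] <- g[[nm]][[i]] * f
    } else {
      g[[nm]] <- g[[nm]] * f
    }
  }
  g
}

#' Train a tracking model with backpropagation through time
#'
#' Minimizes the mean per-frame L2 distance (px) between predicted and true
#' shape coordinates over the training split of an event dataset, unrolling
#' the temporal dynamics over all frames of each movie. The history records
#' train/validation loss and the trainable time constants after every epoch.
#'
#' @param model a [build_model()] result.
#' @param dataset an [make_dataset()] result (or any list with `movies` and
#'   `split`).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with the trained `model` and a `history` data-holder
#'   (`train_loss`, `val_loss` per epoch, `mu` snapshots including the
#'   initial values).
#' @export
train <- function(model, dataset, config, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  train_idx <- which(dataset$split == "train")
  val_idx <- which(dataset$split == "validation")
  history <- list(train_loss = numeric(0), val_loss = numeric(0),
                  mu = list(c(mu1 = model$params$mu1,
                              mu2 = model$params$mu2)))
  if (config$epochs == 0L) {
    return(list(model = model, history = history))
  }
  set.seed(config$seed)
  S <- model$config$n_output_shapes
  opt <- adam_init(model$params)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0; nb <- 0
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (b in batches) {
      total <- NULL; bloss <- 0
      for (i in b) {
        mv <- dataset$movies[[i]]
        fwd <- model_forward(model, movie_input(mv), keep = TRUE)
        bk <- model_backward(model, fwd,
                             mv$labels[, seq_len(S), , drop = FALSE])
        total <- accumulate_grads(total, bk$grads)
        bloss <- bloss + bk$loss
      }
      if (!is.finite(bloss)) {
        stop("train: loss diverged (non-finite) at epoch ", epoch,
             "; reduce the learning rate")
      }
      total <- scale_grads(total, 1 / length(b))
      upd <- adam_step(model, total, opt, config$learning_rate)
      model <- upd$model; opt <- upd$state
      ep_loss <- ep_loss + bloss / length(b); nb <- nb + 1
    }
    vloss <- evaluate(model, dataset, indices = val_idx)
    history$train_loss <- c(history$train_loss, ep_loss / nb)
    history$val_loss <- c(history$val_loss, vloss)
    history$mu <- c(history$mu, list(c(mu1 = model$params$mu1,
                                       mu2 = model$params$mu2)))
    if (verbose) {
      message(sprintf("epoch %d: train %.2f px, validation %.2f px",
                      epoch, ep_loss / nb, vloss))
    }
  }
  list(model = model, history = history)
}

#' Mean tracking loss of a model over (part of) a dataset
#'
#' @param model trained model.
#' @param dataset event dataset.
#' @param indices movie indices to evaluate (default: the validation split).
#' @return mean per-frame L2 loss in px.
#' @export
evaluate <- function(model, dataset, indices = NULL) {
  if (is.null(indices)) indices <- which(dataset$split == "validation")
  losses <- vapply(indices, function(i) {
    predict_movie(model, dataset$movies[[i]])$loss
  }, numeric(1))
  mean(losses)
}

#' Per-scale generalization curve
#'
#' Evaluates the validation loss separately for movies binned by their
#' transformation scale: starting size (spatial kind) or scale-velocity
#' magnitude (temporal kind), assigned to the nearest bin in log space.
#'
#' @param model trained model.
#' @param dataset event dataset with per-movie scale metadata.
#' @param bins bin centres; default `c(10, 20, 40, 80)` px (spatial) or
#'   `c(0.16, 0.32, 0.64, 1.28)` px/step (temporal).
#' @param indices movie indices (default: validation split).
#' @return data.frame with `bin`, `loss`, `n`; empty bins are omitted with a
#'   warning.
#' @export
evaluate_per_scale <- function(model, dataset, bins = NULL, indices = NULL) {
  if (is.null(bins)) {
    bins <- if (dataset$kind == "spatial") c(10, 20, 40, 80) else
      c(0.16, 0.32, 0.64, 1.28)
  }
  if (is.null(indices)) indices <- which(dataset$split == "validation")
  scales <- vapply(indices, function(i) {
    m <- dataset$movies[[i]]$meta
    if (dataset$kind == "spatial") m$size0 else m$scale_speed
  }, numeric(1))
  assign_bin <- bins[apply(abs(outer(log(scales), log(bins), "-")), 1,
                           which.min)]
  losses <- vapply(indices, function(i) {
    predict_movie(model, dataset$movies[[i]])$loss
  }, numeric(1))
  out <- do.call(rbind, lapply(bins, function(b) {
    sel <- assign_bin == b
    if (!any(sel)) return(NULL)
    data.frame(bin = b, loss = mean(losses[sel]), n = sum(sel))
  }))
  if (length(setdiff(bins, out$bin))) {
    warning("evaluate_per_scale: empty bins omitted: ",
            paste(setdiff(bins, out$bin), collapse = ", "))
  }
  out
}

#' Standardized effect size (Cohen's d) between two loss groups
#'
#' Computes `d = (mean(losses_init) - mean(losses_uniform)) / sigma_pool`
#' with the pooled standard deviation
#' `sigma_pool = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' The `"printed"` weight variant replaces the `(n2-1)` weight with
#' `(n2-2)`.
#'
#' @param losses_init,losses_uniform numeric vectors (>= 2 values each) of
#'   per-run losses for the two groups.
#' @param weights `"standard"` (default) or `"printed"`.
#' @return object of class `effect_size_report` with means, group variances,
#'   pooled SD and `cohens_d`.
#' @export
effect_size <- function(losses_init, losses_uniform,
                        weights = c("standard", "printed")) {
  weights <- match.arg(weights)
  n1 <- length(losses_init); n2 <- length(losses_uniform)
  if (n1 < 2 || n2 < 2) stop("effect_size: each group needs >= 2 samples")
  v1 <- var(losses_init); v2 <- var(losses_uniform)
  w2 <- if (weights == "standard") n2 - 1 else n2 - 2
  sp2 <- ((n1 - 1) * v1 + w2 * v2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("effect_size: zero pooled variance; d is undefined")
  sp <- sqrt(sp2)
  structure(list(mean_init = mean(losses_init),
                 mean_uniform = mean(losses_uniform),
                 sigma_pool = sp,
                 cohens_d = (mean(losses_init) - mean(losses_uniform)) / sp,
                 group_sizes = c(n1, n2), group_variances = c(v1, v2),
                 weights = weights),
            class = "effect_size_report")
}

#' @export
print.effect_size_report <- function(x, ...) {
  cat(sprintf(
    "effect size: mean_init %.3f, mean_uniform %.3f, sigma_pool %.3f, Cohen's d %.3f\n",
    x$mean_init, x$mean_uniform, x$sigma_pool, x$cohens_d))
  invisible(x)
}

#' Relative drift of the trainable time constants during training
#'
#' For every trainable time constant, computes the squared relative deviation
#' from its initial value, `((mu(e) - mu(0)) / mu(0))^2`, averaged across
#' constants, per epoch: a per-run analogue of the relative variance of the
#' time constants as training progresses. Frozen time constants give an
#' all-zero trace.
#'
#' @param history the `history` element of a [train()] result (or any list
#'   with a `mu` list of per-epoch snapshots, initial values first).
#' @return numeric vector, one value per recorded epoch (excluding the
#'   initial snapshot).
#' @export
mu_drift <- function(history) {
  mus <- history$mu
  if (length(mus) < 2) return(numeric(0))
  mu0 <- mus[[1]]
  vapply(mus[-1], function(m) mean(((m - mu0) / mu0)^2), numeric(1))
}

#' Repeated-run initialization comparison
#'
#' Trains pairs of models (receptive-field vs. uniform initialization) with
#' identical architecture on one shared dataset across several training
#' seeds, and collects the final validation losses: the desk-scale analogue
#' of the paper-style initialization experiment. The improvement percentage
#' is `(l_uniform - l_init) / l_uniform * 100` on the mean final losses.
#'
#' @param dataset event dataset to train on.
#' @param bank kernel bank matching the configuration.
#' @param config_args list of overrides for [scaled_down_config()].
#' @param n_seeds number of training runs per initialization.
#' @param epochs,batch_size,learning_rate training hyper-parameters.
#' @param seed master seed; run seeds are derived with [split_seed()].
#' @param verbose print progress.
#' @return list with `losses` (data.frame of per-run final validation
#'   losses), `histories`, `effect` (an [effect_size()] report) and
#'   `improvement_percent`.
#' @export
rf_comparison_experiment <- function(dataset, bank = scaled_down_bank(),
                                     config_args = list(), n_seeds = 5L,
                                     epochs = 20L, batch_size = 16L,
                                     learning_rate = 1e-3, seed = 1L,
                                     verbose = FALSE) {
  run_seeds <- split_seed(seed, n_seeds, stream = 7L)
  rows <- list(); histories <- list()
  for (r in seq_len(n_seeds)) {
    for (init in c("rf", "uniform")) {
      cfg <- do.call(scaled_down_config,
                     modifyList(list(init = init), config_args))
      mdl <- build_model(cfg, bank = bank, seed = run_seeds[r])
      tc <- train_config(epochs = epochs, batch_size = batch_size,
                         learning_rate = learning_rate,
                         seed = run_seeds[r])
      fit <- train(mdl, dataset, tc, verbose = FALSE)
      final <- tail(fit$history$val_loss, 1)
      rows[[length(rows) + 1L]] <-
        data.frame(run = r, init = init, final_val_loss = final)
      histories[[paste(init, r, sep = "_")]] <- fit$history
      if (verbose) {
        message(sprintf("run %d (%s): final validation loss %.2f px",
                        r, init, final))
      }
    }
  }
  losses <- do.call(rbind, rows)
  li <- losses$final_val_loss[losses$init == "rf"]
  lu <- losses$final_val_loss[losses$init == "uniform"]
  eff <- effect_size(li, lu)
  list(losses = losses, histories = histories, effect = eff,
       improvement_percent = (mean(lu) - mean(li)) / mean(lu) * 100,
       rf_wins = sum(li < lu), n_seeds = n_seeds)
}
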