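# Two-phase training orchestration: the VAE is trained first on normalized
# signals; the diffusion noise predictor is then trained on frozen-VAE
# latents (posterior means, standardized per channel), conditioned on the
# text + patient embedding. Four variants mirror the ablation grid:
# full / no_patient_info / no_vae / no_patient_info_no_vae.

VARIANTS <- c("full", "no_patient_info", "no_vae", "no_patient_info_no_vae")

#' Train the diffusion noise predictor
#'
#' Per step: draw a minibatch of clean latents z0, sample t uniformly in
#' 1..T per element, sample eps ~ N(0, I), form z_t by the forward marginal
#' and minimize mean((eps - eps_hat)^2) with Adam.
#'
#' @param z0 array [C, L, N] of clean (standardized) latents.
#' @param cond matrix [cond_dim x N] of condition vectors.
#' @param sched a [make_linear_schedule()].
#' @param model a [unet_init()] model (its config fixes shapes).
#' @param steps optimizer steps. @param batch_size,lr optimizer settings.
#' @param seed integer seed. @param verbose print progress.
#' @return list: `model`, `history` (loss per logged step).
#' @export
train_diffusion <- function(z0, cond, sched, model, steps = 2000L,
                            batch_size = 64L, lr = 5e-4, seed = 1,
                            verbose = FALSE) {
  d <- dim(z0)
  stopifnot(length(d) == 3L, d[1] == model$cfg$latent_ch,
            d[2] == model$cfg$latent_len, ncol(cond) == d[3],
            nrow(cond) == model$cfg$cond_dim, sched$T == model$cfg$T_steps)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  N <- d[3]
  losses <- numeric(steps)
  for (step in seq_len(steps)) {
    idx <- sample.int(N, min(batch_size, N))
    B <- length(idx)
    zb <- z0[, , idx, drop = FALSE]
    cb <- cond[, idx, drop = FALSE]
    t_b <- sample.int(sched$T, B, replace = TRUE)
    eps <- array(stats::rnorm(length(zb)), dim = dim(zb))
    ab <- sched$alpha_bar[t_b]
    zt <- sweep(zb, 3, sqrt(ab), `*`) + sweep(eps, 3, sqrt(1 - ab), `*`)
    pred <- unet_forward(model, zt, t_b, cb)
    losses[step] <- training_loss(eps, pred)
    nn_zero_grads(model$params)
    unet_backward(model, 2 * (pred - eps) / length(pred))
    nn_adam_step(model$params, lr, step)
    if (verbose && step %% 100 == 0)
      message(sprintf("step %d: loss %.4f (mean last 100: %.4f)", step,
                      losses[step], mean(losses[max(1, step - 99):step])))
  }
  list(model = model, history = losses)
}

#' Fit the conditional latent diffusion ECG generator
#'
#' End-to-end two-phase fit on a list of raw records or a preprocessed
#' dataset: curation (RR validation, filtering, downsampling,
#' normalization), condition assembly (ordered prompts through the text
#' embedder plus heart rate / age / sex), VAE training, latent
#' standardization, and diffusion training on the frozen-VAE posterior
#' means. Under `no_vae` variants the diffusion runs directly in signal
#' space; under `no_patient_info` variants the condition is the text
#' embedding alone.
#'
#' @param x list of [ecg_record]s or a [preprocess_records()] result.
#' @param variant one of "full", "no_patient_info", "no_vae",
#'   "no_patient_info_no_vae".
#' @param embedder a text embedder (default seeded hash embedder, dim 64).
#' @param latent_ch,latent_len latent shape (default 4 x 128).
#' @param unet_channels channel schedule (stages = its length).
#' @param T_steps,beta_start,beta_end noise schedule.
#' @param vae_epochs,diffusion_steps,batch_size,lr training settings.
#' @param scalars_mode "scaled" (hr/100, age/100) or "raw".
#' @param seed master seed.
#' @param cfg a [preprocess_config()] used when `x` is a raw record list.
#' @param verbose print training progress.
#' @return an object of class `cardiodiff`.
#' @export
cardiodiff <- function(x, variant = "full",
                       embedder = make_hash_embedder(64L, seed = 0L),
                       latent_ch = 4L, latent_len = 128L,
                       unet_channels = c(32, 48, 64),
                       T_steps = 1000L, beta_start = 0.00085,
                       beta_end = 0.0120,
                       vae_epochs = 8L, diffusion_steps = 2000L,
                       batch_size = 64L, lr = 5e-4,
                       scalars_mode = "scaled", seed = 1,
                       cfg = preprocess_config(), verbose = FALSE) {
  variant <- match.arg(variant, VARIANTS)
  ds <- if (is.list(x) && !is.null(x$x)) x else preprocess_records(x, cfg)
  use_vae <- !grepl("no_vae", variant)
  use_patient <- !grepl("no_patient_info", variant)

  cond <- condition_matrix(ds, embedder, scalars_mode,
                           patient_info = use_patient)

  vae_fit <- NULL
  if (use_vae) {
    vae_fit <- train_vae(ds$x, epochs = vae_epochs, batch_size = batch_size,
                         lr = lr, latent_ch = latent_ch,
                         latent_len = latent_len, seed = seed,
                         verbose = verbose)
    z0 <- vae_encode(vae_fit$model, ds$x)$mu
  } else {
    z0 <- ds$x
    latent_ch <- dim(ds$x)[1]; latent_len <- dim(ds$x)[2]
  }
  # standardize latents per channel so diffusion operates at unit scale
  ch_mean <- apply(z0, 1, mean)
  ch_sd <- pmax(apply(z0, 1, stats::sd), 1e-6)
  z0 <- sweep(sweep(z0, 1, ch_mean), 1, ch_sd, `/`)

  sched <- make_linear_schedule(beta_start, beta_end, T_steps)
  ucfg <- unet_config(latent_ch = latent_ch, latent_len = latent_len,
                      channels = unet_channels, cond_dim = nrow(cond),
                      T_steps = T_steps)
  unet <- unet_init(ucfg, seed = seed + 1)
  diff_fit <- train_diffusion(z0, cond, sched, unet,
                              steps = diffusion_steps,
                              batch_size = batch_size, lr = lr,
                              seed = seed + 2, verbose = verbose)

  structure(list(variant = variant, embedder = embedder,
                 scalars_mode = scalars_mode,
                 vae = if (use_vae) vae_fit$model else NULL,
                 vae_history = if (use_vae) vae_fit$history else NULL,
                 unet = diff_fit$model, diffusion_history = diff_fit$history,
                 sched = sched, latent_ch = latent_ch,
                 latent_len = latent_len,
                 latent_mean = ch_mean, latent_sd = ch_sd,
                 denorm_center = stats::median(ds$norm$center),
                 denorm_half = stats::median(ds$norm$half_range),
                 fs = ds$fs, n_train = dim(ds$x)[3], seed = seed),
            class = "cardiodiff")
}

#' Build a condition vector for generation
#'
#' @param fit a [cardiodiff] fit.
#' @param reports character vector of report strings.
#' @param sex,age,heart_rate patient-specific values (ignored under
#'   `no_patient_info` variants).
#' @return numeric condition vector of the fit's cond_dim.
#' @export
condition_for <- function(fit, reports, sex = "F", age = 60,
                          heart_rate = 70) {
  if (grepl("no_patient_info", fit$variant)) {
    fit$embedder$embed(build_prompt(reports))
  } else {
    assemble_condition(reports,
                       list(heart_rate = heart_rate, age = age, sex = sex),
                       fit$embedder, fit$scalars_mode)
  }
}

#' Generate 12-lead ECG signals from a fitted model
#'
#' Runs `n` independent ancestral sampling chains conditioned on the given
#' reports and patient-specific values, de-standardizes the latents, decodes
#' them through the VAE (identity under `no_vae`), and inverts the
#' normalization to millivolts. Deterministic given `seed`.
#'
#' @param fit a [cardiodiff] fit.
#' @param reports character vector of report strings.
#' @param sex,age,heart_rate conditioning values.
#' @param n number of signals. @param seed integer seed.
#' @param as_records return [ecg_record]s instead of a raw array.
#' @param conditional when FALSE the condition vector is zeroed — the
#'   unconditional baseline used in the patient-specific-information
#'   ablation.
#' @return [12, L, n] array of signals (mV), or a list of records.
#' @export
generate_ecg <- function(fit, reports, sex = "F", age = 60, heart_rate = 70,
                         n = 1L, seed = 1, as_records = FALSE,
                         conditional = TRUE) {
  cond <- condition_for(fit, reports, sex, age, heart_rate)
  if (!conditional) cond <- 0 * cond
  latent_dim <- c(fit$latent_ch, fit$latent_len)
  predictor <- function(z, t, cc) unet_forward(fit$unet, z, t, cc)
  L_out <- if (is.null(fit$vae)) fit$latent_len else fit$vae$L
  out <- array(0, dim = c(12, L_out, n))
  for (i in seq_len(n)) {
    z <- sample_loop(predictor, cond, fit$sched, latent_dim,
                     seed = seed + i - 1L)
    z <- sweep(sweep(z, 1, fit$latent_sd, `*`), 1, fit$latent_mean, `+`)
    sig <- if (is.null(fit$vae)) z else vae_decode(fit$vae, z)
    out[, , i] <- denormalize_signal(sig, fit$denorm_center, fit$denorm_half)
  }
  if (!as_records) return(out)
  lapply(seq_len(n), function(i) {
    ecg_record(out[, , i], fs = fit$fs,
               record_id = sprintf("gen%04d", i), patient_id = "generated",
               reports = reports, sex = sex, age = age,
               heart_rate = heart_rate)
  })
}

#' @export
print.cardiodiff <- function(x, ...) {
  cat(sprintf("<cardiodiff fit: variant '%s'>\n", x$variant))
  cat(sprintf("  latent %d x %d%s; diffusion T = %d, beta in [%g, %g]\n",
              x$latent_ch, x$latent_len,
              if (is.null(x$vae)) " (signal space, no VAE)" else "",
              x$sched$T, x$sched$beta[1], x$sched$beta[x$sched$T]))
  cat(sprintf("  trained on %d records; condition dim %d (%s scalars)\n",
              x$n_train, x$unet$cfg$cond_dim,
              if (grepl("no_patient_info", x$variant)) "no" else x$scalars_mode))
  invisible(x)
}

#' @export
summary.cardiodiff <- function(object, ...) {
  print(object)
  if (!is.null(object$vae_history)) {
    cat("  VAE loss by epoch: ",
        paste(sprintf("%.4f", object$vae_history$loss), collapse = " "), "\n")
  }
  h <- object$diffusion_history
  tail_n <- min(200L, length(h))
  cat(sprintf("  diffusion loss: first 100 = %.4f, last %d = %.4f\n",
              mean(h[seq_len(min(100, length(h)))]), tail_n,
              mean(h[(length(h) - tail_n + 1):length(h)])))
  invisible(object)
}

#' Simulate ECGs from a fitted generator
#'
#' `simulate` method: draws `nsim` conditional ECGs per row of `newdata`
#' (columns reports, sex, age, heart_rate; `reports` may be a list column).
#'
#' @param object a [cardiodiff] fit.
#' @param nsim signals per condition. @param seed integer seed.
#' @param newdata data.frame of conditions; defaults to one generic row.
#' @param ... unused.
#' @return list (one per condition row) of [12, L, nsim] arrays.
#' @export
simulate.cardiodiff <- function(object, nsim = 1, seed = 1, newdata = NULL,
                                ...) {
  if (is.null(newdata))
    newdata <- data.frame(reports = I(list("sinus rhythm")), sex = "F",
                          age = 60, heart_rate = 70)
  lapply(seq_len(nrow(newdata)), function(i) {
    reps <- newdata$reports[[i]]
    generate_ecg(object, reps, sex = as.character(newdata$sex[i]),
                 age = newdata$age[i], heart_rate = newdata$heart_rate[i],
                 n = nsim, seed = seed + 1000L * (i - 1L))
  })
}

#' Benchmark a fit against held-out records
#'
#' For each held-out record one ECG is generated from that record's own
#' conditions; the paired real/generated sets are then scored with the
#' three-level evaluation.
#'
#' @param fit a [cardiodiff] fit.
#' @param holdout list of [ecg_record]s (already curated: heart rate, sex,
#'   age present; length-matched to the model input after downsampling).
#' @param encoder a `signal_encoder` for the signal-level metrics.
#' @param k manifold neighbour order. @param seed integer seed.
#' @param alignment,text optional diagnostic-level inputs (see
#'   [evaluate_three_level()]).
#' @return a `metrics_report`.
#' @export
run_benchmark <- function(fit, holdout, encoder, k = 3L, seed = 1,
                          alignment = NULL, text = NULL) {
  gen <- vector("list", length(holdout))
  for (i in seq_along(holdout)) {
    r <- holdout[[i]]
    sig <- generate_ecg(fit, r$reports, sex = r$sex, age = r$age,
                        heart_rate = r$heart_rate, n = 1L,
                        seed = seed + i)
    gen[[i]] <- ecg_record(sig[, , 1], fs = fit$fs,
                           record_id = paste0("gen_", r$record_id),
                           reports = r$reports, sex = r$sex, age = r$age,
                           heart_rate = r$heart_rate)
  }
  evaluate_three_level(holdout, gen, encoder, k = k,
                       hr_ref = vapply(holdout, `[[`, 0, "heart_rate"),
                       alignment = alignment, text = text)
}
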