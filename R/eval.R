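## Evaluation protocols: leave-one-subject-out cross-validation with
## micro-averaged metrics and ROC analysis, the few-shot personalization
## protocol over the fusion head, and the subject-wise learning curve with
## its saturating-exponential fit.

## Per-epoch unimodal and fused binary predictions from a decision table.
.fd_binary_preds <- function(dec, alpha) {
  s <- ifelse(is.na(dec$s_anomaly), 0, dec$s_anomaly)
  list(fused = dec$label == "FALL",
       imu = s > alpha,
       vision = dec$p_fall > alpha,
       fused_score = pmin(dec$p_fall, s),
       imu_score = s,
       vision_score = dec$p_fall,
       truth = dec$truth)
}

.fd_counts <- function(pred, truth) {
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' Leave-one-subject-out evaluation of the bimodal detector
#'
#' For each subject: trains the detector (autoencoder on non-fall windows,
#' threshold calibration, transformer) on every other subject, then scores
#' all of the held-out subject's trials per 1-s epoch. Fused decisions use
#' the conjunctive rule; IMU-only (`s_anomaly > alpha`) and vision-only
#' (`p_fall > alpha`) baselines are evaluated on the same epochs.
#' Micro-averaged metrics pool confusion counts across folds before
#' computing rates; LOW_CONFIDENCE maps to not-FALL.
#'
#' @param cohort An [fd_generate_cohort()] cohort.
#' @param config An [fd_config()].
#' @param seed Integer seed.
#' @param verbose Progress messages.
#' @return List of class `fd_loso`: `folds` (per-fold counts, metrics and
#'   AUCs for the three systems), `micro` (pooled metrics), `epochs`
#'   (pooled per-epoch table with subject ids).
#' @export
fd_loso_run <- function(cohort, config = fd_config(), seed = 1,
                        verbose = FALSE) {
  .fd_assert(length(cohort$subjects) >= 2, "LOSO needs >= 2 subjects")
  folds <- list()
  pooled <- list(fused = c(tp = 0, fp = 0, tn = 0, fn = 0),
                 imu = c(tp = 0, fp = 0, tn = 0, fn = 0),
                 vision = c(tp = 0, fp = 0, tn = 0, fn = 0))
  all_epochs <- list()
  for (held in cohort$subjects) {
    if (length(cohort$trials[[held]]) == 0) {
      warning(sprintf("subject %s has no trials; fold skipped", held))
      next
    }
    if (verbose) message("LOSO fold: holding out ", held)
    train_subj <- setdiff(cohort$subjects, held)
    det <- fall_detector(cohort, subjects = train_subj, config = config,
                         seed = fd_subseed(seed, match(held, cohort$subjects)),
                         verbose = FALSE)
    dec <- do.call(rbind, lapply(cohort$trials[[held]], function(tr) {
      d <- predict(det, tr)
      d$subject <- held
      d$activity <- tr$script$activity_kind
      d
    }))
    bp <- .fd_binary_preds(dec, config$alpha)
    fold <- list(subject = held, train_subjects = train_subj)
    for (sys in c("fused", "imu", "vision")) {
      cnt <- .fd_counts(bp[[sys]], bp$truth)
      fold[[sys]] <- c(cnt, fd_metrics(cnt$tp, cnt$fp, cnt$tn, cnt$fn))
      pooled[[sys]] <- pooled[[sys]] +
        c(tp = cnt$tp, fp = cnt$fp, tn = cnt$tn, fn = cnt$fn)
      sc <- bp[[paste0(sys, "_score")]]
      fold[[paste0(sys, "_auc")]] <-
        if (length(unique(bp$truth)) == 2) fd_roc_auc(sc, bp$truth)$auc
        else NA_real_
    }
    folds[[held]] <- fold
    all_epochs[[held]] <- dec
  }
  micro <- lapply(pooled, function(cn) {
    fd_metrics(unname(cn["tp"]), unname(cn["fp"]),
               unname(cn["tn"]), unname(cn["fn"]))
  })
  structure(list(folds = folds, micro = micro,
                 epochs = do.call(rbind, all_epochs), seed = seed),
            class = "fd_loso")
}

#' @export
print.fd_loso <- function(x, ...) {
  cat("LOSO evaluation over", length(x$folds), "folds,",
      nrow(x$epochs), "pooled epochs\n")
  cat(sprintf("  micro F1 : fused %.3f | IMU-only %.3f | vision-only %.3f\n",
              x$micro$fused$f1, x$micro$imu$f1, x$micro$vision$f1))
  cat(sprintf("  micro FPR: fused %.3f | IMU-only %.3f | vision-only %.3f\n",
              x$micro$fused$fpr, x$micro$imu$fpr, x$micro$vision$fpr))
  invisible(x)
}

#' Per-fold metric vector from a LOSO result
#'
#' @param loso An [fd_loso_run()] result.
#' @param system `"fused"`, `"imu"` or `"vision"`.
#' @param metric Metric name from [fd_metrics()].
#' @return Numeric vector, one value per fold.
#' @export
fd_fold_values <- function(loso, system = "fused", metric = "f1") {
  vapply(loso$folds, function(f) f[[system]][[metric]], numeric(1))
}

#' Per-subject labeled score sets from a LOSO result
#'
#' Extracts each held-out subject's per-epoch `(p_fall, s_anomaly, label)`
#' triples — the inputs the few-shot personalization protocol fine-tunes the
#' fusion head on (both encoders are frozen, so the head only ever sees
#' these scores).
#'
#' @param loso An [fd_loso_run()] result.
#' @return Named list of data.frames with columns `p_fall`, `s_anomaly`,
#'   `label` (binary).
#' @export
fd_score_sets <- function(loso) {
  ep <- loso$epochs
  out <- lapply(split(ep, ep$subject), function(d) {
    data.frame(p_fall = d$p_fall,
               s_anomaly = ifelse(is.na(d$s_anomaly), 0, d$s_anomaly),
               label = as.integer(d$truth))
  })
  out
}

#' Simulate subject-shifted branch-score cohorts
#'
#' Generates per-subject labeled `(p_fall, s_anomaly)` pairs with
#' subject-specific operating points: each subject's fall-epoch score means
#' are drawn once (some subjects' vision scores sit below the global
#' threshold, emulating the inter-individual shift that personalization is
#' meant to absorb), then per-epoch scores are drawn around those means and
#' clamped to `[0, 1]`.
#'
#' @param n_subjects Number of subjects.
#' @param n_fall,n_normal Epochs per class per subject.
#' @param seed Integer seed.
#' @param noise_sd Score noise.
#' @return Named list of data.frames (`p_fall`, `s_anomaly`, `label`).
#' @export
fd_simulate_score_cohort <- function(n_subjects = 16, n_fall = 20,
                                     n_normal = 40, seed = 1,
                                     noise_sd = 0.08) {
  out <- list()
  for (i in seq_len(n_subjects)) {
    set.seed(fd_subseed(seed, 301L, i))
    mu_pf <- stats::runif(1, 0.5, 0.9)    # some subjects below alpha = 0.7
    mu_sf <- stats::runif(1, 0.75, 0.95)
    mu_pn <- stats::runif(1, 0.1, 0.4)
    mu_sn <- stats::runif(1, 0.15, 0.45)
    clamp <- function(x) pmin(pmax(x, 0), 1)
    d <- data.frame(
      p_fall = clamp(c(stats::rnorm(n_fall, mu_pf, noise_sd),
                       stats::rnorm(n_normal, mu_pn, noise_sd))),
      s_anomaly = clamp(c(stats::rnorm(n_fall, mu_sf, noise_sd),
                          stats::rnorm(n_normal, mu_sn, noise_sd))),
      label = c(rep(1L, n_fall), rep(0L, n_normal)))
    out[[sprintf("S%02d", i)]] <- d
  }
  out
}

## Class-stratified sample of K calibration indices from a labeled set.
.fd_sample_cal <- function(labels, K, seed) {
  set.seed(seed)
  n <- length(labels)
  K <- min(K, n - 1L)  # keep at least one test item
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (length(pos) == 0 || length(neg) == 0) return(sort(sample(n, K)))
  k_pos <- max(1L, min(round(K * length(pos) / n), length(pos), K - 1L))
  if (K == 1L) k_pos <- sample(0:1, 1)
  k_neg <- K - k_pos
  k_neg <- min(k_neg, length(neg))
  k_pos <- K - k_neg
  sort(c(sample(pos, k_pos), sample(neg, k_neg)))
}

#' Few-shot personalization curve
#'
#' For each subject (fold) and each K: draws a class-stratified calibration
#' set of exactly K labeled score pairs (without replacement), fine-tunes a
#' fresh AND-rule-initialized fusion head on it, and evaluates F1 on the
#' disjoint remainder of the subject's set. Reports the fold-mean F1 per K
#' (with the fold-wise Student-t confidence interval), averaged over
#' replicate seeds.
#'
#' @param score_sets Named list of per-subject data.frames (`p_fall`,
#'   `s_anomaly`, `label`), e.g. from [fd_score_sets()] or
#'   [fd_simulate_score_cohort()].
#' @param K_range Calibration-set sizes (default 1..10).
#' @param n_seeds Replicate draws.
#' @param seed Base seed.
#' @param alpha Threshold for the head initialization.
#' @param lr,iterations Fine-tuning recipe (see [fd_fine_tune_head()]).
#' @return List of class `fd_fewshot`: `summary` data.frame (`K`,
#'   `mean_f1`, `ci_lower`, `ci_upper`), `fold_f1` array
#'   (seed x K x subject), `baseline_f1` (untuned head, per subject).
#' @export
fd_few_shot_curve <- function(score_sets, K_range = 1:10, n_seeds = 10,
                              seed = 1, alpha = 0.70, lr = 0.05,
                              iterations = 50) {
  subjects <- names(score_sets)
  .fd_assert(length(subjects) >= 2, "need >= 2 subjects")
  f1_of <- function(head, d) {
    ph <- fd_fusion_head_predict(head, d$p_fall, d$s_anomaly)
    pred <- ph > 0.5
    m <- fd_metrics(sum(pred & d$label == 1), sum(pred & d$label == 0),
                    sum(!pred & d$label == 0), sum(!pred & d$label == 1))
    if (is.na(m$f1)) 0 else m$f1
  }
  base_head <- fd_fusion_head(alpha = alpha, seed = seed)
  baseline <- vapply(score_sets, function(d) f1_of(base_head, d), numeric(1))
  arr <- array(NA_real_, c(n_seeds, length(K_range), length(subjects)),
               dimnames = list(NULL, paste0("K", K_range), subjects))
  for (sd_i in seq_len(n_seeds)) {
    for (ki in seq_along(K_range)) {
      K <- K_range[ki]
      for (si in seq_along(subjects)) {
        d <- score_sets[[si]]
        .fd_assert(nrow(d) >= 2, "subject %s has too few sequences",
                   subjects[si])
        if (K > nrow(d) - 1L) {
          warning(sprintf("K=%d exceeds subject %s's sequences; capped",
                          K, subjects[si]))
        }
        cal <- .fd_sample_cal(d$label, K, fd_subseed(seed, sd_i, ki, si))
        test <- setdiff(seq_len(nrow(d)), cal)
        head <- fd_fusion_head(alpha = alpha, seed = seed)
        head <- fd_fine_tune_head(head, d$p_fall[cal], d$s_anomaly[cal],
                                  d$label[cal], lr = lr,
                                  iterations = iterations)
        arr[sd_i, ki, si] <- f1_of(head, d[test, , drop = FALSE])
      }
    }
  }
  fold_means <- apply(arr, c(2, 3), mean)  # K x subject, averaged over seeds
  summ <- do.call(rbind, lapply(seq_along(K_range), function(ki) {
    ci <- fd_fold_ci(fold_means[ki, ])
    data.frame(K = K_range[ki], mean_f1 = ci$mean, ci_lower = ci$lower,
               ci_upper = ci$upper)
  }))
  structure(list(summary = summ, fold_f1 = arr, baseline_f1 = baseline),
            class = "fd_fewshot")
}

#' @export
print.fd_fewshot <- function(x, ...) {
  cat("Few-shot personalization curve (fold-mean F1 by K):\n")
  print(x$summary, row.names = FALSE, digits = 3)
  cat("Untuned-head fold-mean F1:", format(mean(x$baseline_f1), digits = 3),
      "\n")
  invisible(x)
}

#' Fit a saturating exponential to learning-curve points
#'
#' Nonlinear least squares for `F1(n) = a - b * exp(-c * n)` with
#' initialization `a0 = max(mean F1)`, `b0 = a0 - min(mean F1)`,
#' `c0 = 0.3`. The asymptote equals `a`; its confidence interval is obtained
#' by bootstrap over the per-m replicate values when supplied. The
#' saturation flag is raised when the fitted gain from m = 12 to m = 16 (or
#' between the last two grid points when the grid is smaller) is below 0.5
#' percentage points.
#'
#' @param m Training-set sizes (subjects).
#' @param f1 Mean F1 per size (same scale as the data, typically `[0, 1]`).
#' @param replicates Optional repeats-by-m matrix of per-draw F1 values for
#'   the bootstrap CI.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return List of class `fd_lcfit`: `a`, `b`, `c`, `fitted`, `asymptote`,
#'   `asymptote_ci` (or NULL), `saturated`, `fit` (the nls object).
#' @export
fd_fit_learning_curve <- function(m, f1, replicates = NULL, n_boot = 1000,
                                  seed = 1) {
  .fd_assert(length(m) == length(f1) && length(m) >= 3,
             "need >= 3 (m, F1) points")
  a0 <- max(f1); b0 <- max(a0 - min(f1), 1e-3); c0 <- 0.3
  dat <- data.frame(m = m, f1 = f1)
  if (diff(range(f1)) < 1e-8) {
    ## constant points: the exponential term is unidentifiable; the curve
    ## degenerates to its asymptote with no growth component
    cf <- c(a = mean(f1), b = 0, c = c0)
    fit <- NULL
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(f1 ~ a - b * exp(-c * m), data = dat,
                        start = list(a = a0, b = b0, c = c0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        stop(sprintf(paste0("learning-curve fit failed to converge: %s ",
                            "(starts a=%.4f b=%.4f c=%.2f over %d points)"),
                     conditionMessage(e), a0, b0, c0, length(m)),
             call. = FALSE)
      })
    cf <- stats::coef(fit)
  }
  pred <- function(cfv, mm) cfv["a"] - cfv["b"] * exp(-cfv["c"] * mm)
  gain <- if (max(m) >= 16 && min(m) <= 12) {
    pred(cf, 16) - pred(cf, 12)
  } else {
    pred(cf, max(m)) - pred(cf, sort(m, decreasing = TRUE)[2])
  }
  scale_pp <- if (max(f1) <= 1.5) 0.005 else 0.5  # 0.5 percentage points
  ci <- NULL
  if (!is.null(replicates)) {
    replicates <- as.matrix(replicates)
    .fd_assert(ncol(replicates) == length(m),
               "replicates must have one column per m")
    boots <- numeric(n_boot)
    for (bb in seq_len(n_boot)) {
      set.seed(fd_subseed(seed, 401L, bb))
      f1b <- vapply(seq_len(ncol(replicates)), function(j) {
        v <- replicates[, j]
        mean(v[sample(length(v), replace = TRUE)])
      }, numeric(1))
      fb <- tryCatch(
        minpack.lm::nlsLM(f1 ~ a - b * exp(-c * m),
                          data = data.frame(m = m, f1 = f1b),
                          start = as.list(cf),
                          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      boots[bb] <- if (is.null(fb)) NA_real_ else stats::coef(fb)["a"]
    }
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  }
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["c"]),
                 fitted = unname(pred(cf, m)), asymptote = unname(cf["a"]),
                 asymptote_ci = ci, saturated = gain < scale_pp,
                 gain_12_16 = unname(gain), fit = fit),
            class = "fd_lcfit")
}

#' @export
print.fd_lcfit <- function(x, ...) {
  cat(sprintf("Saturating-exponential fit: F1(n) = %.4f - %.4f exp(-%.4f n)\n",
              x$a, x$b, x$c))
  cat("Asymptote:", format(x$asymptote, digits = 4))
  if (!is.null(x$asymptote_ci)) {
    cat(sprintf(" (95%% CI %.4f-%.4f)", x$asymptote_ci[1], x$asymptote_ci[2]))
  }
  cat(" | saturated:", x$saturated, "\n")
  invisible(x)
}

#' Subject-wise learning curve
#'
#' For each cohort size m in `m_grid`, repeatedly samples m subjects and
#' runs LOSO within the sampled subset (each fold trains on m - 1 subjects),
#' recording the fold-mean fused F1. Reports the mean and Student-t CI per
#' m and the saturating-exponential fit over the means.
#'
#' @param cohort An [fd_generate_cohort()] cohort.
#' @param m_grid Cohort sizes to evaluate (each <= number of subjects).
#' @param repeats Random draws per size.
#' @param config An [fd_config()].
#' @param seed Integer seed.
#' @param verbose Progress messages.
#' @return List of class `fd_lcurve`: `points` data.frame (`m`, `mean_f1`,
#'   `ci_lower`, `ci_upper`), `replicates` (repeats x m matrix), `fit`.
#' @export
fd_learning_curve <- function(cohort, m_grid = seq(2, 16, by = 2),
                              repeats = 10, config = fd_config(), seed = 1,
                              verbose = FALSE) {
  .fd_assert(max(m_grid) <= length(cohort$subjects),
             "m_grid exceeds cohort size")
  reps <- matrix(NA_real_, repeats, length(m_grid))
  for (mi in seq_along(m_grid)) {
    m <- m_grid[mi]
    for (r in seq_len(repeats)) {
      set.seed(fd_subseed(seed, 501L, mi, r))
      subj <- sample(cohort$subjects, m)
      sub <- list(subjects = subj, trials = cohort$trials[subj],
                  seed = cohort$seed)
      class(sub) <- "fd_cohort"
      ls <- fd_loso_run(sub, config = config,
                        seed = fd_subseed(seed, 502L, mi, r),
                        verbose = FALSE)
      reps[r, mi] <- mean(fd_fold_values(ls, "fused", "f1"), na.rm = TRUE)
      if (verbose) message(sprintf("m=%d rep %d: F1=%.3f", m, r, reps[r, mi]))
    }
  }
  pts <- do.call(rbind, lapply(seq_along(m_grid), function(mi) {
    v <- reps[, mi]
    ci <- if (repeats >= 2) fd_fold_ci(v) else
      list(mean = mean(v), lower = NA, upper = NA)
    data.frame(m = m_grid[mi], mean_f1 = ci$mean, ci_lower = ci$lower,
               ci_upper = ci$upper)
  }))
  fit <- if (length(m_grid) >= 3) {
    fd_fit_learning_curve(pts$m, pts$mean_f1, replicates = reps, seed = seed)
  } else NULL
  structure(list(points = pts, replicates = reps, fit = fit),
            class = "fd_lcurve")
}

#' @export
print.fd_lcurve <- function(x, ...) {
  cat("Subject-wise learning curve:\n")
  print(x$points, row.names = FALSE, digits = 3)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
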